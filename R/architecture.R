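#' Network configuration for the W-shaped separator
#'
#' Describes the dual encoder-decoder ("W") architecture: two attention
#' R2U-Net branches share one input segment; the maternal branch (wider
#' kernel, 5) reconstructs the maternal ECG, the fetal branch (kernel 3)
#' reconstructs the fetal ECG after subtracting the maternal encoder's
#' features level by level (`tanh(fetal - maternal)`). Each branch has
#' `depth` encoder levels of recurrent-residual convolution blocks joined
#' by factor-2 max pooling, and a mirrored decoder of linear upsampling,
#' additive attention gates on the skip paths, and RRC blocks; output heads
#' are linear 1x1 convolutions.
#'
#' @param depth encoder levels (>= 2, default 5).
#' @param channels per-level widths; default `base_channels * 2^(0:(depth-1))
#'   * width_multiplier` = 64, 128, 256, 512, 1024 at full width.
#' @param base_channels width of the first level before scaling.
#' @param width_multiplier scale factor for desk-scale configurations
#'   (e.g. 1/8).
#' @param kernel_maternal,kernel_fetal odd kernel sizes of the two branches
#'   (defaults 5 and 3).
#' @param recurrence_T recurrence steps inside each block (default 2).
#' @param pool_factor pooling factor (fixed at 2).
#' @param fusion_levels encoder levels at which maternal features are
#'   subtracted (default: all levels including the bottleneck).
#' @param fuse_feedforward if `TRUE`, the fetal encoder consumes the fused
#'   maps when descending to the next level; if `FALSE` (default) fusion
#'   feeds only the decoder skip paths and the bottleneck.
#' @param activation `"leaky_relu"` (default) or `"relu"`.
#' @param block_type `"rrc"` (default), `"forward"`, `"residual"` or
#'   `"recurrent"` — the ablation axis over block variants.
#' @param attention use attention gates on skip paths (`TRUE`) or plain
#'   skips (`FALSE`).
#' @param input_length nominal segment length (1024); any length divisible
#'   by `2^(depth-1)` is accepted at run time.
#' @return an object of class `r2wnet_config`.
#' @export
r2wnet_config <- function(depth = 5L, channels = NULL, base_channels = 64L,
                          width_multiplier = 1, kernel_maternal = 5L,
                          kernel_fetal = 3L, recurrence_T = 2L,
                          pool_factor = 2L, fusion_levels = NULL,
                          fuse_feedforward = FALSE,
                          activation = c("leaky_relu", "relu"),
                          block_type = c("rrc", "forward", "residual",
                                         "recurrent"),
                          attention = TRUE, input_length = 1024L) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2")
  if (is.null(channels))
    channels <- pmax(1L, as.integer(round(base_channels *
                                            2^(seq_len(depth) - 1L) *
                                            width_multiplier)))
  channels <- as.integer(channels)
  if (length(channels) != depth) stop("channels must have one width per level")
  if (any(diff(channels) <= 0)) stop("channels must be strictly increasing")
  if (kernel_maternal %% 2L != 1L || kernel_fetal %% 2L != 1L)
    stop("kernels must be odd")
  recurrence_T <- as.integer(recurrence_T)
  if (recurrence_T < 1L) stop("recurrence_T must be >= 1")
  if (pool_factor != 2L) stop("only pool_factor = 2 is supported")
  if (is.null(fusion_levels)) fusion_levels <- seq_len(depth)
  fusion_levels <- sort(unique(as.integer(fusion_levels)))
  if (any(fusion_levels < 1L | fusion_levels > depth))
    stop("fusion_levels out of range")
  structure(list(depth = depth, channels = channels,
                 kernel_maternal = as.integer(kernel_maternal),
                 kernel_fetal = as.integer(kernel_fetal),
                 recurrence_T = recurrence_T, pool_factor = 2L,
                 fusion_levels = fusion_levels,
                 fuse_feedforward = isTRUE(fuse_feedforward),
                 activation = match.arg(activation),
                 block_type = match.arg(block_type),
                 attention = isTRUE(attention),
                 input_length = as.integer(input_length)),
            class = "r2wnet_config")
}

#' @export
print.r2wnet_config <- function(x, ...) {
  cat("<r2wnet_config>\n")
  cat(sprintf("  depth %d, channels %s\n", x$depth,
              paste(x$channels, collapse = "/")))
  cat(sprintf("  kernels maternal %d / fetal %d, recurrence T = %d, %s blocks\n",
              x$kernel_maternal, x$kernel_fetal, x$recurrence_T, x$block_type))
  cat(sprintf("  fusion at levels %s%s, attention %s, activation %s\n",
              paste(x$fusion_levels, collapse = ","),
              if (x$fuse_feedforward) " (feed-forward wiring)" else "",
              ifelse(x$attention, "on", "off"), x$activation))
  invisible(x)
}

# Initialise all parameters of both branches into a flat named list.
init_model_params <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  par <- list()
  ch <- config$channels; d <- config$depth
  for (side in c("m", "f")) {
    k <- if (side == "m") config$kernel_maternal else config$kernel_fetal
    cin <- 1L
    for (l in seq_len(d)) {
      par <- block_init(par, sprintf("%s.enc%d", side, l), cin, ch[l], k,
                        config$block_type)
      cin <- ch[l]
    }
    for (l in seq_len(d - 1L)) {
      par[[sprintf("%s.up%d.W", side, l)]] <- init_conv(ch[l], ch[l + 1L], k)
      par[[sprintf("%s.up%d.b", side, l)]] <- numeric(ch[l])
      if (config$attention)
        par <- ag_init(par, sprintf("%s.ag%d", side, l), ch[l], ch[l])
      par <- block_init(par, sprintf("%s.dec%d", side, l), 2L * ch[l], ch[l],
                        k, config$block_type)
    }
    par[[sprintf("%s.head.W", side)]] <- init_conv(1L, ch[1L], 1L, gain = 0.5)
    par[[sprintf("%s.head.b", side)]] <- 0
  }
  par
}

#' Count trainable parameters
#'
#' @param model an `r2wnet` fit, an `r2wnet_model`, or a flat parameter
#'   list.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  par <- if (is.list(model) && !is.null(model$params)) model$params else model
  sum(vapply(par, length, integer(1)))
}

#' Construct an (untrained) W-shaped separator
#'
#' Builds the parameter set for a [r2wnet_config()] with seeded He-style
#' initialisation. Training is done by [r2wnet()] or [train_r2wnet()].
#'
#' @param config an [r2wnet_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `r2wnet_model` (list with `params`,
#'   `config`, `seed`).
#' @export
r2wnet_model <- function(config = r2wnet_config(), seed = 1L) {
  structure(list(params = init_model_params(config, seed), config = config,
                 seed = as.integer(seed)),
            class = "r2wnet_model")
}

check_input_length <- function(L, config) {
  div <- 2L^(config$depth - 1L)
  if (L %% div != 0L)
    stop("input length ", L, " is not divisible by 2^(depth-1) = ", div)
}

# ---- encoder ----------------------------------------------------------

enc_forward_side <- function(par, side, x, config, feed = NULL) {
  # feed: optional list replacing the per-level descent input (fused maps)
  d <- config$depth
  k <- if (side == "m") config$kernel_maternal else config$kernel_fetal
  feats <- vector("list", d); caches <- vector("list", d)
  pools <- vector("list", d - 1L)
  for (l in seq_len(d)) {
    blk <- block_fw(x, par, sprintf("%s.enc%d", side, l), k,
                    config$block_type, config$recurrence_T,
                    config$activation)
    feats[[l]] <- blk$out; caches[[l]] <- blk$cache
    if (l < d) {
      src <- if (!is.null(feed) && !is.null(feed[[l]])) feed[[l]] else blk$out
      mp <- maxpool_fw(src)
      x <- mp$out; pools[[l]] <- mp$first
    }
  }
  list(feats = feats, caches = caches, pools = pools)
}

#' Run one encoder branch
#'
#' Exposes the per-level feature maps of one branch's encoder for a single
#' input window: level `l` has `channels[l]` channels and length
#' `L / 2^(l-1)`; the deepest level is the bottleneck.
#'
#' @param segment numeric vector or 1 x L matrix (a preprocessed window).
#' @param side `"maternal"` or `"fetal"` (selects the branch kernel).
#' @param model an `r2wnet_model` or `r2wnet` fit.
#' @return list of per-level feature maps (the last one is the
#'   bottleneck).
#' @export
encoder_forward <- function(segment, side = c("maternal", "fetal"), model) {
  side <- match.arg(side)
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1L)
  config <- model$config
  check_input_length(ncol(segment), config)
  enc_forward_side(model$params, substr(side, 1L, 1L), segment,
                   config)$feats
}

# ---- decoder ----------------------------------------------------------

dec_forward_side <- function(par, side, skips, config) {
  d <- config$depth
  k <- if (side == "m") config$kernel_maternal else config$kernel_fetal
  x <- skips[[d]]
  caches <- vector("list", d - 1L)
  for (l in rev(seq_len(d - 1L))) {
    u2 <- upsample_fw(x)
    zup <- conv_fw(u2, par[[sprintf("%s.up%d.W", side, l)]],
                   par[[sprintf("%s.up%d.b", side, l)]], k)
    g <- act_fw(zup, config$activation)
    s <- skips[[l]]
    if (config$attention) {
      ag <- ag_fw(s, g, par, sprintf("%s.ag%d", side, l))
      gs <- ag$out; agc <- ag$cache
    } else { gs <- s; agc <- NULL }
    blk <- block_fw(rbind(gs, g), par, sprintf("%s.dec%d", side, l), k,
                    config$block_type, config$recurrence_T,
                    config$activation)
    caches[[l]] <- list(u2 = u2, zup = zup, ag = agc, blk = blk$cache,
                        c_l = config$channels[l])
    x <- blk$out
  }
  pred <- conv_fw(x, par[[sprintf("%s.head.W", side)]],
                  par[[sprintf("%s.head.b", side)]], 1L)
  list(pred = pred, caches = caches, top = x)
}

dec_backward_side <- function(gpred, fwd, par, side, config, genv) {
  d <- config$depth
  k <- if (side == "m") config$kernel_maternal else config$kernel_fetal
  acc_grad(genv, sprintf("%s.head.W", side), conv_bw_w(gpred, fwd$top, 1L))
  acc_grad(genv, sprintf("%s.head.b", side), sum(gpred))
  gx <- conv_bw_x(gpred, par[[sprintf("%s.head.W", side)]], 1L,
                  config$channels[1L])
  gskips <- vector("list", d)
  for (l in seq_len(d - 1L)) {
    cc <- fwd$caches[[l]]
    gcat <- block_bw(gx, cc$blk, par, sprintf("%s.dec%d", side, l), genv)
    ggs <- gcat[seq_len(cc$c_l), , drop = FALSE]
    gg <- gcat[cc$c_l + seq_len(cc$c_l), , drop = FALSE]
    if (config$attention) {
      agb <- ag_bw(ggs, cc$ag, par, sprintf("%s.ag%d", side, l), genv)
      gskips[[l]] <- agb$gu
      gg <- gg + agb$gg
    } else gskips[[l]] <- ggs
    gzup <- gg * act_grad(cc$zup, config$activation)
    acc_grad(genv, sprintf("%s.up%d.W", side, l), conv_bw_w(gzup, cc$u2, k))
    acc_grad(genv, sprintf("%s.up%d.b", side, l), rowSums(gzup))
    gu2 <- conv_bw_x(gzup, par[[sprintf("%s.up%d.W", side, l)]], k,
                     config$channels[l + 1L])
    gx <- upsample_bw(gu2)
  }
  gskips[[d]] <- gx
  gskips
}

# ---- full model -------------------------------------------------------

# Forward pass for one window: returns both predictions and every cache
# needed by model_backward.
model_forward <- function(par, x, config, with_cache = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  check_input_length(ncol(x), config)
  enc_m <- enc_forward_side(par, "m", x, config)
  # fetal encoder: optionally descend through the fused maps
  d <- config$depth
  if (config$fuse_feedforward) {
    # interleave fusion with the descent
    feats_f <- vector("list", d); caches_f <- vector("list", d)
    pools_f <- vector("list", d - 1L); fused <- vector("list", d)
    xi <- x
    for (l in seq_len(d)) {
      blk <- block_fw(xi, par, sprintf("f.enc%d", l), config$kernel_fetal,
                      config$block_type, config$recurrence_T,
                      config$activation)
      feats_f[[l]] <- blk$out; caches_f[[l]] <- blk$cache
      fused[[l]] <- if (l %in% config$fusion_levels)
        tanh(blk$out - enc_m$feats[[l]]) else blk$out
      if (l < d) {
        mp <- maxpool_fw(fused[[l]])
        xi <- mp$out; pools_f[[l]] <- mp$first
      }
    }
    enc_f <- list(feats = feats_f, caches = caches_f, pools = pools_f)
  } else {
    enc_f <- enc_forward_side(par, "f", x, config)
    fused <- enc_f$feats
    for (l in config$fusion_levels)
      fused[[l]] <- tanh(enc_f$feats[[l]] - enc_m$feats[[l]])
  }
  dec_m <- dec_forward_side(par, "m", enc_m$feats, config)
  dec_f <- dec_forward_side(par, "f", fused, config)
  out <- list(fecg = as.numeric(dec_f$pred), mecg = as.numeric(dec_m$pred))
  if (with_cache)
    out$cache <- list(x = x, enc_m = enc_m, enc_f = enc_f, fused = fused,
                      dec_m = dec_m, dec_f = dec_f)
  out
}

# Backward pass: gf/gm are gradients of the loss w.r.t. the two predicted
# windows (numeric vectors). Gradients accumulate into genv.
model_backward <- function(par, cache, gf, gm, config, genv) {
  d <- config$depth
  gsk_f <- dec_backward_side(matrix(gf, nrow = 1L), cache$dec_f, par, "f",
                             config, genv)
  gsk_m <- dec_backward_side(matrix(gm, nrow = 1L), cache$dec_m, par, "m",
                             config, genv)
  gem_extra <- vector("list", d)   # fusion gradients into the maternal encoder

  # fetal encoder (top level down), folding in fusion backward per level
  gchain <- NULL
  for (l in rev(seq_len(d))) {
    gfuse <- gsk_f[[l]]
    if (config$fuse_feedforward && l < d)
      gfuse <- gfuse + maxpool_bw(gchain, cache$enc_f$pools[[l]])
    if (l %in% config$fusion_levels) {
      dt <- gfuse * (1 - cache$fused[[l]]^2)
      ge <- dt
      gem_extra[[l]] <- -dt
    } else ge <- gfuse
    if (!config$fuse_feedforward && l < d)
      ge <- ge + maxpool_bw(gchain, cache$enc_f$pools[[l]])
    gchain <- block_bw(ge, cache$enc_f$caches[[l]], par,
                       sprintf("f.enc%d", l), genv)
  }

  # maternal encoder: decoder skips + fusion contributions
  gchain <- NULL
  for (l in rev(seq_len(d))) {
    ge <- gsk_m[[l]]
    if (!is.null(gem_extra[[l]])) ge <- ge + gem_extra[[l]]
    if (l < d) ge <- ge + maxpool_bw(gchain, cache$enc_m$pools[[l]])
    gchain <- block_bw(ge, cache$enc_m$caches[[l]], par,
                       sprintf("m.enc%d", l), genv)
  }
  invisible(NULL)
}

#' Separate one preprocessed window
#'
#' Runs the full W-shaped forward pass on a single normalised 1024-sample
#' window and returns both reconstructions.
#'
#' @param segment numeric vector (or 1 x L matrix), length divisible by
#'   `2^(depth-1)`.
#' @param model an `r2wnet_model` or `r2wnet` fit.
#' @return list with `fecg` and `mecg` numeric vectors of the input
#'   length.
#' @export
forward_segment <- function(segment, model) {
  out <- model_forward(model$params, segment, model$config,
                       with_cache = FALSE)
  out[c("fecg", "mecg")]
}

#' @export
print.r2wnet_model <- function(x, ...) {
  cat("<r2wnet_model> (untrained)\n")
  print(x$config)
  cat(sprintf("  %s trainable parameters\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
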