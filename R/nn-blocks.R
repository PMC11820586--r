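# Convolution blocks and attention gates with explicit forward/backward
# passes. Parameters live in a flat named list; gradients are accumulated
# into an environment keyed by the same names.

acc_grad <- function(genv, name, g) {
  cur <- genv[[name]]
  genv[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# --- convolution block -------------------------------------------------
# Variants: "forward"  y = act(conv_f(x))
#           "residual" y = x' + act(conv_f(x))
#           "recurrent" unrolled recurrence, no residual
#           "rrc"      recurrence + residual (the default block)
# Recurrence (T steps): y0 = act(z), y_t = act(z + conv_r(y_{t-1})) with
# z = conv_f(x) computed once; conv_r has no separate bias (the block has a
# single bias term, carried by conv_f).

block_fw <- function(x, par, prefix, k, type, T, act) {
  Wf <- par[[paste0(prefix, ".Wf")]]
  bf <- par[[paste0(prefix, ".bf")]]
  cin <- nrow(x); cout <- nrow(Wf)
  z <- conv_fw(x, Wf, bf, k)
  use_rec <- type %in% c("recurrent", "rrc") && T >= 1L
  use_res <- type %in% c("residual", "rrc")
  ys <- list(); pres <- list()
  y <- act_fw(z, act)
  if (use_rec) {
    Wr <- par[[paste0(prefix, ".Wr")]]
    br0 <- numeric(cout)
    ys[[1]] <- y
    for (t in seq_len(T)) {
      pre <- z + conv_fw(y, Wr, br0, k)
      pres[[t]] <- pre
      y <- act_fw(pre, act)
      ys[[t + 1L]] <- y
    }
  }
  if (use_res) {
    if (cin != cout) {
      Wp <- par[[paste0(prefix, ".Wp")]]
      if (is.null(Wp)) stop("channel mismatch (", cin, " -> ", cout,
                            ") requires a projection weight at ", prefix)
      xp <- conv_fw(x, Wp, numeric(cout), 1L)
    } else xp <- x
    out <- xp + y
  } else out <- y
  list(out = out,
       cache = list(x = x, z = z, ys = ys, pres = pres, k = k, type = type,
                    T = T, act = act, use_rec = use_rec, use_res = use_res,
                    cin = cin, cout = cout))
}

block_bw <- function(gout, cache, par, prefix, genv) {
  with(cache, {
    Wf <- par[[paste0(prefix, ".Wf")]]
    gx_res <- NULL
    if (use_res) {
      if (cin != cout) {
        Wp <- par[[paste0(prefix, ".Wp")]]
        acc_grad(genv, paste0(prefix, ".Wp"), conv_bw_w(gout, x, 1L))
        gx_res <- conv_bw_x(gout, Wp, 1L, cin)
      } else gx_res <- gout
    }
    if (use_rec) {
      Wr <- par[[paste0(prefix, ".Wr")]]
      gz <- matrix(0, cout, ncol(gout))
      g <- gout
      for (t in rev(seq_len(T))) {
        dpre <- g * act_grad(pres[[t]], act)
        gz <- gz + dpre
        acc_grad(genv, paste0(prefix, ".Wr"), conv_bw_w(dpre, ys[[t]], k))
        g <- conv_bw_x(dpre, Wr, k, cout)
      }
      gz <- gz + g * act_grad(z, act)
    } else {
      gz <- gout * act_grad(z, act)
    }
    acc_grad(genv, paste0(prefix, ".Wf"), conv_bw_w(gz, x, k))
    acc_grad(genv, paste0(prefix, ".bf"), rowSums(gz))
    gx <- conv_bw_x(gz, Wf, k, cin)
    if (!is.null(gx_res)) gx <- gx + gx_res
    gx
  })
}

block_init <- function(par, prefix, cin, cout, k, type, seedless = TRUE) {
  par[[paste0(prefix, ".Wf")]] <- init_conv(cout, cin, k)
  par[[paste0(prefix, ".bf")]] <- numeric(cout)
  if (type %in% c("recurrent", "rrc"))
    par[[paste0(prefix, ".Wr")]] <- init_conv(cout, cout, k, gain = 0.5)
  if (type %in% c("residual", "rrc") && cin != cout)
    par[[paste0(prefix, ".Wp")]] <- init_conv(cout, cin, 1L)
  par
}

# --- additive attention gate -------------------------------------------
# q = Wphi( relu(Wu u + Wg g + bg) ) + bphi ; alpha = sigmoid(q) in [0,1]
# out = alpha (*) u, alpha broadcast over channels. All projections 1x1.

ag_fw <- function(u, g, par, prefix) {
  Wu <- par[[paste0(prefix, ".Wu")]]
  Wg <- par[[paste0(prefix, ".Wg")]]
  bg <- par[[paste0(prefix, ".bg")]]
  Wphi <- par[[paste0(prefix, ".Wphi")]]
  bphi <- par[[paste0(prefix, ".bphi")]]
  if (ncol(u) != ncol(g))
    stop("attention gate: encoder and gating maps disagree in length (",
         ncol(u), " vs ", ncol(g), ")")
  a <- conv_fw(u, Wu, bg, 1L) + conv_fw(g, Wg, numeric(length(bg)), 1L)
  h <- pmax(a, 0)
  q <- conv_fw(h, Wphi, bphi, 1L)
  alpha <- sigmoid(q)
  am <- matrix(alpha, nrow(u), ncol(u), byrow = TRUE)
  list(out = u * am, alpha = as.numeric(alpha),
       cache = list(u = u, g = g, a = a, h = h, alpha = am))
}

ag_bw <- function(gout, cache, par, prefix, genv) {
  with(cache, {
    Wu <- par[[paste0(prefix, ".Wu")]]
    Wg <- par[[paste0(prefix, ".Wg")]]
    Wphi <- par[[paste0(prefix, ".Wphi")]]
    gu <- gout * alpha
    galpha <- colSums(gout * u)
    gq <- matrix(galpha * alpha[1, ] * (1 - alpha[1, ]), nrow = 1L)
    acc_grad(genv, paste0(prefix, ".Wphi"), conv_bw_w(gq, h, 1L))
    acc_grad(genv, paste0(prefix, ".bphi"), sum(gq))
    gh <- conv_bw_x(gq, Wphi, 1L, nrow(h))
    ga <- gh * (a > 0)
    acc_grad(genv, paste0(prefix, ".Wu"), conv_bw_w(ga, u, 1L))
    acc_grad(genv, paste0(prefix, ".Wg"), conv_bw_w(ga, g, 1L))
    acc_grad(genv, paste0(prefix, ".bg"), rowSums(ga))
    list(gu = gu + conv_bw_x(ga, Wu, 1L, nrow(u)),
         gg = conv_bw_x(ga, Wg, 1L, nrow(g)))
  })
}

ag_init <- function(par, prefix, c_feat, c_gate) {
  c_int <- max(1L, c_feat %/% 2L)   # internal width: half the gated features
  par[[paste0(prefix, ".Wu")]] <- init_conv(c_int, c_feat, 1L)
  par[[paste0(prefix, ".Wg")]] <- init_conv(c_int, c_gate, 1L)
  par[[paste0(prefix, ".bg")]] <- numeric(c_int)
  par[[paste0(prefix, ".Wphi")]] <- init_conv(1L, c_int, 1L, gain = 0.5)
  par[[paste0(prefix, ".bphi")]] <- 0
  par
}

#' Recurrent-residual convolution block
#'
#' Applies one convolution block to a feature map (channels x length
#' matrix). The default `"rrc"` variant computes `z = conv_f(x)`,
#' unrolls the recurrence `y_0 = act(z)`, `y_t = act(z + conv_r(y_{t-1}))`
#' for `t = 1..recurrence_T`, and returns `x' + y_T`, where `x'` is `x`
#' itself when input and output channel counts match and a learned 1x1
#' projection otherwise. With all weights zero and matching channels the
#' block is the identity. Variants drop the recurrence and/or the residual
#' (`"forward"`, `"residual"`, `"recurrent"`).
#'
#' @param x feature map, channels x length numeric matrix (a vector is one
#'   channel).
#' @param weights list with `Wf` (`c_out x c_in*k`), `bf` (`c_out`), and,
#'   as the variant requires, `Wr` (`c_out x c_out*k`) and `Wp`
#'   (`c_out x c_in`).
#' @param recurrence_T number of recurrence steps (>= 0).
#' @param kernel odd kernel size k.
#' @param block_type `"rrc"`, `"forward"`, `"residual"` or `"recurrent"`.
#' @param activation `"relu"` or `"leaky_relu"`.
#' @return feature map of `nrow(weights$Wf)` channels, same length.
#' @export
rrc_block <- function(x, weights, recurrence_T = 2L, kernel = 3L,
                      block_type = "rrc", activation = "relu") {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  par <- list()
  for (nm in names(weights)) par[[paste0("blk.", nm)]] <- weights[[nm]]
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  block_fw(x, par, "blk", as.integer(kernel), block_type,
           as.integer(recurrence_T), activation)$out
}

#' Additive attention gate
#'
#' Gates an encoder feature map `u` with a decoder-side gating signal `g`:
#' `q = Wphi(relu(Wu u + Wg g + bg)) + bphi`, `alpha = sigmoid(q)`, output
#' `alpha * u` with the per-position coefficients `alpha` in `[0, 1]`
#' broadcast over channels. `u` and `g` must share length (upsample `g`
#' first if it is coarser).
#'
#' @param u encoder feature map, channels x length matrix.
#' @param g gating feature map, channels x length matrix (same length).
#' @param params list with `Wu` (`c_int x c_u`), `Wg` (`c_int x c_g`),
#'   `bg` (`c_int`), `Wphi` (`1 x c_int`), `bphi` (scalar).
#' @return list with `out` (gated map, same shape as `u`) and `alpha`
#'   (numeric vector of attention coefficients).
#' @export
attention_gate <- function(u, g, params) {
  if (is.vector(u)) u <- matrix(u, nrow = 1L)
  if (is.vector(g)) g <- matrix(g, nrow = 1L)
  par <- list()
  for (nm in names(params)) par[[paste0("ag.", nm)]] <- params[[nm]]
  r <- ag_fw(u, g, par, "ag")
  list(out = r$out, alpha = r$alpha)
}

#' Cross-branch feature subtraction with tanh
#'
#' The fetal branch isolates fetal features by subtracting the maternal
#' encoder's features and bounding the difference with tanh:
#' `fused = tanh(fetal - maternal)` at each fusion level; other levels pass
#' through unchanged.
#'
#' @param fetal_feats,maternal_feats lists of shape-congruent feature maps
#'   (one per encoder level).
#' @param fusion_levels integer levels at which to fuse (default: all).
#' @return list of per-level feature maps, values in (-1, 1) at fused
#'   levels.
#' @export
fuse_subtract_tanh <- function(fetal_feats, maternal_feats,
                               fusion_levels = seq_along(fetal_feats)) {
  stopifnot(length(fetal_feats) == length(maternal_feats))
  out <- fetal_feats
  for (l in fusion_levels) {
    f <- fetal_feats[[l]]; m <- maternal_feats[[l]]
    if (!all(dim(f) == dim(m)))
      stop("fusion level ", l, ": feature shapes disagree")
    out[[l]] <- tanh(f - m)
  }
  out
}
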