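#' Training configuration
#'
#' Joint supervised training of both branches. The reference configuration
#' (`preset = "reference"`) uses MAE loss, Adam with learning rate 1e-4, batch
#' size 32 and 30 epochs at full width. The `"desk"` preset is a
#' CPU-budget configuration for the scaled-down network
#' (`width_multiplier = 1/8`): Adam 1e-3, batch size 8, 8 epochs.
#'
#' @param loss `"mae"` (default) or `"mse"` — the loss-function ablation
#'   axis.
#' @param learning_rate Adam step size (> 0).
#' @param batch_size windows per optimiser step (>= 1).
#' @param epochs training epochs.
#' @param loss_weights length-2 numeric `(fetal, maternal)` term weights,
#'   non-negative, not both zero.
#' @param val_fraction fraction of *records* held out for validation
#'   (split by record, never by window, to avoid leakage across
#'   overlapping segments).
#' @param clip_norm global gradient-norm clip (guards the non-finite-loss
#'   abort).
#' @param seed integer seed controlling shuffling (weight initialisation is
#'   seeded separately via the model).
#' @param preset `"desk"` or `"reference"`; presets fill the other fields,
#'   explicit arguments still win.
#' @param verbose print one log line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(loss = c("mae", "mse"), learning_rate = NULL,
                         batch_size = NULL, epochs = NULL,
                         loss_weights = c(1, 1), val_fraction = 0.1,
                         clip_norm = 5, seed = 1L,
                         preset = c("desk", "reference"), verbose = FALSE) {
  preset <- match.arg(preset)
  defaults <- if (preset == "reference")
    list(learning_rate = 1e-4, batch_size = 32L, epochs = 30L)
  else list(learning_rate = 1e-3, batch_size = 8L, epochs = 8L)
  if (is.null(learning_rate)) learning_rate <- defaults$learning_rate
  if (is.null(batch_size)) batch_size <- defaults$batch_size
  if (is.null(epochs)) epochs <- defaults$epochs
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (length(loss_weights) != 2L || any(loss_weights < 0) ||
      sum(loss_weights) == 0)
    stop("loss_weights must be two non-negative values, not both zero")
  structure(list(loss = match.arg(loss), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 loss_weights = as.numeric(loss_weights),
                 val_fraction = val_fraction, clip_norm = clip_norm,
                 seed = as.integer(seed), preset = preset,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Joint two-branch reconstruction loss
#'
#' `weights[1] * L(fetal) + weights[2] * L(maternal)` where `L` is the
#' mean absolute error (default) or mean squared error.
#'
#' @param fecg_pred,fecg_true,mecg_pred,mecg_true numeric vectors of one
#'   shared length.
#' @param weights length-2 `(fetal, maternal)` weights.
#' @param loss `"mae"` or `"mse"`.
#' @return scalar loss.
#' @export
joint_loss <- function(fecg_pred, fecg_true, mecg_pred, mecg_true,
                       weights = c(1, 1), loss = c("mae", "mse")) {
  loss <- match.arg(loss)
  n <- length(fecg_true)
  if (length(fecg_pred) != n || length(mecg_pred) != length(mecg_true))
    stop("prediction/target length mismatch")
  term <- function(p, y) if (loss == "mae") mean(abs(p - y)) else
    mean((p - y)^2)
  weights[1] * term(fecg_pred, fecg_true) +
    weights[2] * term(mecg_pred, mecg_true)
}

loss_grad <- function(pred, true, w, loss) {
  n <- length(pred)
  if (loss == "mae") w * sign(pred - true) / n else w * 2 * (pred - true) / n
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = Inf) {
  gn2 <- 0
  for (nm in names(grads)) gn2 <- gn2 + sum(grads[[nm]]^2)
  gn <- sqrt(gn2)
  scale <- if (is.finite(clip_norm) && gn > clip_norm) clip_norm / gn else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# ---- dataset assembly -------------------------------------------------

# Turn records into training triples (input window, fetal target, maternal
# target), all in the mixture's normalised units.
build_training_windows <- function(records) {
  xs <- list(); yf <- list(); ym <- list(); rec_id <- integer()
  for (i in seq_along(records)) {
    pp <- preprocess_record(records[[i]])
    if (is.null(pp$target_fetal) || is.null(pp$target_maternal))
      stop("training records must carry fetal_truth and maternal_truth ",
           "channels (record ", i, ")")
    ns <- length(pp$input$segments)
    xs <- c(xs, pp$input$segments)
    yf <- c(yf, pp$target_fetal)
    ym <- c(ym, pp$target_maternal)
    rec_id <- c(rec_id, rep(i, ns))
  }
  list(x = xs, yf = yf, ym = ym, rec_id = rec_id)
}

eval_loss_on <- function(par, config, data, idx, tc) {
  if (!length(idx)) return(NA_real_)
  tot <- 0
  for (i in idx) {
    out <- model_forward(par, data$x[[i]], config, with_cache = FALSE)
    tot <- tot + joint_loss(out$fecg, data$yf[[i]], out$mecg, data$ym[[i]],
                            tc$loss_weights, tc$loss)
  }
  tot / length(idx)
}

#' Train a W-shaped separator on synthetic records
#'
#' Joint training of both branches: the fetal branch is supervised by the
#' clean fetal component and the maternal branch by the clean maternal
#' component, both expressed in the mixture window's normalised units.
#' Records are split into training and validation *by record*; the
#' parameters of the best validation epoch are kept. Deterministic given
#' the model seed and `config$seed`.
#'
#' @param model an `r2wnet_model` (see [r2wnet_model()]).
#' @param records list of [ecg_record()] objects with both truth channels,
#'   or a manifest path accepted by [load_dataset()].
#' @param config a [train_config()].
#' @return list with `model` (an `r2wnet_model` carrying the trained
#'   parameters) and `history` (class `train_history`: per-epoch training
#'   and validation loss, best epoch, seconds per epoch).
#' @export
train_r2wnet <- function(model, records, config = train_config()) {
  stopifnot(inherits(model, "r2wnet_model"), inherits(config, "train_config"))
  if (is.character(records)) records <- load_dataset(records)
  if (!length(records)) stop("empty training set")
  data <- build_training_windows(records)
  nrec <- length(records)
  set.seed(config$seed)
  n_val <- if (nrec >= 2L) max(1L, round(config$val_fraction * nrec)) else 0L
  val_rec <- if (n_val) sort(sample.int(nrec, n_val)) else integer()
  tr_idx <- which(!(data$rec_id %in% val_rec))
  va_idx <- which(data$rec_id %in% val_rec)
  if (!length(tr_idx)) stop("no training windows left after the split")

  par <- model$params
  state <- adam_init(par)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), seconds = numeric())
  best <- list(loss = Inf, par = par, epoch = 0L)
  nb <- ceiling(length(tr_idx) / config$batch_size)

  for (ep in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample(tr_idx)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      ids <- ord[((b - 1L) * config$batch_size + 1L):
                   min(b * config$batch_size, length(ord))]
      genv <- new.env(parent = emptyenv())
      bl <- 0
      for (i in ids) {
        out <- model_forward(par, data$x[[i]], config = model$config)
        l <- joint_loss(out$fecg, data$yf[[i]], out$mecg, data$ym[[i]],
                        config$loss_weights, config$loss)
        if (!is.finite(l))
          stop("non-finite loss in epoch ", ep, ", batch ", b,
               " (window ", i, "); lower the learning rate")
        bl <- bl + l
        gf <- loss_grad(out$fecg, data$yf[[i]], config$loss_weights[1],
                        config$loss)
        gm <- loss_grad(out$mecg, data$ym[[i]], config$loss_weights[2],
                        config$loss)
        model_backward(par, out$cache, gf, gm, model$config, genv)
      }
      grads <- as.list(genv)
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(ids)
      upd <- adam_step(par, grads, state, config$learning_rate,
                       clip_norm = config$clip_norm)
      par <- upd$par; state <- upd$state
      ep_loss <- ep_loss + bl
    }
    ep_loss <- ep_loss / length(tr_idx)
    vl <- eval_loss_on(par, model$config, data, va_idx, config)
    secs <- proc.time()[["elapsed"]] - t0
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl, seconds = secs))
    score <- if (is.na(vl)) ep_loss else vl
    if (score < best$loss) best <- list(loss = score, par = par, epoch = ep)
    if (config$verbose)
      message(sprintf("epoch %d/%d  train %.5f  val %s  (%.1fs)", ep,
                      config$epochs, ep_loss,
                      ifelse(is.na(vl), "-", sprintf("%.5f", vl)), secs))
  }
  trained <- model
  trained$params <- best$par
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "val_records") <- val_rec
  class(hist) <- c("train_history", "data.frame")
  list(model = trained, history = hist)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epoch(s), best epoch %d\n", nrow(x),
              attr(x, "best_epoch")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Ablation harness
#'
#' Re-trains the desk-scale model along one design axis with a shared seed
#' and identical record split, and evaluates each variant on held-out
#' records. Axes: `loss` (mae vs mse), `depth` (4/5/6 encoder levels),
#' `block_type` (forward / residual / recurrent / rrc). No ordering among
#' variants is asserted by the harness — it only makes them comparable.
#'
#' @param records training records (list or manifest path).
#' @param axis `"loss"`, `"depth"` or `"block_type"`.
#' @param values values along the axis; defaults to the full supported
#'   set.
#' @param eval_records held-out records for metric rows (default: the
#'   validation records of the split).
#' @param base_config an [r2wnet_config()] used as the template
#'   (desk-scale by default).
#' @param train_cfg a [train_config()] template.
#' @param seed shared seed for every variant.
#' @return data.frame with one row per value: final losses, parameter
#'   count, and (when evaluation records exist) MSE/MAE/SNR and SE/PPV/F1.
#' @export
ablate <- function(records, axis = c("loss", "depth", "block_type"),
                   values = NULL, eval_records = NULL,
                   base_config = r2wnet_config(width_multiplier = 1 / 8),
                   train_cfg = train_config(), seed = 1L) {
  axis <- match.arg(axis)
  supported <- list(loss = c("mae", "mse"), depth = c(4L, 5L, 6L),
                    block_type = c("forward", "residual", "recurrent", "rrc"))
  if (is.null(values)) values <- supported[[axis]]
  if (!all(values %in% supported[[axis]]))
    stop("unsupported ", axis, " value(s): ",
         paste(setdiff(values, supported[[axis]]), collapse = ", "))
  if (is.character(records)) records <- load_dataset(records)
  rows <- list()
  for (v in values) {
    cfg <- base_config
    tc <- train_cfg
    tc$seed <- as.integer(seed)
    if (axis == "loss") tc$loss <- v
    if (axis == "block_type") cfg$block_type <- v
    if (axis == "depth") {
      d <- as.integer(v)
      base_w <- cfg$channels[1]
      cfg <- r2wnet_config(depth = d,
                           channels = base_w * 2L^(seq_len(d) - 1L),
                           kernel_maternal = cfg$kernel_maternal,
                           kernel_fetal = cfg$kernel_fetal,
                           recurrence_T = cfg$recurrence_T,
                           fusion_levels = NULL,
                           fuse_feedforward = cfg$fuse_feedforward,
                           activation = cfg$activation,
                           block_type = cfg$block_type,
                           attention = cfg$attention)
    }
    fit <- train_r2wnet(r2wnet_model(cfg, seed = seed), records, tc)
    h <- fit$history
    row <- data.frame(axis = axis, value = as.character(v),
                      n_params = count_parameters(fit$model),
                      final_train_loss = h$train_loss[nrow(h)],
                      final_val_loss = h$val_loss[nrow(h)],
                      stringsAsFactors = FALSE)
    ev <- eval_records
    if (is.null(ev)) {
      vr <- attr(h, "val_records")
      if (length(vr)) ev <- records[vr]
    }
    if (!is.null(ev) && length(ev)) {
      reps <- lapply(ev, evaluate_record, model = fit$model)
      agg <- aggregate_reports(reps)
      for (nm in c("mse", "mae", "snr_db", "se_pct", "ppv_pct", "f1_pct"))
        row[[nm]] <- agg[[nm]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
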