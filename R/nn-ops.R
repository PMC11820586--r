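# Elementary differentiable ops on channels-x-length feature maps.
# Every *_fw returns what the matching *_bw needs; gradients are exact.

conv_fw <- function(x, W, b, k) .conv1d_fw(x, W, b, k)
conv_bw_x <- function(gout, W, k, cin) .conv1d_bw_x(gout, W, k, cin)
conv_bw_w <- function(gout, x, k) .conv1d_bw_w(gout, x, k)

act_fw <- function(z, type) {
  if (type == "relu") pmax(z, 0)
  else z * (z > 0) + 0.01 * z * (z <= 0)   # leaky_relu, slope 0.01
}

act_grad <- function(z, type) {
  if (type == "relu") (z > 0) * 1
  else (z > 0) + 0.01 * (z <= 0)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Max pooling, factor 2, ties broken toward the earlier sample.
maxpool_fw <- function(x) {
  L <- ncol(x)
  stopifnot(L %% 2L == 0L)
  a <- x[, seq(1L, L, 2L), drop = FALSE]
  b <- x[, seq(2L, L, 2L), drop = FALSE]
  first <- a >= b
  list(out = a * first + b * !first, first = first)
}

maxpool_bw <- function(gout, first) {
  L2 <- ncol(gout)
  g <- matrix(0, nrow(gout), 2L * L2)
  g[, seq(1L, 2L * L2, 2L)] <- gout * first
  g[, seq(2L, 2L * L2, 2L)] <- gout * !first
  g
}

# Linear-interpolation upsampling, factor 2: odd output samples copy the
# input, even samples average neighbours (last one repeats the endpoint).
upsample_fw <- function(x) {
  L <- ncol(x)
  out <- matrix(0, nrow(x), 2L * L)
  out[, seq(1L, 2L * L, 2L)] <- x
  if (L > 1L)
    out[, seq(2L, 2L * L - 2L, 2L)] <-
      0.5 * (x[, -L, drop = FALSE] + x[, -1L, drop = FALSE])
  out[, 2L * L] <- x[, L]
  out
}

upsample_bw <- function(gout) {
  L <- ncol(gout) %/% 2L
  g <- gout[, seq(1L, 2L * L, 2L), drop = FALSE]
  if (L > 1L) {
    ge <- gout[, seq(2L, 2L * L - 2L, 2L), drop = FALSE]
    g[, -L] <- g[, -L, drop = FALSE] + 0.5 * ge
    g[, -1L] <- g[, -1L, drop = FALSE] + 0.5 * ge
  }
  g[, L] <- g[, L] + gout[, 2L * L]
  g
}

# He-style initialiser for a conv weight c_out x (c_in * k).
init_conv <- function(cout, cin, k, gain = 1) {
  matrix(rnorm(cout * cin * k, sd = gain * sqrt(2 / (cin * k))),
         nrow = cout)
}
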