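# Independent scalar-loop oracles used to cross-check the vectorised /
# compiled implementations on tiny inputs.

# Plain scalar 1D convolution: x is c_in x L, W is c_out x (c_in*k)
# (tap-major layout: column (j-1)*c_in + ci), zero padding, stride 1.
oracle_conv1d <- function(x, W, b, k) {
  cin <- nrow(x); L <- ncol(x); cout <- nrow(W)
  pad <- (k - 1) / 2
  out <- matrix(0, cout, L)
  for (co in seq_len(cout)) for (t in seq_len(L)) {
    acc <- b[co]
    for (j in seq_len(k)) {
      src <- t + (j - 1) - pad
      if (src >= 1 && src <= L)
        for (ci in seq_len(cin))
          acc <- acc + W[co, (j - 1) * cin + ci] * x[ci, src]
    }
    out[co, t] <- acc
  }
  out
}

# Step-by-step unrolled recurrent-residual block: z = conv_f(x);
# y0 = act(z); y_t = act(z + conv_r(y_{t-1})); out = x' + y_T.
oracle_rrc <- function(x, weights, T, k, act = function(z) pmax(z, 0)) {
  cout <- nrow(weights$Wf)
  z <- oracle_conv1d(x, weights$Wf, weights$bf, k)
  y <- act(z)
  for (t in seq_len(T))
    y <- act(z + oracle_conv1d(y, weights$Wr, numeric(cout), k))
  xp <- if (nrow(x) == cout) x else
    oracle_conv1d(x, weights$Wp, numeric(cout), 1)
  xp + y
}

# Element-by-element additive attention gate.
oracle_attention_gate <- function(u, g, p) {
  cint <- nrow(p$Wu); L <- ncol(u)
  out <- u * 0
  alpha <- numeric(L)
  for (t in seq_len(L)) {
    h <- numeric(cint)
    for (ci in seq_len(cint)) {
      s <- p$bg[ci]
      for (cu in seq_len(nrow(u))) s <- s + p$Wu[ci, cu] * u[cu, t]
      for (cg in seq_len(nrow(g))) s <- s + p$Wg[ci, cg] * g[cg, t]
      h[ci] <- max(s, 0)
    }
    q <- p$bphi
    for (ci in seq_len(cint)) q <- q + p$Wphi[1, ci] * h[ci]
    alpha[t] <- 1 / (1 + exp(-q))
    out[, t] <- alpha[t] * u[, t]
  }
  list(out = out, alpha = alpha)
}

# Exhaustive maximum-cardinality one-to-one matching under a tolerance
# (recursive branch over each true peak's candidate predictions).
oracle_match_count <- function(predicted, truth, tol) {
  np <- length(predicted)
  rec <- function(ti, used) {
    if (ti > length(truth)) return(0L)
    best <- rec(ti + 1L, used)     # leave this truth unmatched
    for (p in seq_len(np)) {
      if (!used[p] && abs(predicted[p] - truth[ti]) <= tol) {
        used2 <- used; used2[p] <- TRUE
        best <- max(best, 1L + rec(ti + 1L, used2))
      }
    }
    best
  }
  rec(1L, logical(np))
}

# Random parameter sets for the block / gate oracles.
random_block_weights <- function(cin, cout, k) {
  list(Wf = matrix(rnorm(cout * cin * k, sd = 0.5), cout),
       bf = rnorm(cout, sd = 0.2),
       Wr = matrix(rnorm(cout * cout * k, sd = 0.5), cout),
       Wp = matrix(rnorm(cout * cin, sd = 0.5), cout))
}

random_ag_params <- function(cu, cg, cint) {
  list(Wu = matrix(rnorm(cint * cu), cint), Wg = matrix(rnorm(cint * cg), cint),
       bg = rnorm(cint), Wphi = matrix(rnorm(cint), 1), bphi = rnorm(1))
}

# A physiological true-peak train: spacing always above `min_gap` samples.
random_peak_train <- function(n, min_gap, spread) {
  cumsum(min_gap + sample.int(spread, n, replace = TRUE))
}
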