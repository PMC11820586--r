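test_that("a zero-weight RRC block with matching channels is the identity", {
  set.seed(1)
  x <- matrix(rnorm(3 * 16), nrow = 3)
  w <- list(Wf = matrix(0, 3, 9), bf = numeric(3), Wr = matrix(0, 3, 9))
  expect_equal(rrc_block(x, w, recurrence_T = 2, kernel = 3), x)
})

test_that("T = 0 reduces the block to a plain residual conv block", {
  set.seed(2)
  x <- matrix(rnorm(2 * 12), nrow = 2)
  w <- random_block_weights(2, 2, 3)
  got <- rrc_block(x, w, recurrence_T = 0, kernel = 3)
  want <- x + pmax(oracle_conv1d(x, w$Wf, w$bf, 3), 0)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("the unrolled block matches a scalar-loop computation", {
  set.seed(3)
  for (case in 1:6) {
    cin <- sample(1:3, 1); cout <- sample(1:4, 1)
    k <- sample(c(3, 5), 1); T <- sample(0:2, 1); L <- sample(4:16, 1)
    x <- matrix(rnorm(cin * L), nrow = cin)
    w <- random_block_weights(cin, cout, k)
    got <- rrc_block(x, w, recurrence_T = T, kernel = k,
                     activation = "relu")
    want <- oracle_rrc(x, w, T, k)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("attention coefficients live in [0,1] and saturate correctly", {
  set.seed(4)
  u <- matrix(rnorm(4 * 10), nrow = 4)
  g <- matrix(rnorm(4 * 10), nrow = 4)
  p <- random_ag_params(4, 4, 2)
  # gate driven shut: output ~ 0
  p_shut <- p; p_shut$bphi <- -50
  shut <- attention_gate(u, g, p_shut)
  expect_lt(max(abs(shut$out)), 1e-12)
  # gate driven open: output ~ u
  p_open <- p; p_open$bphi <- 50
  open <- attention_gate(u, g, p_open)
  expect_equal(open$out, u, tolerance = 1e-9)
  got <- attention_gate(u, g, p)
  expect_true(all(got$alpha >= 0 & got$alpha <= 1))
  expect_error(attention_gate(u, matrix(rnorm(4 * 5), 4), p), "length")
})

test_that("the attention gate matches an element-by-element evaluation", {
  set.seed(5)
  for (case in 1:6) {
    cu <- sample(1:4, 1); L <- sample(4:16, 1)
    u <- matrix(rnorm(cu * L), nrow = cu)
    g <- matrix(rnorm(cu * L), nrow = cu)
    p <- random_ag_params(cu, cu, max(1, cu %/% 2))
    got <- attention_gate(u, g, p)
    want <- oracle_attention_gate(u, g, p)
    expect_equal(got$out, want$out, tolerance = 1e-6)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-6)
  }
})

test_that("feature fusion is the bounded difference of branch features", {
  set.seed(6)
  f <- lapply(c(8, 4), function(L) matrix(rnorm(2 * L), nrow = 2))
  m <- lapply(c(8, 4), function(L) matrix(rnorm(2 * L, sd = 4), nrow = 2))
  fused <- fuse_subtract_tanh(f, m)
  expect_equal(fused[[1]], tanh(f[[1]] - m[[1]]))
  expect_true(all(abs(unlist(fused)) < 1))
  # identical features cancel exactly; zero maternal passes tanh(fetal)
  expect_true(all(fuse_subtract_tanh(f, f)[[1]] == 0))
  z <- lapply(f, function(x) x * 0)
  expect_equal(fuse_subtract_tanh(f, z)[[2]], tanh(f[[2]]))
  # partial fusion leaves other levels untouched
  part <- fuse_subtract_tanh(f, m, fusion_levels = 2)
  expect_identical(part[[1]], f[[1]])
  expect_error(fuse_subtract_tanh(f, rev(m)), "shapes")
})

test_that("encoder produces the documented channel/length pyramid", {
  cfg <- r2wnet_config(width_multiplier = 1 / 8)
  expect_equal(cfg$channels, c(8L, 16L, 32L, 64L, 128L))
  m <- r2wnet_model(cfg, seed = 1)
  feats <- encoder_forward(rnorm(1024), "fetal", m)
  expect_equal(vapply(feats, ncol, integer(1)), c(1024L, 512L, 256L, 128L, 64L))
  expect_equal(vapply(feats, nrow, integer(1)), cfg$channels)
  # determinism
  same_in <- rnorm(1024)
  a <- encoder_forward(same_in, "maternal", m)
  b <- encoder_forward(same_in, "maternal", m)
  expect_identical(a, b)
})

test_that("forward pass keeps shape, is deterministic, fully convolutional", {
  cfg <- r2wnet_config(width_multiplier = 1 / 16)
  m <- r2wnet_model(cfg, seed = 3)
  x <- rnorm(1024)
  o1 <- forward_segment(x, m)
  o2 <- forward_segment(x, m)
  expect_length(o1$fecg, 1024)
  expect_length(o1$mecg, 1024)
  expect_identical(o1, o2)
  # doubling the input length doubles the output length
  o3 <- forward_segment(rnorm(2048), m)
  expect_length(o3$fecg, 2048)
  expect_error(forward_segment(rnorm(1000), m), "divisible")
})

test_that("parameter counts scale with width and depth", {
  n_full <- count_parameters(r2wnet_model(r2wnet_config(), seed = 1))
  n_half <- count_parameters(
    r2wnet_model(r2wnet_config(width_multiplier = 1 / 2), seed = 1))
  expect_lt(n_half, n_full)
  cfg4 <- r2wnet_config(depth = 4, channels = c(64L, 128L, 256L, 512L))
  expect_lt(count_parameters(r2wnet_model(cfg4, seed = 1)), n_full)
  expect_equal(count_parameters(r2wnet_model(r2wnet_config(), seed = 2)),
               n_full)
})

test_that("training gradients are exact and reach every parameter", {
  set.seed(11)
  cfg <- r2wnet_config(depth = 3, channels = c(2L, 3L, 5L),
                       input_length = 16)
  m <- r2wnet_model(cfg, seed = 7)
  x <- rnorm(16); yf <- rnorm(16); ym <- rnorm(16)
  out <- r2wnet:::model_forward(m$params, x, cfg)
  genv <- new.env(parent = emptyenv())
  r2wnet:::model_backward(m$params, out$cache, 2 * (out$fecg - yf) / 16,
                          2 * (out$mecg - ym) / 16, cfg, genv)
  g <- as.list(genv)
  expect_setequal(names(g), names(m$params))
  expect_true(all(vapply(g, function(v) any(v != 0), logical(1))))
  lossfn <- function(par) {
    o <- r2wnet:::model_forward(par, x, cfg, with_cache = FALSE)
    mean((o$fecg - yf)^2) + mean((o$mecg - ym)^2)
  }
  eps <- 1e-5
  for (nm in sample(names(m$params), 8)) {
    i <- sample(length(m$params[[nm]]), 1)
    pp <- m$params
    pp[[nm]][i] <- pp[[nm]][i] + eps
    up <- lossfn(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    dn <- lossfn(pp)
    fd <- (up - dn) / (2 * eps)
    if (abs(fd) > 1e-4 || abs(g[[nm]][i]) > 1e-4)
      expect_close(g[[nm]][i], fd, 1e-4 * max(1, abs(fd)))
  }
})

test_that("checkpoints round-trip the architecture and weights", {
  dir <- withr::local_tempdir()
  cfg <- r2wnet_config(width_multiplier = 1 / 16, fusion_levels = c(3, 5))
  m <- r2wnet_model(cfg, seed = 2)
  save_r2wnet(m, file.path(dir, "ckpt"))
  m2 <- load_r2wnet(file.path(dir, "ckpt"))
  expect_equal(m2$config$fusion_levels, c(3L, 5L))
  x <- rnorm(1024)
  expect_identical(forward_segment(x, m), forward_segment(x, m2))
  # architecture mismatch is detected
  other <- r2wnet_model(r2wnet_config(width_multiplier = 1 / 8), seed = 1)
  saveRDS(other$params, file.path(dir, "ckpt", "weights.rds"))
  expect_error(load_r2wnet(file.path(dir, "ckpt")), "do not match")
})
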