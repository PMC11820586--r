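test_that("record construction enforces structural invariants", {
  r <- ecg_record(matrix(rnorm(500), ncol = 2), fs = 250,
                  channel_roles = c("abdominal_mixture", "fetal_truth"),
                  rpeaks_fetal = c(10L, 60L, 200L))
  expect_s3_class(r, "ecg_record")
  expect_equal(record_length(r), 250)
  expect_equal(record_duration(r), 1)
  expect_error(ecg_record(rnorm(100), fs = -1), "fs")
  expect_error(ecg_record(rnorm(100), fs = 250, rpeaks_fetal = c(5, 5)),
               "strictly increasing")
  expect_error(ecg_record(rnorm(100), fs = 250, rpeaks_fetal = c(5, 101)),
               "out of range")
  expect_error(ecg_record(matrix(1, 10, 2), fs = 10,
                          channel_roles = "only_one"),
               "channel_roles")
})

test_that("slicing keeps only in-window samples and re-bases annotations", {
  # peaks at samples 100 and 600 (0-based), fs 250; slice [1 s, 3 s)
  # keeps only the second peak, re-based to 350 (0-based)
  x <- rnorm(1000)
  r <- ecg_record(x, fs = 250, rpeaks_fetal = c(101L, 601L))
  s <- slice_record(r, 1, 3)
  expect_equal(record_length(s), 500)
  expect_equal(s$rpeaks_fetal, 351L)
  # identity slice
  full <- slice_record(r, 0, record_duration(r))
  expect_equal(full$signals, r$signals)
  expect_equal(full$rpeaks_fetal, r$rpeaks_fetal)
  expect_error(slice_record(r, 3, 1), "start_s")
  expect_error(slice_record(r, 0, 10), "start_s")
})

test_that("slicing composes: [a,b) then [c,d) equals [a+c, a+d)", {
  r <- quick_record(20, seed = 11)
  s1 <- slice_record(slice_record(r, 2, 16), 3, 9)
  s2 <- slice_record(r, 5, 11)
  expect_equal(s1$signals, s2$signals)
  expect_equal(s1$rpeaks_fetal, s2$rpeaks_fetal)
  expect_equal(s1$rpeaks_maternal, s2$rpeaks_maternal)
})

test_that("csv round trip preserves samples, fs, roles and annotations", {
  dir <- withr::local_tempdir()
  r <- quick_record(10, seed = 3)
  base <- write_record(r, file.path(dir, "rec1"), format = "csv")
  r2 <- read_record_csv(base)
  expect_equal(r2$signals, r$signals, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(r2$fs, r$fs)
  expect_equal(r2$channel_roles, r$channel_roles)
  expect_equal(r2$rpeaks_fetal, r$rpeaks_fetal)
  expect_equal(r2$rpeaks_maternal, r$rpeaks_maternal)
  # a constant-zero record writes plain zero rows
  z <- ecg_record(numeric(1000), fs = 250)
  write_record(z, file.path(dir, "zeros"), format = "csv")
  tab <- read.csv(file.path(dir, "zeros.csv"))
  expect_equal(nrow(tab), 1000)
  expect_true(all(tab[[1]] == 0))
})

test_that("wfdb round trip reproduces samples and annotations", {
  dir <- withr::local_tempdir()
  r <- quick_record(5, seed = 4)
  base <- write_record(r, file.path(dir, "w1"), format = "wfdb")
  r2 <- read_wfdb_record(base)
  # format 16 quantises at 0.5/gain; gain is auto-scaled per channel
  amax <- apply(abs(r$signals), 2, max)
  expect_true(all(abs(r2$signals - r$signals) <=
                    matrix(amax / 64000 + 1e-12, nrow(r$signals),
                           ncol(r$signals), byrow = TRUE)))
  expect_equal(r2$fs, r$fs)
  expect_equal(r2$rpeaks_fetal, r$rpeaks_fetal)
  # values already on the ADC grid survive exactly
  rq <- r2
  base2 <- write_record(rq, file.path(dir, "w2"), format = "wfdb")
  r3 <- read_wfdb_record(base2)
  expect_equal(r3$signals, rq$signals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(write_record(r, file.path(dir, "x"), format = "edf"))
})

test_that("header/signal inconsistencies are reported as format errors", {
  dir <- withr::local_tempdir()
  r <- ecg_record(matrix(rnorm(400 * 3), ncol = 3), fs = 250,
                  channel_roles = rep("abdominal_mixture", 3))
  base <- write_record(r, file.path(dir, "bad"), format = "wfdb")
  # truncate the signal file so it holds fewer samples than declared
  datf <- paste0(base, ".dat")
  sz <- file.info(datf)$size
  raw <- readBin(datf, "raw", sz)
  writeBin(raw[seq_len(sz - 300)], datf)
  expect_error(read_wfdb_record(base), "shorter")
  expect_error(read_wfdb_record(file.path(dir, "missing")), "header")
})

test_that("binary MIT annotation streams decode to beat sample indices", {
  dir <- withr::local_tempdir()
  # hand-assembled stream: NORMAL(code 1) at +250, NORMAL at +300,
  # then SKIP of 1000 and NORMAL at +50, then EOF
  word <- function(code, delta) {
    as.raw(c(bitwAnd(delta, 255L),
             bitwOr(bitwShiftL(code, 2), bitwShiftR(delta, 8))))
  }
  skip_words <- c(word(59L, 0L),
                  as.raw(c(0L, 0L)),      # high 16 bits of interval
                  as.raw(c(232L, 3L)))    # low 16 bits = 1000
  stream <- c(word(1L, 250L), word(1L, 300L), skip_words, word(1L, 50L),
              as.raw(c(0, 0)))
  f <- file.path(dir, "r.qrs")
  writeBin(stream, f)
  expect_equal(read_wfdb_annotation(f), c(251L, 551L, 1601L))
})
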