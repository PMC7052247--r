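test_that("envelope rectifies, preserves constants, and spreads impulses", {
  rate <- 1000
  const <- lip_trace(rep(-3, 500), rate)
  expect_equal(lip_envelope(const)$samples, rep(3, 500))

  imp <- lip_trace(c(rep(0, 250), 1, rep(0, 249)), rate)
  env <- lip_envelope(imp, window_ms = 140)$samples
  k <- round(0.140 * rate)
  expect_equal(max(env), 1 / k)
  expect_equal(sum(env > 0), k)

  tr <- lip_trace(sin(seq(0, 20, length.out = 500)), rate)
  flipped <- tr
  flipped$samples <- -tr$samples
  expect_equal(lip_envelope(flipped)$samples, lip_envelope(tr)$samples)
  expect_error(lip_envelope(lip_trace(1:5, 10), window_ms = 1000), "longer")
})

test_that("envelope is linear and shift-equivariant on rectified inputs", {
  rate <- 500
  set.seed(5)
  e <- function(x) lip_envelope(lip_trace(x, rate))$samples
  for (rep in 1:10) {
    # superposition on non-negative inputs (where rectification is identity)
    a <- abs(rnorm(400))
    b <- abs(rnorm(400))
    expect_equal(e(a + 2 * b), e(a) + 2 * e(b), tolerance = 1e-12)
    # shift equivariance away from the edges
    sa <- c(numeric(25), a)
    expect_equal(e(sa)[101:350], e(a)[76:325], tolerance = 1e-12)
  }
})

test_that("alignment maps the reference to t = 0 and is shift invariant", {
  rate <- 1000
  mk <- function(peak_at, t0 = 0) {
    tt <- seq(0, 2, by = 1 / rate)
    lip_trace(exp(-(tt + t0 - peak_at)^2 / (2 * 0.05^2)), rate, t0 = t0,
              vocal_onset = peak_at)
  }
  tr <- mk(0.7)
  # symmetric peaks tie after smoothing; the earliest-maximum rule applies
  al <- suppressWarnings(align_traces(list(tr), mode = "maximum"))
  peak_idx <- which.max(al$matrix[1, ])
  expect_lt(abs(al$time[peak_idx]), 0.005)

  # shifting the input start time leaves the aligned copy unchanged
  al2 <- suppressWarnings(align_traces(list(mk(0.75, t0 = 0.05)),
                                       mode = "maximum"))
  common <- intersect(round(al$time, 6), round(al2$time, 6))
  i1 <- match(common, round(al$time, 6))
  i2 <- match(common, round(al2$time, 6))
  expect_equal(al$matrix[1, i1], al2$matrix[1, i2], tolerance = 1e-9)

  # vocal-onset mode uses the stored reference
  al3 <- align_traces(list(tr), mode = "vocal_onset")
  expect_lt(abs(al3$time[which.max(al3$matrix[1, ])]), 0.005)

  flat <- lip_trace(rep(1, 100), 100)
  expect_warning(align_traces(list(flat), mode = "maximum"), "not unique")
})

test_that("oral synthetic traces peak at the vocal onset", {
  peaks <- vapply(1:10, function(s) {
    tr <- simulate_lip_trace("oral", vocal_onset = 1.0, seed = s)
    env <- lip_envelope(tr)$samples
    (which.max(env) - 1) / tr$rate - 1.0
  }, numeric(1))
  expect_lt(abs(mean(peaks)), 0.020)
})

test_that("modality amplitude ratio recovers the planted scale separation", {
  expect_equal(modality_amplitude_ratio(c(1, 2, 3), c(1, 2, 3))$ratio, 1)
  expect_equal(modality_amplitude_ratio(c(2, 4), c(1, 2))$ratio, 2)
  # common gain invariance
  r1 <- modality_amplitude_ratio(c(1, 2, 4), c(0.1, 0.2, 0.3))$ratio
  r2 <- modality_amplitude_ratio(10 * c(1, 2, 4), 10 * c(0.1, 0.2, 0.3))$ratio
  expect_equal(r1, r2)
  expect_warning(out <- modality_amplitude_ratio(c(1, 2), c(0, 0)), "zero")
  expect_identical(out$ratio, Inf)
  expect_identical(out$flag, "infinite")

  oral <- vapply(1:12, function(s)
    lip_peak(simulate_lip_trace("oral", seed = s)), numeric(1))
  silent <- vapply(1:12, function(s)
    lip_peak(simulate_lip_trace("silent", seed = 100 + s)), numeric(1))
  r <- modality_amplitude_ratio(oral, silent)$ratio
  expect_gte(r, 50)
  expect_lte(r, 200)
})

test_that("log ratio stays within 0.3 of the planted separation across seeds", {
  ratios <- vapply(1:20, function(s) {
    oral <- vapply(0:4, function(k)
      lip_peak(simulate_lip_trace("oral", seed = 1000 + 5 * s + k)), numeric(1))
    silent <- vapply(0:4, function(k)
      lip_peak(simulate_lip_trace("silent", seed = 2000 + 5 * s + k)), numeric(1))
    modality_amplitude_ratio(oral, silent)$ratio
  }, numeric(1))
  expect_true(all(abs(log10(ratios) - 2) <= 0.3))
})

test_that("lip traces round-trip through delimited text", {
  tr <- simulate_lip_trace("oral", vocal_onset = 1.0, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lip_trace(tr, path)
  back <- read_lip_trace(path)
  expect_equal(back$modality, "oral")
  expect_equal(back$vocal_onset, 1.0)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
})
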