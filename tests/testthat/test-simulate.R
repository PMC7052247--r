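test_that("design arithmetic matches the study protocol", {
  d <- build_design(30, seed = 1)
  expect_equal(nrow(d), 10800)                       # 30 x 2 x 180
  expect_equal(length(unique(d$ccv)), 72)
  one_block <- dplyr::filter(d, subject == 1, block == "oral")
  expect_equal(nrow(one_block), 180)
  expect_equal(max(one_block$screen), 30)
  expect_equal(sum(one_block$ccv %in% analysis_ccvs()$ccv), 45)
  counts <- table(one_block$ccv)
  expect_true(all(counts[analysis_ccvs()$ccv] == 3))
  expect_setequal(as.integer(counts[setdiff(names(counts), analysis_ccvs()$ccv)]),
                  c(2, 3))
  expect_equal(sum(counts) - 45, 135)
  expect_true(all(d$repetition %in% 1:3))
  # interior retention after edge discard
  expect_equal(sum(d$pos %in% 2:5), 7200)
})

test_that("the design generator is a pure function of its seed", {
  expect_identical(build_design(4, seed = 9), build_design(4, seed = 9))
  expect_false(identical(build_design(4, seed = 9), build_design(4, seed = 10)))
  # global RNG state is untouched
  set.seed(123)
  before <- .Random.seed
  invisible(build_design(2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise simulation returns the calibrated means exactly", {
  cal <- default_calibration()
  cal$ccv_table$tau_sd <- 0
  cal$ccv_table$T_sd <- 0
  cal$couplings[c("delta_sd", "ffd_sd", "fprt_sd", "tft_sd")] <- 0
  d <- build_design(2, seed = 1)
  r <- simulate_timing(d, cal, seed = 2, unfixated_rate = 0)
  oral <- dplyr::filter(r, block == "oral")
  idx <- match(oral$ccv, cal$ccv_table$ccv)
  expect_equal(oral$tau_norm, cal$ccv_table$tau_mean[idx], tolerance = 1e-12)
  expect_equal(oral$T, rep(0.490, nrow(oral)), tolerance = 1e-12)
  expect_equal(oral$delta, 0.30 + 0.30 * oral$tau_norm, tolerance = 1e-12)
  silent <- dplyr::filter(r, block == "silent")
  idx_s <- match(silent$ccv, cal$ccv_table$ccv)
  expect_equal(silent$ffd,
               pmax(cal$couplings["ffd_silent_intercept"] +
                      cal$couplings["ffd_silent_slope"] *
                        cal$ccv_table$tau_mean[idx_s], 40),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulated subgroup means land within sampling error of calibration", {
  d <- build_design(28, seed = 1)
  r <- simulate_timing(d, seed = 1)
  oral <- dplyr::filter(r, block == "oral")
  check <- function(ccvs, target) {
    v <- oral$tau_norm[oral$ccv %in% ccvs]
    sem <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 3 * sem)
  }
  check(fully_voiced_ccvs(), 0.3815)
  check(devoiced_ccvs(), 0.413)
  check(place_subgroups()$forward, 0.373)
  check(place_subgroups()$interchanged, 0.390)
})

test_that("the planted delta-tau' coupling is recovered by regression", {
  d <- build_design(28, seed = 2)
  r <- simulate_timing(d, seed = 3)
  oral <- dplyr::filter(r, block == "oral", ccv %in% analysis_ccvs()$ccv)
  res <- ols_regression(oral, "delta", c("tau_norm", "repetition"))
  slope <- res[res$term == "tau_norm", ]
  expect_lt(abs(slope$estimate - 0.30), 2 * slope$se)
  expect_gt(slope$statistic, 0)
})

test_that("ocular ordering holds on every simulated trial", {
  r <- simulate_timing(build_design(6, seed = 4), seed = 5)
  ok <- with(r, ffd <= fprt & fprt <= tft)
  expect_true(all(ok, na.rm = TRUE))
  # FFD has no repetition trend: slope indistinguishable from zero
  silent <- dplyr::filter(r, block == "silent", ccv %in% analysis_ccvs()$ccv)
  res <- ols_regression(silent, "ffd", "repetition")
  expect_gt(res$p[res$term == "repetition"], 0.01)
})

test_that("fixation realisation round-trips through the gaze pipeline", {
  lay <- screen_layout()
  fx <- realize_fixations(200, 200, 200, lay, target_aoi = 3)
  expect_equal(nrow(fx), 2)  # single target fixation + pass terminator
  m <- compute_measures(assign_fixations(fx, lay), 3)
  expect_equal(c(m$ffd, m$fprt, m$tft), c(200, 200, 200))

  fx2 <- realize_fixations(100, 250, 330, lay, target_aoi = 2)
  m2 <- compute_measures(assign_fixations(fx2, lay), 2)
  expect_equal(c(m2$ffd, m2$fprt, m2$tft), c(100, 250, 330))

  set.seed(55)
  for (i in 1:500) {
    ffd <- runif(1, 50, 400)
    fprt <- ffd + sample(c(0, runif(1, 0, 400)), 1)
    tft <- fprt + sample(c(0, runif(1, 0, 400)), 1)
    target <- sample(1:6, 1)
    fx <- realize_fixations(ffd, fprt, tft, lay, target_aoi = target)
    m <- compute_measures(assign_fixations(fx, lay), target)
    expect_equal(c(m$ffd, m$fprt, m$tft), c(ffd, fprt, tft))
  }
  expect_error(realize_fixations(300, 200, 400, lay), "inconsistent")
})

test_that("whole screens round-trip with interior AOIs intact", {
  lay <- screen_layout()
  set.seed(77)
  for (i in 1:20) {
    ffd <- runif(6, 80, 300)
    fprt <- ffd + runif(6, 0, 300)
    tft <- fprt + runif(6, 0, 300)
    meas <- tibble::tibble(aoi = 1:6, ffd = ffd, fprt = fprt, tft = tft)
    fx <- realize_screen_fixations(meas, lay)
    got <- screen_measures(assign_fixations(fx, lay), lay)
    interior <- discard_edges(got)
    expect_equal(interior$ffd, ffd[2:5])
    expect_equal(interior$fprt, fprt[2:5])
    expect_equal(interior$tft, tft[2:5])
  }
})

test_that("audio synthesis is seeded and validates landmark placement", {
  a1 <- synthesize_ccv_audio(0.3, c(0.35, 0.55), seed = 8)
  a2 <- synthesize_ccv_audio(0.3, c(0.35, 0.55), seed = 8)
  expect_identical(a1$samples, a2$samples)
  expect_error(synthesize_ccv_audio(0.3, c(0.25, 0.55)), "outside")
  expect_error(synthesize_ccv_audio(0.3, c(0.55, 0.35)), "increasing")
})

test_that("calibration is internally consistent and round-trips as text", {
  cal <- default_calibration()
  tab <- cal$ccv_table
  m_fwd <- mean(tab$tau_mean[tab$ccv %in% place_subgroups()$forward])
  m_int <- mean(tab$tau_mean[tab$ccv %in% place_subgroups()$interchanged])
  m_voiced <- mean(tab$tau_mean[tab$ccv %in% fully_voiced_ccvs()])
  expect_lt(m_fwd, m_int)
  expect_equal((m_fwd + m_int) / 2, m_voiced, tolerance = 0.002)
  expect_lt(m_voiced, mean(tab$tau_mean[tab$ccv %in% devoiced_ccvs()]))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$couplings, cal$couplings)
  expect_equal(back$ccv_table$tau_mean, cal$ccv_table$tau_mean)
})
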