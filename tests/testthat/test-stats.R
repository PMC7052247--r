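test_that("OLS matches the normal-equation oracle and basic identities", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  res <- ols_regression(d, "y", "x")
  expect_equal(res$estimate[res$term == "x"], 2, tolerance = 1e-12)
  expect_equal(sum(abs(res$se[res$term == "x"])), 0, tolerance = 1e-10)

  set.seed(42)
  d2 <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40), y = rnorm(40))
  res2 <- ols_regression(d2, "y", c("x1", "x2"))
  X <- cbind(1, d2$x1, d2$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(res2$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_equal(unique(res2$df), 40 - 2 - 1)

  # orthogonal predictor: t near zero
  d3 <- tibble::tibble(x = rep(c(-1, 1), 50), y = rep(c(1, 1), 50) + rnorm(100, 0, 1e-8))
  res3 <- ols_regression(d3, "y", "x")
  expect_lt(abs(res3$statistic[res3$term == "x"]), 1)

  d4 <- tibble::tibble(x = rnorm(10), y = rnorm(10))
  d4$z <- d4$x
  expect_error(ols_regression(d4, "y", c("x", "z")), "singular")
})

test_that("WLS reduces to OLS under equal weights and zero-weights drop points", {
  set.seed(1)
  agg <- tibble::tibble(
    ccv = letters[1:10],
    y_mean = rnorm(10, 100, 10), y_sem = rep(2.5, 10),
    x_mean = rnorm(10, 0.4, 0.02)
  )
  w <- wls_regression(agg, "y", "x")
  o <- ols_regression(tibble::tibble(y = agg$y_mean, x = agg$x_mean), "y", "x")
  expect_equal(w$estimate, o$estimate, tolerance = 1e-12)
  expect_equal(w$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(unique(w$df), 8)

  # a point with infinite SEM has zero weight: the fit ignores it
  agg2 <- dplyr::bind_rows(agg, tibble::tibble(ccv = "k", y_mean = 1e5,
                                               y_sem = Inf, x_mean = 0.4))
  w2 <- wls_regression(agg2, "y", "x")
  expect_equal(w2$estimate, w$estimate, tolerance = 1e-9)
  agg3 <- agg
  agg3$y_sem[1] <- 0
  expect_error(wls_regression(agg3, "y", "x"), "zero SEM")
})

test_that("WLS slope coverage: planted slope within 2 SE in >= 93/100 seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- runif(15, 0.35, 0.45)
    sem <- runif(15, 2, 5)
    y <- 100 + 0.5 * x * 1000 + rnorm(15, 0, sem)
    agg <- tibble::tibble(ccv = as.character(1:15), y_mean = y,
                          y_sem = sem, x_mean = x)
    res <- wls_regression(agg, "y", "x")
    abs(res$estimate[2] - 500) <= 2 * res$se[2]
  }, logical(1))
  expect_gte(sum(hits), 93)
})

test_that("pooled t-test matches hand and textbook-formula oracles", {
  res <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  ident <- two_sample_ttest(rep(2, 5), rep(2, 7))
  expect_equal(ident$statistic, 0)
  expect_error(two_sample_ttest(rep(1, 5), rep(2, 5)), "zero pooled variance")

  set.seed(3)
  for (i in 1:100) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), 0.3)
    res <- two_sample_ttest(a, b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(res$statistic, t_ref, tolerance = 1e-10)
    expect_equal(res$p, 2 * pt(-abs(t_ref), length(a) + length(b) - 2),
                 tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches the sum-of-squares oracle and F = t^2", {
  res_flat <- one_way_anova(list(c(1, 2, 1, 2), c(1.5, 1.5, 1.5, 1.5)))
  expect_lt(res_flat$statistic, 1e-10)

  set.seed(9)
  a <- rnorm(20)
  b <- rnorm(25, 0.5)
  f2 <- one_way_anova(list(a, b))
  t2 <- two_sample_ttest(a, b)
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p, t2$p, tolerance = 1e-10)

  groups <- list(rnorm(10), rnorm(12, 0.4), rnorm(9, -0.2))
  res <- one_way_anova(groups)
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_ref <- (ssb / 2) / (ssw / (length(all_v) - 3))
  expect_equal(res$statistic, f_ref, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df, length(all_v) - 3)
  expect_error(one_way_anova(list(rnorm(5), 1)), "at least 2")
})

test_that("per-CCV aggregates give mean and SEM with a streaming oracle", {
  rec <- tibble::tibble(ccv = c("bda", "bda", "gta", "gta", "gta"),
                        ffd = c(10, 20, 30, 40, 50))
  agg <- aggregate_by_ccv(rec, "ffd")
  expect_equal(agg$ffd_mean[agg$ccv == "bda"], 15)
  expect_equal(agg$ffd_sem[agg$ccv == "bda"], 5)

  set.seed(13)
  rec2 <- tibble::tibble(ccv = sample(analysis_ccvs()$ccv, 600, replace = TRUE),
                         ffd = rnorm(600, 250, 40))
  agg2 <- aggregate_by_ccv(rec2, "ffd")
  expect_equal(nrow(agg2), 15)
  for (cc in agg2$ccv) {
    v <- rec2$ffd[rec2$ccv == cc]
    m1 <- sum(v) / length(v)
    m2 <- sum((v - m1)^2) / (length(v) - 1)
    expect_equal(agg2$ffd_mean[agg2$ccv == cc], m1)
    expect_equal(agg2$ffd_sem[agg2$ccv == cc], sqrt(m2 / length(v)))
  }
  thin <- tibble::tibble(ccv = c("bda", "bda", "gta"), ffd = c(1, 2, 3))
  expect_warning(out <- aggregate_by_ccv(thin, "ffd"), "fewer than 2")
  expect_equal(out$ccv, "bda")
})

test_that("calibrated cross-block FFD slope is positive and significant", {
  hits <- vapply(1:10, function(s) {
    d <- build_design(30, seed = s)
    r <- simulate_timing(d, seed = s + 1000)
    clean <- qc_cascade(r)$records
    agg <- cross_block_aggregates(clean)
    res <- wls_regression(agg, "ffd", "tau_norm")
    slope <- res[res$term == "tau_norm", ]
    reps <- vapply(c("fprt", "tft"), function(v) {
      rr <- ols_regression(dplyr::filter(clean, block == "silent",
                                         ccv %in% analysis_ccvs()$ccv),
                           v, "repetition")
      rr$estimate[rr$term == "repetition"] < 0
    }, logical(1))
    (slope$estimate > 0 && slope$p < 0.01) && all(reps)
  }, logical(1))
  expect_gte(sum(hits), 9)
})
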