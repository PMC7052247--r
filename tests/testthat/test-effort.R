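test_that("devoicing term fires only for CCVs with an unvoiced plosive", {
  expect_equal(devoicing_term(ccv_spec("bda"), 2.5), 0)
  expect_equal(devoicing_term(ccv_spec("gta"), 2.5), 2.5)
  for (cc in fully_voiced_ccvs()) expect_equal(devoicing_term(ccv_spec(cc), 1), 0)
  for (cc in devoiced_ccvs()) expect_equal(devoicing_term(ccv_spec(cc), 1), 1)
  expect_equal(devoicing_term(ccv_spec("gta"), 0), 0)
  expect_error(ccv_spec("xta"), "unknown consonant")
})

test_that("tract effort integrates |A - A_Omega| with the trapezoid rule", {
  geom <- tiny_geometry()
  v0 <- vowel_gesture(0, 0, 0.4)
  f <- area_function(geom, v0, list(), seq(0, 0.4, by = 0.01))
  expect_equal(tract_effort(f), 0)

  # constant offset: integral is offset * L * T
  f_off <- f
  f_off$area <- f$area + 1
  expect_equal(tract_effort(f_off), geom$L * 0.4, tolerance = 1e-12)

  # refinement oracle: analytic midpoint rule at 10x resolution, written
  # from the parametric forms directly (independent of area_function)
  L <- 17.5
  q1 <- 0.9
  q2 <- 0.95
  T_tot <- 0.4
  occ <- occlusion_gesture(0.6 * L, 0.15, sigma = 1, w = 0.12)
  coarse <- area_function(
    default_tract_geometry(n = 36), vowel_gesture(q1, q2, T_tot),
    list(occ), seq(0, T_tot, by = 0.01)
  )
  e_coarse <- tract_effort(coarse)
  dx <- L / 350
  dt <- 0.001
  xm <- seq(dx / 2, L - dx / 2, by = dx)
  tm <- seq(dt / 2, T_tot - dt / 2, by = dt)
  omega <- 1.8 - 0.4 * cos(pi * xm / L)
  diam <- omega + outer(q1 * cos(pi * xm / L) + q2 * cos(2 * pi * xm / L),
                        tm / T_tot)
  a <- (pi / 4) * diam^2
  cm <- outer(exp(-(xm - occ$x_k)^2 / 2),
              ifelse(abs(tm - occ$t_k) < occ$w / 2,
                     0.5 * (1 + cos(2 * pi * (tm - occ$t_k) / occ$w)), 0))
  e_fine <- sum(abs(a * (1 - pmin(cm, 1)) - (pi / 4) * omega^2)) * dx * dt
  expect_lt(abs(e_coarse - e_fine) / e_fine, 0.005)
})

test_that("halving both grid steps changes the tract effort by < 0.1%", {
  v <- function(g) vowel_gesture(g$q1_a, g$q2_a, 0.49)
  occ <- function(g) list(occlusion_gesture(g$L, 0.1, 1, 0.12),
                          occlusion_gesture(0.85 * g$L, 0.3, 1, 0.12))
  g1 <- default_tract_geometry(n = 101)
  g2 <- default_tract_geometry(n = 201)
  e1 <- tract_effort(area_function(g1, v(g1), occ(g1), seq(0, 0.49, by = 0.002)))
  e2 <- tract_effort(area_function(g2, v(g2), occ(g2), seq(0, 0.49, by = 0.001)))
  expect_lt(abs(e2 - e1) / e1, 0.001)
})

test_that("effort table covers the analysis set deterministically", {
  cfg <- fast_effort_config()
  tab <- effort_table(analysis_ccvs(), cfg)
  expect_equal(nrow(tab), 15)
  expect_identical(tab$ccv, analysis_ccvs()$ccv)
  expect_equal(effort_table(analysis_ccvs(), cfg), tab)  # bit-for-bit rerun
  expect_equal(nrow(effort_table(analysis_ccvs()[0, ], cfg)), 0)
  expect_error(ccv_effort(ccv_spec("sfa"), cfg), "unsupported cluster")
  bad <- cfg
  bad$dt_closure <- 1
  expect_error(ccv_effort(ccv_spec("bda"), bad), "smaller than T")
  # laryngeal additivity
  gta <- ccv_effort(ccv_spec("gta"), cfg)
  expect_equal(gta$E_total - gta$E_tract, cfg$E0)
})

test_that("place asymmetry: forward orders cost less than interchanged", {
  tab <- effort_table(analysis_ccvs(), fast_effort_config(E0 = 0))
  e <- function(cc) tab$E_total[tab$ccv == cc]
  expect_lt(e("bda"), e("dba"))
  expect_lt(e("bga"), e("gba"))
  expect_lt(e("dga"), e("gda"))
})

test_that("devoiced group mean exceeds voiced group mean under calibration", {
  cfg <- fast_effort_config(E0 = NULL)
  expect_gt(cfg$E0, 0)
  tab <- effort_table(analysis_ccvs(), cfg)
  m_voiced <- mean(tab$E_total[tab$ccv %in% fully_voiced_ccvs()])
  m_devoiced <- mean(tab$E_total[tab$ccv %in% devoiced_ccvs()])
  expect_gt(m_devoiced, m_voiced)
  cal <- default_calibration()$ccv_table
  ratio_tau <- mean(cal$tau_mean[cal$ccv %in% devoiced_ccvs()]) /
    mean(cal$tau_mean[cal$ccv %in% fully_voiced_ccvs()])
  expect_equal(m_devoiced / m_voiced, ratio_tau, tolerance = 1e-6)
})

test_that("effort is positively associated with tau' across the dt sweep", {
  cal <- default_calibration()$ccv_table
  sweep <- effort_dt_sweep(analysis_ccvs(), fast_effort_config(E0 = NULL))
  rho <- sweep |>
    dplyr::group_by(dt_closure) |>
    dplyr::summarise(r = stats::cor(E_total,
                                    cal$tau_mean[match(ccv, cal$ccv)],
                                    method = "spearman"))
  expect_equal(nrow(rho), 9)  # 100-300 ms in 25-ms steps
  expect_true(all(rho$r > 0))
})
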