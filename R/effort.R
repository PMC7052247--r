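#' Total vocal effort of a CCV
#'
#' The effort functional has a laryngeal and a vocal-tract component:
#' \deqn{E = E_0 + \int_0^T \int_0^L |A(x,t) - A_\Omega(x)|\, dx\, dt}
#' The laryngeal term is a constant `E0 > 0` when any phoneme of the CCV is
#' devoiced (the glottis must be actively abducted to stop the folds) and 0
#' otherwise. The tract term integrates the deformation of the area function
#' away from the neutral shape over the whole utterance (cm^2 s).
#'
#' @name effort
NULL

#' Laryngeal (devoicing) effort term
#'
#' @param ccv A one-row CCV record from [ccv_spec()].
#' @param E0_value Devoicing effort constant (>= 0, cm^2 s).
#' @return `E0_value` if any consonant of the CCV is unvoiced, else 0.
#' @export
devoicing_term <- function(ccv, E0_value) {
  stopifnot(is.numeric(E0_value), E0_value >= 0)
  # voicing flags were validated against the consonant identity at spec time
  c1 <- canonical_consonant(ccv$c1)
  c2 <- canonical_consonant(ccv$c2)
  devoiced <- (c1 %in% .unvoiced_plosives) || (c2 %in% .unvoiced_plosives)
  if (devoiced) E0_value else 0
}

#' Vocal-tract deformation effort
#'
#' Integrates `|A(x,t) - A_Omega(x)|` over the space-time grid by the
#' trapezoidal rule on both axes.
#'
#' @param field An `area_field` from [area_function()].
#' @return Tract effort in cm^2 s (non-negative; 0 iff the field equals the
#'   neutral profile everywhere).
#' @export
tract_effort <- function(field) {
  stopifnot(inherits(field, "area_field"))
  a <- field$area
  if (nrow(a) != length(field$x_grid) || ncol(a) != length(field$t_grid)) {
    stop("area matrix does not match the grids")
  }
  if (nrow(a) < 2L || ncol(a) < 2L) stop("need at least 2 points per axis")
  dev <- abs(a - field$neutral)  # neutral recycles down columns (space-major)
  inner <- apply(dev, 2, function(col) pracma::trapz(field$x_grid, col))
  pracma::trapz(field$t_grid, inner)
}

#' Devoicing-effort calibration
#'
#' `E0` is not observable directly; the packaged default is calibrated once
#' so that the mean total effort of the nine devoiced CCVs exceeds the mean
#' of the six fully voiced CCVs by the same ratio as their measured
#' normalised-transition group means in the packaged calibration table
#' (41.3 vs 38.2, in 1e-2 units). This is a calibration, not a measurement.
#'
#' @param geometry A `tract_geometry`.
#' @param config An effort config (see [default_effort_config()]); its `E0`
#'   entry is ignored.
#' @return The calibrated `E0` (cm^2 s).
#' @export
calibrate_devoicing_effort <- function(geometry = default_tract_geometry(),
                                       config = NULL) {
  if (is.null(config)) config <- default_effort_config(geometry, E0 = 0)
  config$E0 <- 0
  config$geometry <- geometry
  tab <- effort_table(analysis_ccvs(), config)
  voiced <- tab$E_total[tab$ccv %in% fully_voiced_ccvs()]
  devoiced <- tab$E_total[tab$ccv %in% devoiced_ccvs()]
  cal <- default_calibration()$ccv_table
  ratio <- mean(cal$tau_mean[cal$ccv %in% devoiced_ccvs()]) /
    mean(cal$tau_mean[cal$ccv %in% fully_voiced_ccvs()])
  E0 <- ratio * mean(voiced) - mean(devoiced)
  if (E0 <= 0) stop("calibration produced a non-positive E0; check the geometry")
  E0
}

#' Effort configuration
#'
#' Bundles the parameters of the effort computation: utterance duration
#' `T_total` (s; the packaged default 0.490 s is the mean CCV duration),
#' inter-closure interval `dt_closure` (s; 0.200 s default), first-closure
#' time `t1` (s), occlusion shape parameters (`sigma` cm, `w` s), the time
#' step of the integration grid, the geometry and the devoicing constant
#' `E0`. When `E0 = NULL` it is calibrated via
#' [calibrate_devoicing_effort()].
#'
#' @param geometry A `tract_geometry`.
#' @param T_total,dt_closure,t1,sigma,w,dt_time,E0 See description.
#' @return A list of class `effort_config`.
#' @export
default_effort_config <- function(geometry = default_tract_geometry(),
                                  T_total = 0.490, dt_closure = 0.200,
                                  t1 = 0.100, sigma = 1.0, w = 0.120,
                                  dt_time = 0.001, E0 = NULL) {
  cfg <- structure(
    list(geometry = geometry, T_total = T_total, dt_closure = dt_closure,
         t1 = t1, sigma = sigma, w = w, dt_time = dt_time, E0 = E0),
    class = "effort_config"
  )
  if (is.null(cfg$E0)) cfg$E0 <- calibrate_devoicing_effort(geometry, cfg)
  cfg
}

#' Effort of one plosive-plosive CCV
#'
#' Builds the two occlusion gestures at `t1` and `t1 + dt_closure` riding
#' the linear vowel trajectory towards /a/, integrates the tract
#' deformation, and adds the devoicing term.
#'
#' @param ccv A one-row CCV record (plosive-plosive only).
#' @param config An `effort_config`.
#' @return One-row tibble: `ccv, E_tract, E0, E_total, dt_closure`.
#' @export
ccv_effort <- function(ccv, config = default_effort_config()) {
  if (ccv$cluster_type != "plosive-plosive") {
    stop("unsupported cluster: effort is defined only for plosive-plosive CCVs (",
         ccv$ccv, " is ", ccv$cluster_type, ")")
  }
  if (config$dt_closure >= config$T_total) {
    stop("inter-closure interval dt_closure must be smaller than T")
  }
  geom <- config$geometry
  vowel <- vowel_gesture(geom$q1_a, geom$q2_a, config$T_total)
  occ <- list(
    occlusion_gesture(ccv$x1_frac * geom$L, config$t1,
                      sigma = config$sigma, w = config$w),
    occlusion_gesture(ccv$x2_frac * geom$L, config$t1 + config$dt_closure,
                      sigma = config$sigma, w = config$w)
  )
  t_grid <- seq(0, config$T_total, by = config$dt_time)
  field <- area_function(geom, vowel, occ, t_grid)
  e_tract <- tract_effort(field)
  e0 <- devoicing_term(ccv, config$E0)
  tibble::tibble(ccv = ccv$ccv, E_tract = e_tract, E0 = e0,
                 E_total = e_tract + e0, dt_closure = config$dt_closure)
}

#' Effort table for a set of CCVs
#'
#' @param ccvs Tibble of CCV records (rows as from [ccv_spec()]).
#' @param config An `effort_config`.
#' @return Tibble with one [ccv_effort()] row per CCV, order preserved.
#' @export
effort_table <- function(ccvs, config = default_effort_config()) {
  if (nrow(ccvs) == 0L) {
    return(tibble::tibble(ccv = character(), E_tract = numeric(),
                          E0 = numeric(), E_total = numeric(),
                          dt_closure = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(ccvs)), function(i) {
    tryCatch(ccv_effort(ccvs[i, ], config),
             error = function(e) stop("effort(", ccvs$ccv[i], "): ",
                                      conditionMessage(e), call. = FALSE))
  })
}

#' Inter-closure interval sweep
#'
#' Recomputes the effort table across a range of inter-closure intervals to
#' probe every degree of overlap between the two plosive gestures. The
#' default sweep covers 100-300 ms in 25-ms steps.
#'
#' @param ccvs Tibble of CCV records.
#' @param config An `effort_config`.
#' @param dt_values Inter-closure intervals in seconds.
#' @return Long tibble of effort tables, one block per `dt_closure`.
#' @export
effort_dt_sweep <- function(ccvs, config = default_effort_config(),
                            dt_values = seq(0.100, 0.300, by = 0.025)) {
  purrr::map_dfr(dt_values, function(dt) {
    cfg <- config
    cfg$dt_closure <- dt
    effort_table(ccvs, cfg)
  })
}

#' Write an effort table as delimited text
#'
#' @param tab Effort table.
#' @param path Output path.
#' @param comment Optional header comment lines (without the leading `#`).
#' @export
write_effort_table <- function(tab, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
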