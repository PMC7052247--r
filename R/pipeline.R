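#' Pipeline configuration
#'
#' One flat list drives the whole run: the design (subjects, seed), the
#' calibration, the QC thresholds, the effort configuration and the
#' significance level.
#'
#' @param seed Master seed; every random draw in the run derives from it.
#' @param n_subjects Number of simulated participants.
#' @param calibration A `ccv_calibration`.
#' @param effort An `effort_config` (built lazily when `NULL`).
#' @param alpha Significance level (in (0, 1)).
#' @param max_mispronounced_fraction Participant-exclusion threshold.
#' @param n_audio_check Number of oral trials whose audio is synthesised
#'   and re-measured as an end-to-end check of the landmark detectors.
#' @param dt_sweep Inter-closure intervals (s) for the effort sweep.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 30,
                            calibration = default_calibration(),
                            effort = NULL, alpha = 0.01,
                            max_mispronounced_fraction = 0.45,
                            n_audio_check = 24,
                            dt_sweep = seq(0.100, 0.300, by = 0.025)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(seed = seed, n_subjects = n_subjects,
                 calibration = calibration, effort = effort, alpha = alpha,
                 max_mispronounced_fraction = max_mispronounced_fraction,
                 n_audio_check = n_audio_check, dt_sweep = dt_sweep),
            class = "pipeline_config")
}

config_hash <- function(config) {
  key <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), c("effort", "calibration"))]
  )), collapse = "")
  sum(utf8ToInt(key) * seq_len(nchar(key))) %% 1e9
}

#' Run the full analysis
#'
#' generate -> extract -> filter -> aggregate -> infer. Produces (i) the
#' oral-block multiple regressions, silent-block repetition regressions
#' and frequency ANOVAs (one statistic table), (ii) cross-block CCV
#' aggregates with the SEM-weighted FFD/FPRT/TFT-vs-tau' regressions,
#' (iii) the effort table, inter-closure sweep and effort-vs-tau'
#' association, and (iv) the QC report. Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return A named list of tibbles (the results bundle) with the config
#'   hash and seed attached as attributes.
#' @export
run_analysis <- function(config = pipeline_config()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  design <- stage("generate", build_design(config$n_subjects, seed = config$seed))
  records <- stage("simulate", simulate_timing(design, config$calibration,
                                               seed = config$seed + 1))
  extraction <- stage("extract", .audio_extraction_check(records, config))
  qc <- stage("qc", qc_cascade(records,
                               max_mispronounced_fraction = config$max_mispronounced_fraction))
  clean <- qc$records
  analysis_set <- analysis_ccvs()
  oral <- dplyr::filter(clean, .data$block == "oral",
                        .data$ccv %in% analysis_set$ccv)
  silent <- dplyr::filter(clean, .data$block == "silent",
                          .data$ccv %in% analysis_set$ccv)
  stats_tab <- stage("stats", block_statistics(oral, silent, analysis_set,
                                               config$alpha))
  aggregates <- stage("aggregate", cross_block_aggregates(clean))
  cross <- stage("cross-block", purrr::map_dfr(c("ffd", "fprt", "tft"), function(v) {
    res <- wls_regression(aggregates, v, "tau_norm", alpha = config$alpha)
    dplyr::mutate(dplyr::filter(res, .data$term == "tau_norm"),
                  response = v, .before = 1)
  }))
  if (is.null(config$effort)) config$effort <- default_effort_config()
  efforts <- stage("effort", effort_table(analysis_set, config$effort))
  sweep <- stage("effort-sweep",
                 effort_dt_sweep(analysis_set, config$effort, config$dt_sweep))
  tau_agg <- aggregate_by_ccv(oral, "tau_norm")
  eff_assoc <- stage("effort-association", {
    j <- dplyr::inner_join(efforts, tau_agg, by = "ccv")
    sweep_rho <- sweep |>
      dplyr::inner_join(tau_agg, by = "ccv") |>
      dplyr::group_by(.data$dt_closure) |>
      dplyr::summarise(spearman = stats::cor(.data$E_total, .data$tau_norm_mean,
                                             method = "spearman"),
                       .groups = "drop")
    fit <- stats::lm(tau_norm_mean ~ E_total, data = j,
                     weights = 1 / j$tau_norm_sem^2)
    sm <- summary(fit)$coefficients
    list(
      regression = tibble::tibble(term = "E_total", estimate = sm[2, 1],
                                  se = sm[2, 2], statistic = sm[2, 3],
                                  df = fit$df.residual, p = sm[2, 4]),
      sweep_spearman = sweep_rho
    )
  })
  bundle <- list(
    records = records,
    qc_report = qc$report,
    statistics = stats_tab,
    aggregates = aggregates,
    cross_block = cross,
    efforts = efforts,
    effort_sweep = sweep,
    effort_vs_tau = eff_assoc$regression,
    effort_sweep_spearman = eff_assoc$sweep_spearman,
    extraction_check = extraction
  )
  attr(bundle, "seed") <- config$seed
  attr(bundle, "config_hash") <- config_hash(config)
  bundle
}

# end-to-end detector check: synthesise audio for a subsample of oral
# plosive-plosive trials and re-measure tau against the planted value
.audio_extraction_check <- function(records, config) {
  if (config$n_audio_check < 1) return(tibble::tibble())
  oral <- dplyr::filter(records, .data$block == "oral",
                        .data$ccv %in% analysis_ccvs()$ccv,
                        !is.na(.data$tau))
  take <- oral[unique(round(seq(1, nrow(oral),
                                length.out = min(config$n_audio_check,
                                                 nrow(oral))))), ]
  purrr::map_dfr(seq_len(nrow(take)), function(i) {
    r <- take[i, ]
    onset <- 0.300
    t1 <- onset + 0.35 * (r$T - r$tau)
    au <- synthesize_ccv_audio(onset, c(t1, t1 + r$tau), T_total = r$T,
                               seed = config$seed + i)
    meas <- phonatory_measures(au$samples, au$sample_rate, "plosive-plosive")
    tibble::tibble(ccv = r$ccv, tau_true = r$tau, tau_est = meas$tau,
                   onset_true = onset,
                   onset_est = detect_vocal_onset(au$samples, au$sample_rate))
  })
}

#' Per-block regression and ANOVA battery
#'
#' Oral block: multiple regressions of the onset delay and each ocular
#' variable on the normalised transition and the repetition number.
#' Silent block: simple regressions on repetition number. Both blocks:
#' one-way ANOVAs of each variable across intra-word frequency levels.
#'
#' @param oral,silent Trial tibbles restricted to one block each.
#' @param analysis_set CCV records supplying the frequency column.
#' @param alpha Significance level.
#' @return A long tibble of coefficient rows
#'   (`block, response, test, term, estimate, se, statistic, df, p`).
#' @export
block_statistics <- function(oral, silent, analysis_set = analysis_ccvs(),
                             alpha = 0.01) {
  oral <- dplyr::mutate(oral, freq_level = bin_frequency(
    analysis_set$f[match(.data$ccv, analysis_set$ccv)]))
  silent <- dplyr::mutate(silent, freq_level = bin_frequency(
    analysis_set$f[match(.data$ccv, analysis_set$ccv)]))
  reg_rows <- function(data, response, predictors, block) {
    res <- ols_regression(data, response, predictors, alpha = alpha)
    res <- dplyr::filter(res, .data$term != "(Intercept)")
    dplyr::mutate(res, block = block, response = response,
                  test = "regression", .before = 1)
  }
  anova_rows <- function(data, response, block) {
    keep <- !is.na(data[[response]])
    groups <- split(data[[response]][keep], data$freq_level[keep], drop = TRUE)
    groups <- groups[vapply(groups, length, 1L) >= 2]
    res <- one_way_anova(groups, alpha = alpha)
    dplyr::mutate(res, block = block, response = response,
                  test = "anova_frequency", .before = 1)
  }
  dplyr::bind_rows(
    reg_rows(oral, "delta", c("tau_norm", "repetition"), "oral"),
    purrr::map_dfr(c("tft", "fprt", "ffd"),
                   ~reg_rows(oral, .x, c("tau_norm", "repetition"), "oral")),
    purrr::map_dfr(c("tft", "fprt", "ffd"),
                   ~reg_rows(silent, .x, "repetition", "silent")),
    anova_rows(oral, "delta", "oral"),
    purrr::map_dfr(c("tft", "fprt", "ffd"), ~anova_rows(oral, .x, "oral")),
    purrr::map_dfr(c("tft", "fprt", "ffd"), ~anova_rows(silent, .x, "silent"))
  )
}

#' Write the results bundle as delimited text
#'
#' One tab-separated file per table, each carrying the seed and config
#' hash in a header comment.
#'
#' @param bundle Result of [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- sprintf("seed=%s config_hash=%s",
                  attr(bundle, "seed"), attr(bundle, "config_hash"))
  for (nm in names(bundle)) {
    tab <- bundle[[nm]]
    if (!is.data.frame(tab)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(paste("#", meta), con)
    utils::write.table(as.data.frame(tab)[!vapply(tab, is.list, TRUE)], con,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Load a deposited trial table
#'
#' Reads a trial-level table exported in the package's interchange format
#' (tab- or comma-separated with a header; columns `subject, block, ccv,
#' repetition, ffd, fprt, tft, delta, T, tau, tau_norm, unfixated,
#' mispronounced, multi_attempt`). Intended for replication against the
#' study's deposited dataset once converted to this layout.
#'
#' @param path Path to the trial table.
#' @return A trial tibble.
#' @export
read_deposited_trials <- function(path) {
  if (!file.exists(path)) {
    stop("deposited trial table not found at '", path,
         "'; download and convert the study dataset first")
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                             comment.char = "#"))
  need <- c("subject", "block", "ccv", "ffd", "fprt", "tft")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("deposited table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' Replicate the cross-block analysis on a deposited trial table
#'
#' Runs the exclusion cascade and the SEM-weighted regression of silent
#' first-fixation durations on oral normalised transitions, reporting the
#' retained plosive-plosive count and the slope t-statistic.
#'
#' @param path Path to the deposited trial table
#'   (see [read_deposited_trials()]).
#' @param alpha Significance level.
#' @return List: `n_retained` (plosive-plosive records after the cascade),
#'   `ffd_regression` (a `stat_result`), and the `qc_report`.
#' @export
replicate_deposited_analysis <- function(path, alpha = 0.01) {
  records <- read_deposited_trials(path)
  qc <- qc_cascade(records)
  keep <- dplyr::filter(qc$records, .data$ccv %in% analysis_ccvs()$ccv)
  aggregates <- cross_block_aggregates(qc$records)
  list(
    n_retained = sum(keep$block == "oral") ,
    ffd_regression = wls_regression(aggregates, "ffd", "tau_norm", alpha = alpha),
    qc_report = qc$report
  )
}
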