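#' Quality-control cascade
#'
#' Trials are screened in a fixed order: (1) participants who mispronounce
#' more than 45% of their CCVs are removed entirely; (2) trials that were
#' not fixated, were mispronounced, or contained more than one production
#' attempt are removed; (3) trials with any key variable outside the
#' participant's own mean +/- 2 SD band are removed in a single pass.
#'
#' @name qc-cascade
NULL

#' Exclude high-mispronunciation participants
#'
#' A participant is removed when their mispronounced fraction (over trials
#' carrying a mispronunciation flag, i.e. the oral block) is strictly
#' greater than the threshold.
#'
#' @param records Trial tibble with `subject` and logical `mispronounced`.
#' @param max_mispronounced_fraction Exclusion threshold (default 0.45).
#' @return List: `records` (retained trials) and `report` (one row per
#'   excluded subject with their fraction).
#' @export
exclude_participants <- function(records, max_mispronounced_fraction = 0.45) {
  frac <- records |>
    dplyr::filter(!is.na(.data$mispronounced)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(fraction = mean(.data$mispronounced), .groups = "drop")
  out_subj <- frac$subject[frac$fraction > max_mispronounced_fraction]
  list(
    records = dplyr::filter(records, !(.data$subject %in% out_subj)),
    report = dplyr::filter(frac, .data$subject %in% out_subj)
  )
}

#' Exclude flagged trials
#'
#' Removes trials flagged as unfixated, mispronounced, or containing more
#' than one production attempt. `NA` flags count as not flagged.
#'
#' @param records Trial tibble with logical `unfixated`, `mispronounced`,
#'   `multi_attempt` columns.
#' @return List: `records` and a `report` tibble of counts per reason
#'   (reasons may overlap; `n_removed` counts unique trials).
#' @export
exclude_trials <- function(records) {
  flag <- function(x) !is.na(x) & x
  unf <- flag(records$unfixated)
  mis <- flag(records$mispronounced)
  mul <- flag(records$multi_attempt)
  drop <- unf | mis | mul
  report <- tibble::tibble(
    reason = c("unfixated", "mispronounced", "multi_attempt", "any"),
    n = c(sum(unf), sum(mis), sum(mul), sum(drop))
  )
  list(records = records[!drop, , drop = FALSE], report = report)
}

#' Per-participant 2-SD outlier filter
#'
#' For each participant and each listed variable the band
#' `mean +/- 2 * sd` is computed over the participant's valid values
#' (bounds fixed before any removal, single pass, `sd` with the `n - 1`
#' denominator). A trial is removed if any of its listed variables falls
#' outside its band. Variables with fewer than `min_n` valid values for a
#' participant are skipped for that participant with a warning; a zero SD
#' gives a degenerate band that removes nothing.
#'
#' @param records Trial tibble with `subject` and the variable columns.
#' @param variables Column names to screen.
#' @param min_n Minimum valid values per participant per variable.
#' @return List: `records`, and `report` with per-variable removal counts.
#' @export
outlier_filter <- function(records,
                           variables = c("ffd", "fprt", "tft", "delta", "tau_norm"),
                           min_n = 3L) {
  variables <- intersect(variables, names(records))
  drop <- rep(FALSE, nrow(records))
  per_var <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    x <- records[[v]]
    for (s in unique(records$subject)) {
      in_s <- records$subject == s
      vals <- x[in_s & !is.na(x)]
      if (length(vals) < min_n) {
        if (length(vals) > 0) {
          warning("outlier filter: fewer than ", min_n, " values of '", v,
                  "' for subject ", s, "; variable skipped")
        }
        next
      }
      m <- mean(vals)
      s2 <- stats::sd(vals)
      if (s2 == 0) next
      bad <- in_s & !is.na(x) & (x < m - 2 * s2 | x > m + 2 * s2)
      per_var[v] <- per_var[v] + sum(bad & !drop)
      drop <- drop | bad
    }
  }
  list(
    records = records[!drop, , drop = FALSE],
    report = tibble::tibble(variable = c(variables, "any"),
                            n = c(unname(per_var), sum(drop)))
  )
}

#' Full exclusion cascade
#'
#' Applies [exclude_participants()], [exclude_trials()] and
#' [outlier_filter()] in order and assembles the stage report.
#'
#' @inheritParams exclude_participants
#' @inheritParams outlier_filter
#' @return List: `records` (retained) and `report` tibble
#'   (`stage, reason, n_removed, n_remaining`).
#' @export
qc_cascade <- function(records, max_mispronounced_fraction = 0.45,
                       variables = c("ffd", "fprt", "tft", "delta", "tau_norm")) {
  n0 <- nrow(records)
  p <- exclude_participants(records, max_mispronounced_fraction)
  n1 <- nrow(p$records)
  t <- exclude_trials(p$records)
  n2 <- nrow(t$records)
  o <- outlier_filter(t$records, variables)
  n3 <- nrow(o$records)
  report <- tibble::tibble(
    stage = c("participants", "trials", "outliers"),
    reason = c("mispronounced > threshold", "unfixated/mispronounced/multi-attempt",
               "outside participant mean +/- 2 SD"),
    n_removed = c(n0 - n1, n1 - n2, n2 - n3),
    n_remaining = c(n1, n2, n3)
  )
  list(records = o$records, report = report,
       detail = list(participants = p$report, trials = t$report,
                     outliers = o$report))
}

#' Discretise intra-word frequency
#'
#' Three levels: low (`f < 10`), medium (`10 < f < 50`), high (`f > 50`).
#' The boundary values 10 and 50 are assigned to the lower bin.
#'
#' @param f Intra-word frequency (appearances per million words, >= 0).
#' @return Ordered factor with levels `low < medium < high`.
#' @export
bin_frequency <- function(f) {
  if (any(is.na(f)) || any(f < 0)) stop("frequency must be non-negative")
  cut(f, breaks = c(-Inf, 10, 50, Inf),
      labels = c("low", "medium", "high"),
      right = TRUE, ordered_result = TRUE)
}
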