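#' Statistical battery
#'
#' Ordinary least squares with per-coefficient t-tests, SEM-weighted least
#' squares on CCV aggregates, the pooled two-sample t-test, and one-way
#' ANOVA. All tests are two-sided; the significance level is 0.01
#' throughout, to account for multiple comparisons.
#'
#' @name stats-battery
NULL

.stat_result <- function(terms, kind, alpha) {
  terms$significant <- terms$p < alpha
  structure(terms, kind = kind, alpha = alpha,
            class = c("stat_result", class(terms)))
}

#' Multiple / simple OLS regression with coefficient t-tests
#'
#' @param data Data frame of complete cases for the model variables.
#' @param response Name of the dependent variable.
#' @param predictors Character vector of predictor names.
#' @param alpha Significance level.
#' @return A `stat_result` tibble: one row per coefficient with
#'   `term, estimate, se, statistic, df, p, significant`.
#' @export
ols_regression <- function(data, response, predictors, alpha = 0.01) {
  data <- data[stats::complete.cases(data[, c(response, predictors)]), ]
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1) stop("need more observations than coefficients")
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) stop("singular design matrix")
  sm <- unname(summary(fit)$coefficients)
  .stat_result(tibble::tibble(
    term = c("(Intercept)", predictors),
    estimate = sm[, 1], se = sm[, 2], statistic = sm[, 3],
    df = fit$df.residual, p = sm[, 4]
  ), kind = "ols", alpha = alpha)
}

#' SEM-weighted least squares on CCV aggregates
#'
#' Regression of one aggregated mean on another with weights
#' `1 / SEM(y)^2`, the inverse-variance weighting of the dependent means.
#' With 15 CCVs the slope t-test has 13 residual degrees of freedom.
#' Points with infinite SEM get weight zero; a zero SEM is an error.
#'
#' @param aggregates Tibble of per-CCV aggregates from
#'   [aggregate_by_ccv()].
#' @param y_var,x_var Variable stems: columns `<stem>_mean` and
#'   `<stem>_sem` must exist for `y_var`, `<stem>_mean` for `x_var`.
#' @param alpha Significance level.
#' @return A `stat_result` tibble (intercept and slope rows).
#' @export
wls_regression <- function(aggregates, y_var, x_var, alpha = 0.01) {
  y <- aggregates[[paste0(y_var, "_mean")]]
  sem <- aggregates[[paste0(y_var, "_sem")]]
  x <- aggregates[[paste0(x_var, "_mean")]]
  if (length(y) < 3) stop("need at least 3 aggregates")
  if (any(is.na(y)) || any(is.na(x)) || any(is.na(sem))) stop("missing aggregate values")
  if (any(sem == 0)) stop("zero SEM: weight undefined")
  w <- 1 / sem^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- unname(summary(fit)$coefficients)
  .stat_result(tibble::tibble(
    term = c("(Intercept)", x_var),
    estimate = sm[, 1], se = sm[, 2], statistic = sm[, 3],
    df = fit$df.residual, p = sm[, 4]
  ), kind = "wls", alpha = alpha)
}

#' Pooled two-sample t-test
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-sided.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param alpha Significance level.
#' @return A `stat_result` tibble with one row.
#' @export
two_sample_ttest <- function(a, b, alpha = 0.01) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample")
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      return(.stat_result(tibble::tibble(
        term = "mean(a) - mean(b)", estimate = 0, se = 0, statistic = 0,
        df = df, p = 1
      ), kind = "ttest", alpha = alpha))
    }
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  .stat_result(tibble::tibble(
    term = "mean(a) - mean(b)",
    estimate = unname(diff(rev(ht$estimate))),
    se = unname(ht$stderr),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value
  ), kind = "ttest", alpha = alpha)
}

#' One-way ANOVA
#'
#' Classical equal-variance F-test across `k >= 2` groups with
#' `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups A list of numeric vectors (each n >= 2), or a data frame
#'   given via `values`/`group` column names.
#' @param alpha Significance level.
#' @return A `stat_result` tibble with one row (`statistic` is F).
#' @export
one_way_anova <- function(groups, alpha = 0.01) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  .stat_result(tibble::tibble(
    term = "group",
    estimate = NA_real_, se = NA_real_,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter[2]),
    df1 = unname(ht$parameter[1]),
    p = ht$p.value
  ), kind = "anova", alpha = alpha)
}

#' Per-CCV aggregates (mean and SEM)
#'
#' Averages the requested variables across participants and repetitions
#' within each CCV; `SEM = SD / sqrt(n)`. CCVs with fewer than 2 valid
#' trials for a variable are dropped with a warning.
#'
#' @param records Trial tibble with a `ccv` column.
#' @param variables Columns to aggregate.
#' @return Tibble: `ccv`, `n`, and `<var>_mean` / `<var>_sem` columns.
#' @export
aggregate_by_ccv <- function(records, variables) {
  variables <- intersect(variables, names(records))
  out <- records |>
    dplyr::group_by(.data$ccv) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(variables),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sem = ~stats::sd(.x, na.rm = TRUE) /
                           sqrt(sum(!is.na(.x)))),
                    .names = "{.col}_{.fn}"),
      n_valid = min(vapply(dplyr::pick(dplyr::all_of(variables)),
                           function(x) sum(!is.na(x)), 1L)),
      .groups = "drop"
    )
  thin <- out$n_valid < 2
  if (any(thin)) {
    warning("dropping CCV(s) with fewer than 2 valid trials: ",
            paste(out$ccv[thin], collapse = ", "))
    out <- out[!thin, , drop = FALSE]
  }
  dplyr::select(out, -"n_valid")
}

#' Cross-block CCV aggregates
#'
#' Joins silent-block ocular aggregates with oral-block normalised
#' transitions for the plosive-plosive analysis set: the inputs of the
#' SEM-weighted cross-block regressions.
#'
#' @param records Trial tibble with `block` (`"oral"`/`"silent"`), `ccv`,
#'   ocular columns and `tau_norm`.
#' @param ccvs CCV labels to keep (default: the 15 analysis CCVs).
#' @return Tibble of per-CCV aggregates with ocular (silent) and
#'   `tau_norm` (oral) mean/SEM columns.
#' @export
cross_block_aggregates <- function(records, ccvs = analysis_ccvs()$ccv) {
  silent <- aggregate_by_ccv(
    dplyr::filter(records, .data$block == "silent", .data$ccv %in% ccvs),
    c("ffd", "fprt", "tft")
  )
  oral <- aggregate_by_ccv(
    dplyr::filter(records, .data$block == "oral", .data$ccv %in% ccvs),
    "tau_norm"
  )
  dplyr::inner_join(silent, oral, by = "ccv", suffix = c("_silent", "_oral"))
}

#' Write a statistic table as delimited text
#'
#' @param result A `stat_result` (or tibble of stacked results).
#' @param path Output path.
#' @param comment Optional header comment lines.
#' @export
write_stat_table <- function(result, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.table(as.data.frame(result), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
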