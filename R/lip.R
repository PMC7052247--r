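#' Lip-accelerometer traces
#'
#' A lip trace is a uniformly sampled acceleration series (arbitrary
#' units; all comparisons are ratio-based) with a start time and a reading
#' modality. Oral traces show movement starting roughly half a second
#' before phonation with maximum displacement at the vocal onset; silent
#' traces, when articulation is present at all, are about two orders of
#' magnitude smaller.
#'
#' @param samples Numeric acceleration samples.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample (s).
#' @param modality `"oral"` or `"silent"`.
#' @param vocal_onset Optional vocal-onset time (s) for alignment.
#' @return A `lip_trace` object.
#' @export
lip_trace <- function(samples, rate, t0 = 0, modality = c("oral", "silent"),
                      vocal_onset = NA_real_) {
  modality <- match.arg(modality)
  if (rate <= 0) stop("rate must be positive")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0,
                 modality = modality, vocal_onset = vocal_onset),
            class = "lip_trace")
}

#' Rectified, smoothed envelope of a lip trace
#'
#' Absolute value smoothed by a centred moving window (default 140 ms).
#' The window shrinks at the edges (no zero padding), so constant traces
#' are preserved.
#'
#' @param trace A `lip_trace`.
#' @param window_ms Moving-window length in ms.
#' @return A `lip_trace` whose samples are the envelope.
#' @export
lip_envelope <- function(trace, window_ms = 140) {
  stopifnot(inherits(trace, "lip_trace"))
  k <- round(window_ms / 1000 * trace$rate)
  if (k < 1) stop("window shorter than one sample period")
  if (k > length(trace$samples)) stop("window longer than the trace")
  out <- trace
  out$samples <- moving_average(abs(trace$samples), k)
  out
}

#' Align lip traces at a common reference
#'
#' Re-times every trace so its reference — the vocal onset or the envelope
#' maximum — sits at `t = 0`, then interpolates all traces onto a common
#' grid. Relative timing within each trace is preserved. When the maximum
#' is not unique the earliest one is used (with a warning).
#'
#' @param traces List of `lip_trace`s (same rate).
#' @param mode `"vocal_onset"` or `"maximum"`.
#' @param envelope_window_ms Envelope window used to find maxima.
#' @return List with `time` (common axis, s) and `matrix`
#'   (traces x time, `NA` outside each trace's support).
#' @export
align_traces <- function(traces, mode = c("vocal_onset", "maximum"),
                         envelope_window_ms = 140) {
  mode <- match.arg(mode)
  stopifnot(length(traces) >= 1)
  rate <- traces[[1]]$rate
  refs <- vapply(traces, function(tr) {
    stopifnot(inherits(tr, "lip_trace"))
    if (tr$rate != rate) stop("all traces must share one sampling rate")
    if (mode == "vocal_onset") {
      if (is.na(tr$vocal_onset)) stop("trace lacks a vocal onset reference")
      tr$vocal_onset
    } else {
      env <- lip_envelope(tr, envelope_window_ms)$samples
      mx <- which(env == max(env))
      if (length(mx) > 1) warning("maximum not unique; using the earliest")
      tr$t0 + (mx[1] - 1) / rate
    }
  }, numeric(1))
  rel_lo <- min(vapply(seq_along(traces), function(i) traces[[i]]$t0 - refs[i], 1))
  rel_hi <- max(vapply(seq_along(traces), function(i) {
    traces[[i]]$t0 + (length(traces[[i]]$samples) - 1) / rate - refs[i]
  }, 1))
  time <- seq(rel_lo, rel_hi, by = 1 / rate)
  mat <- t(vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    tt <- tr$t0 + (seq_along(tr$samples) - 1) / rate - refs[i]
    stats::approx(tt, tr$samples, xout = time, rule = 1)$y
  }, numeric(length(time))))
  list(time = time, matrix = mat)
}

#' Peak envelope amplitude of a trace
#'
#' @inheritParams lip_envelope
#' @return Maximum of the rectified, smoothed envelope.
#' @export
lip_peak <- function(trace, window_ms = 140) {
  max(lip_envelope(trace, window_ms)$samples)
}

#' Oral / silent amplitude ratio
#'
#' Ratio of the median aligned peak magnitudes across modalities (the mean
#' ratio is reported alongside, as a robustness check). A zero silent
#' median yields `Inf` with a warning flag.
#'
#' @param oral_peaks,silent_peaks Numeric vectors of per-trial peak
#'   amplitudes (at least one each).
#' @return List with `ratio` (median-based), `ratio_mean`, and `flag`
#'   (`"infinite"` or `NA`).
#' @export
modality_amplitude_ratio <- function(oral_peaks, silent_peaks) {
  if (!length(oral_peaks) || !length(silent_peaks)) {
    stop("need at least one peak per modality")
  }
  med_s <- stats::median(silent_peaks)
  if (med_s == 0) {
    warning("silent median peak is zero; ratio reported as infinite")
    return(list(ratio = Inf, ratio_mean = mean(oral_peaks) / mean(silent_peaks),
                flag = "infinite"))
  }
  list(ratio = stats::median(oral_peaks) / med_s,
       ratio_mean = mean(oral_peaks) / mean(silent_peaks),
       flag = NA_character_)
}

#' Read / write lip traces as delimited text
#'
#' Two-column (`time`, `acceleration`) tab-separated files; the modality
#' and vocal onset travel in `#` header comments.
#'
#' @param trace A `lip_trace` (for writing).
#' @param path File path.
#' @return `read_lip_trace()` returns a `lip_trace`.
#' @export
write_lip_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# modality=%s", trace$modality),
               sprintf("# vocal_onset=%g", trace$vocal_onset)), con)
  tt <- trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
  utils::write.table(data.frame(time = tt, acceleration = trace$samples),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lip_trace
#' @export
read_lip_trace <- function(path) {
  header <- readLines(path, n = 5L)
  modality <- sub(".*=", "", grep("modality", header, value = TRUE)[1])
  onset <- as.numeric(sub(".*=", "", grep("vocal_onset", header, value = TRUE)[1]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  rate <- 1 / stats::median(diff(tab$time))
  lip_trace(tab$acceleration, rate = rate, t0 = tab$time[1],
            modality = modality, vocal_onset = onset)
}
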