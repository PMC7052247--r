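#' Phonatory timing from audio
#'
#' Three timing variables are read off each uttered CCV: the vocal onset
#' (start of the spectral signature of the initial consonant), the total
#' utterance duration `T`, and the consonantal transition `tau` between the
#' release landmarks of the two consonants. Speech-rate differences are
#' washed out by the normalised transition `tau' = tau / T`. The delay
#' `Delta` from the first visual fixation to the vocal onset is the
#' pre-phonatory variable.
#'
#' Landmarks are located on a short-time spectral representation (25-ms
#' Hann window, 5-ms hop): plosive releases as peaks of the broadband
#' (1-8 kHz) spectral-flux onset function, voiced onsets as sustained
#' low-band (75-300 Hz) energy, fricatives as sustained mid-high-band
#' noise. All thresholds are relative, so detection is gain-invariant.
#'
#' @name acoustic-timing
NULL

# moving average with shrink-at-edges (constants preserved)
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# zero-phase band-pass of a waveform; band in Hz
bandpass <- function(wave, sample_rate, band) {
  ny <- sample_rate / 2
  w <- pmin(pmax(band / ny, 1e-6), 0.999)
  bf <- signal::butter(4, w, type = "pass")
  as.numeric(signal::filtfilt(bf, wave))
}

# RMS envelope of a (possibly band-passed) waveform
rms_envelope <- function(x, sample_rate, window_s = 0.010) {
  sqrt(pmax(moving_average(x^2, round(window_s * sample_rate)), 0))
}

# short-time power spectrum: rows = frequency bins, cols = frames
stft_power <- function(wave, sample_rate, window_s = 0.025, hop_s = 0.005) {
  n_win <- round(window_s * sample_rate)
  hop <- max(1L, round(hop_s * sample_rate))
  if (length(wave) < n_win) stop("waveform shorter than one analysis window")
  starts <- seq(1L, length(wave) - n_win + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))
  frames <- vapply(starts, function(s) wave[s:(s + n_win - 1L)] * win,
                   numeric(n_win))
  spec <- stats::mvfft(frames)
  nf <- n_win %/% 2L + 1L
  power <- abs(spec[seq_len(nf), , drop = FALSE])^2
  list(
    power = power,
    freqs = (seq_len(nf) - 1L) * sample_rate / n_win,
    times = (starts - 1L + n_win / 2) / sample_rate
  )
}

band_energy <- function(stft, lo, hi) {
  sel <- stft$freqs >= lo & stft$freqs <= hi
  colSums(stft$power[sel, , drop = FALSE])
}

#' Detect the vocal onset of an utterance
#'
#' Earliest time at which low-band (voiced) energy exceeds an adaptive,
#' gain-invariant threshold for a sustained window.
#'
#' @param wave Mono waveform (numeric).
#' @param sample_rate Samples per second.
#' @param low_band Voicing band in Hz.
#' @param sustain_s Minimum supra-threshold duration in seconds.
#' @param rel_threshold Threshold position between the noise floor and the
#'   peak envelope level (0-1).
#' @return Onset time in seconds (strictly inside the record).
#' @export
detect_vocal_onset <- function(wave, sample_rate, low_band = c(75, 300),
                               sustain_s = 0.030, rel_threshold = 0.5) {
  if (length(wave) < 0.1 * sample_rate) stop("waveform shorter than 0.1 s")
  if (max(abs(wave)) == 0) stop("no-onset: waveform carries no energy")
  env <- rms_envelope(bandpass(wave, sample_rate, low_band), sample_rate)
  floor_lvl <- stats::quantile(env, 0.10, names = FALSE)
  peak_lvl <- stats::quantile(env, 0.95, names = FALSE)
  if (peak_lvl <= floor_lvl * 3 + .Machine$double.eps) {
    stop("no-onset: no supra-threshold low-band energy")
  }
  thr <- floor_lvl + rel_threshold * (peak_lvl - floor_lvl)
  above <- env > thr
  need <- max(1L, round(sustain_s * sample_rate))
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= need)
  if (!length(ok)) stop("no-onset: low-band energy never sustained above threshold")
  idx <- starts[ok[1]]
  # back-track from the sustained crossing to where the envelope left the
  # noise floor, removing the threshold-crossing latency
  thr_low <- floor_lvl + 0.10 * (peak_lvl - floor_lvl)
  while (idx > 1L && env[idx - 1L] > thr_low) idx <- idx - 1L
  (idx - 1L) / sample_rate
}

# locate burst-like broadband transients: returns times (s) of burst onsets
burst_onsets <- function(wave, sample_rate, after = 0, band = c(1000, 8000),
                         rel_flux = 0.30, min_sep_s = 0.030) {
  env <- rms_envelope(bandpass(wave, sample_rate, band), sample_rate,
                      window_s = 0.004)
  s <- stft_power(wave, sample_rate)
  e <- band_energy(s, band[1], band[2])
  le <- log10(e + 1e-12 * max(e, .Machine$double.eps))
  flux <- c(0, pmax(diff(le), 0))
  flux[s$times < after] <- 0
  if (max(flux) <= 0) return(numeric(0))
  thr <- rel_flux * max(flux)
  cand <- which(flux > thr)
  if (!length(cand)) return(numeric(0))
  # group candidates separated by < min_sep into one event, keep peak frame
  groups <- cumsum(c(1, diff(s$times[cand]) > min_sep_s))
  peaks <- vapply(split(cand, groups), function(ix) ix[which.max(flux[ix])], 1L)
  # refine each event at sample level: first crossing of half the local
  # high-band envelope maximum inside +/- 15 ms of the coarse peak
  vapply(s$times[peaks], function(tc) {
    lo <- max(1L, round((tc - 0.015) * sample_rate))
    hi <- min(length(env), round((tc + 0.015) * sample_rate))
    seg <- env[lo:hi]
    cross <- which(seg >= 0.5 * max(seg))[1]
    (lo + cross - 2L) / sample_rate
  }, numeric(1))
}

# sustained high-band noise (fricative) segments: list(onset, offset) times
fricative_segments <- function(wave, sample_rate, band = c(2000, 6000),
                               min_dur_s = 0.050, rel_threshold = 0.25) {
  env <- rms_envelope(bandpass(wave, sample_rate, band), sample_rate,
                      window_s = 0.015)
  floor_lvl <- stats::quantile(env, 0.10, names = FALSE)
  peak_lvl <- stats::quantile(env, 0.98, names = FALSE)
  thr <- floor_lvl + rel_threshold * (peak_lvl - floor_lvl)
  run <- rle(env > thr)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  keep <- run$values & run$lengths >= min_dur_s * sample_rate
  Map(function(s, e) c(onset = (s - 1) / sample_rate, offset = (e - 1) / sample_rate),
      starts[keep], ends[keep])
}

#' Detect the consonantal transition
#'
#' Locates the two release landmarks appropriate to the cluster type and
#' returns their separation `tau`. Plosive-plosive: from the release burst
#' of the first plosive to the release of the second one into the vowel.
#' Plosive-fricative: from the brief broadband plosive burst to the start
#' of the sustained fricative noise. Fricative-plosive: from the abrupt end
#' of the fricative noise to the plosive release. No transition rule exists
#' for fricative-fricative clusters.
#'
#' @inheritParams detect_vocal_onset
#' @param cluster_type One of `"plosive-plosive"`, `"plosive-fricative"`,
#'   `"fricative-plosive"`.
#' @param vocal_onset Optional onset time (s); detected if missing.
#' @return List with `tau` (s) and `landmarks`, a two-row tibble of
#'   `(label, time)`.
#' @export
detect_transition <- function(wave, sample_rate, cluster_type,
                              vocal_onset = NULL) {
  cluster_type <- match.arg(cluster_type,
                            c("plosive-plosive", "plosive-fricative",
                              "fricative-plosive", "fricative-fricative"))
  if (cluster_type == "fricative-fricative") {
    stop("unsupported cluster: no transition rule for fricative-fricative")
  }
  if (is.null(vocal_onset)) {
    vocal_onset <- tryCatch(detect_vocal_onset(wave, sample_rate),
                            error = function(e) 0)
  }
  # a voiced lead-in always precedes the first release; skip its onset edge
  search_from <- vocal_onset + 0.015
  if (cluster_type == "plosive-plosive") {
    bursts <- burst_onsets(wave, sample_rate, after = search_from)
    if (length(bursts) < 2L) {
      stop("no-transition: fewer than two release landmarks detected")
    }
    lm <- tibble::tibble(label = c("release_1", "release_2"),
                         time = bursts[1:2])
  } else if (cluster_type == "plosive-fricative") {
    bursts <- burst_onsets(wave, sample_rate, after = search_from)
    if (!length(bursts)) stop("no-transition: plosive burst not detected")
    fric <- fricative_segments(wave, sample_rate)
    fric <- Filter(function(sg) sg["onset"] > bursts[1] + 0.020, fric)
    if (!length(fric)) stop("no-transition: fricative spot not detected")
    lm <- tibble::tibble(label = c("release_1", "fricative_onset"),
                         time = c(bursts[1], fric[[1]]["onset"]))
  } else { # fricative-plosive
    fric <- fricative_segments(wave, sample_rate)
    if (!length(fric)) stop("no-transition: fricative spot not detected")
    f_end <- fric[[1]]["offset"]
    bursts <- burst_onsets(wave, sample_rate, after = f_end + 0.010)
    if (!length(bursts)) stop("no-transition: plosive release not detected")
    lm <- tibble::tibble(label = c("fricative_offset", "release_2"),
                         time = c(f_end, bursts[1]))
  }
  tau <- diff(lm$time)
  if (tau <= 0) stop("no-transition: landmarks not ordered")
  list(tau = unname(tau), landmarks = lm)
}

#' Total utterance duration from audio
#'
#' `T` is measured from the vocal onset to the last sustained
#' supra-threshold full-band energy.
#'
#' @inheritParams detect_vocal_onset
#' @param vocal_onset Onset time (s); detected if missing.
#' @return Duration in seconds.
#' @export
detect_utterance_duration <- function(wave, sample_rate, vocal_onset = NULL) {
  if (is.null(vocal_onset)) vocal_onset <- detect_vocal_onset(wave, sample_rate)
  env <- rms_envelope(wave, sample_rate)
  floor_lvl <- stats::quantile(env, 0.10, names = FALSE)
  peak_lvl <- stats::quantile(env, 0.95, names = FALSE)
  thr <- floor_lvl + 0.25 * (peak_lvl - floor_lvl)
  above <- which(env > thr)
  if (!length(above)) stop("no supra-threshold energy")
  end_t <- (max(above) - 1L) / sample_rate
  if (end_t <= vocal_onset) stop("utterance end precedes vocal onset")
  end_t - vocal_onset
}

#' Normalised consonantal transition
#'
#' `tau' = tau / T`, removing speech-rate differences between speakers.
#'
#' @param tau Transition in seconds.
#' @param T_total Utterance duration in seconds.
#' @return `tau / T_total` (dimensionless, in `[0, 1]`).
#' @export
normalize_transition <- function(tau, T_total) {
  if (any(T_total <= 0)) stop("T must be positive")
  if (any(tau < 0) || any(tau > T_total)) {
    stop("tau must lie within [0, T]")
  }
  if (any(tau == T_total)) {
    warning("tau equals T: normalised transition at the degenerate bound 1")
  }
  tau / T_total
}

#' Fixation-to-voice onset delay
#'
#' `Delta = vocal_onset - first_fixation_onset`, both on the same clock.
#' Missing timestamps yield `NA` (the trial is excluded later); a negative
#' delay is returned as-is (the sign is a quality-control flag).
#'
#' @param first_fixation_onset Time of the first fixation on the CCV (s).
#' @param vocal_onset Vocal onset time (s).
#' @return Delay in seconds, or `NA_real_` if either timestamp is missing.
#' @export
onset_delay <- function(first_fixation_onset, vocal_onset) {
  ifelse(is.na(first_fixation_onset) | is.na(vocal_onset),
         NA_real_, vocal_onset - first_fixation_onset)
}

#' All phonatory measures of one utterance
#'
#' Convenience wrapper running onset, duration and transition detection and
#' assembling the per-trial phonatory record.
#'
#' @inheritParams detect_transition
#' @param first_fixation_onset First-fixation time on the same clock (s),
#'   or `NA`.
#' @return One-row tibble: `delta, T, tau, tau_norm` plus a `landmarks`
#'   list-column.
#' @export
phonatory_measures <- function(wave, sample_rate, cluster_type,
                               first_fixation_onset = NA_real_) {
  onset <- detect_vocal_onset(wave, sample_rate)
  T_total <- detect_utterance_duration(wave, sample_rate, onset)
  tr <- detect_transition(wave, sample_rate, cluster_type, onset)
  tibble::tibble(
    delta = onset_delay(first_fixation_onset, onset),
    T = T_total,
    tau = tr$tau,
    tau_norm = normalize_transition(tr$tau, T_total),
    landmarks = list(tr$landmarks)
  )
}
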