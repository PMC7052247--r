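#' Run code under a temporary RNG seed
#'
#' Generators are pure functions of (spec, seed): the global RNG state is
#' saved and restored around the seeded computation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Packaged timing calibration
#'
#' Per-CCV means and noise levels for the synthetic oral block, plus the
#' coupling coefficients that tie the other variables to the normalised
#' transition. The plosive-plosive analysis set is calibrated to the
#' measured group structure: tau' means of 0.373 for (bda, bga, dga),
#' 0.390 for the consonant-interchanged (dba, gba, gda) — so the six fully
#' voiced CCVs average 0.3815 — and 0.413 for the nine CCVs with an
#' unvoiced second plosive. Per-CCV means inside a subgroup are assigned
#' uniformly (only subgroup means are observable); users with trial-level
#' data can refit and supply their own table. The trial-level tau' SD of
#' 0.08 is a compromise back-solved from the group standard errors at the
#' study's sample sizes (the voiced, devoiced and place subgroups imply
#' 0.067-0.111). Utterance durations are 0.490 +/- 0.040 s.
#'
#' Couplings (see the methods vignette for the reasoning): the onset delay
#' is `Delta = 0.30 + 0.30 tau' + N(0, 0.15)` seconds; silent-block first
#' fixations are `FFD = -180 + 1100 tau' + N(0, 60)` ms, i.e. a mean near
#' 260 ms with a strong positive transition coupling (oral-block FFD has a
#' flat 260 ms mean: transitions do not feed back into oral eye timing);
#' first-pass and total-time extras shrink by 20 ms per repetition.
#'
#' @return A `ccv_calibration`: list with `ccv_table` (per-CCV `tau_mean`,
#'   `tau_sd`, `T_mean`, `T_sd`) and `couplings` (named numeric vector).
#' @export
default_calibration <- function() {
  inv <- ccv_inventory()
  groups <- place_subgroups()
  tau_mean <- numeric(nrow(inv))
  tau_mean[] <- NA_real_
  tau_mean[inv$ccv %in% groups$forward] <- 0.373
  tau_mean[inv$ccv %in% groups$interchanged] <- 0.390
  tau_mean[inv$ccv %in% devoiced_ccvs()] <- 0.413
  # remaining CCVs (fricative-containing, unvoiced-first plosive-plosive)
  # are outside the analysis set; realistic fillers by cluster type
  fill <- c("plosive-plosive" = 0.41, "plosive-fricative" = 0.44,
            "fricative-plosive" = 0.46, "fricative-fricative" = 0.48)
  miss <- is.na(tau_mean)
  tau_mean[miss] <- fill[inv$cluster_type[miss]]
  structure(list(
    ccv_table = tibble::tibble(
      ccv = inv$ccv, cluster_type = inv$cluster_type,
      tau_mean = tau_mean, tau_sd = 0.08,
      T_mean = 0.490, T_sd = 0.040
    ),
    couplings = c(
      delta_intercept = 0.30, delta_slope = 0.30, delta_sd = 0.15,
      ffd_silent_intercept = -180, ffd_silent_slope = 1100,
      ffd_oral_mean = 260, ffd_sd = 60,
      fprt_extra = 130, fprt_rep_slope = -20, fprt_sd = 60,
      tft_extra = 110, tft_rep_slope = -20, tft_sd = 50
    )
  ), class = "ccv_calibration")
}

#' Read / write a calibration table
#'
#' The per-CCV table as tab-separated text; the coupling coefficients in
#' `# key=value` header comments.
#'
#' @param calibration A `ccv_calibration` (for writing).
#' @param path File path.
#' @return `read_calibration()` returns a `ccv_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%g", names(calibration$couplings),
                     calibration$couplings), con)
  utils::write.table(calibration$ccv_table, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  header <- grep("^#", readLines(path), value = TRUE)
  kv <- sub("^#\\s*", "", header)
  couplings <- stats::setNames(as.numeric(sub(".*=", "", kv)),
                               sub("=.*", "", kv))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(ccv_table = tibble::as_tibble(tab), couplings = couplings),
            class = "ccv_calibration")
}

# allocate repetitions for the 57 non-analysis CCVs: 21 x 3 + 36 x 2 = 135
.other_repetitions <- function(other_ccvs) {
  stopifnot(length(other_ccvs) == 57)
  three <- sample(other_ccvs, 21)
  stats::setNames(ifelse(other_ccvs %in% three, 3L, 2L), other_ccvs)
}

#' Build the trial design
#'
#' Each of the two blocks presents 180 stimuli as 30 screens of 6
#' randomised CCVs: the 15 analysis CCVs (voiced plosive first) three
#' times each (45), and the other 57 CCVs randomly two or three times
#' (135). Repetition numbers are assigned in order of appearance within a
#' subject-block. Deterministic given the seed.
#'
#' @param n_subjects Number of participants.
#' @param seed Integer seed.
#' @param inventory CCV inventory (default [ccv_inventory()]).
#' @return Trial tibble: `subject, block, screen, pos, ccv, repetition`.
#' @export
build_design <- function(n_subjects = 30, seed = 1,
                         inventory = ccv_inventory()) {
  analysis <- analysis_ccvs()$ccv
  others <- setdiff(inventory$ccv, analysis)
  if (length(analysis) * 3 + 135 != 180) stop("repetition scheme cannot tile 180")
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(subj) {
      purrr::map_dfr(c("oral", "silent"), function(blk) {
        reps <- .other_repetitions(others)
        stimuli <- c(rep(analysis, each = 3), rep(names(reps), times = reps))
        stimuli <- sample(stimuli)            # randomise across the block
        tibble::tibble(
          subject = subj, block = blk,
          screen = rep(seq_len(30), each = 6),
          pos = rep(seq_len(6), times = 30),
          ccv = stimuli
        ) |>
          dplyr::group_by(.data$ccv) |>
          dplyr::mutate(repetition = dplyr::row_number()) |>
          dplyr::ungroup()
      })
    })
  })
}

#' Simulate the timing variables of an experiment
#'
#' Draws per-trial phonatory and ocular variables with the calibrated
#' group structure: oral trials get `tau'`, `T`, `tau` and the onset delay
#' `Delta` (coupled positively to `tau'`); silent-block first fixations
#' are coupled positively to the CCV's transition; first-pass and total
#' times shrink across repetitions in both blocks while FFD is free of
#' repetition effects. Ocular triples satisfy `FFD <= FPRT <= TFT` by
#' construction. QC flags (unfixated / mispronounced / multi-attempt) are
#' planted at the given rates.
#'
#' @param design Trial tibble from [build_design()].
#' @param calibration A `ccv_calibration`.
#' @param seed Integer seed.
#' @param unfixated_rate,mispronounce_rate,multi_attempt_rate Flag rates.
#' @return The design with added measure and flag columns (`ffd`, `fprt`,
#'   `tft` in ms; `delta`, `T`, `tau` in s; `tau_norm` dimensionless;
#'   phonatory columns `NA` in the silent block).
#' @export
simulate_timing <- function(design, calibration = default_calibration(),
                            seed = 1, unfixated_rate = 0.02,
                            mispronounce_rate = 0.02,
                            multi_attempt_rate = 0.01) {
  tab <- calibration$ccv_table
  cp <- calibration$couplings
  missing_ccv <- setdiff(unique(design$ccv), tab$ccv)
  if (length(missing_ccv)) {
    stop("missing calibration row(s) for: ", paste(missing_ccv, collapse = ", "))
  }
  idx <- match(design$ccv, tab$ccv)
  n <- nrow(design)
  oral <- design$block == "oral"
  with_seed(seed, {
    tau_norm <- pmin(pmax(stats::rnorm(n, tab$tau_mean[idx], tab$tau_sd[idx]),
                          0.02), 0.98)
    T_total <- pmax(stats::rnorm(n, tab$T_mean[idx], tab$T_sd[idx]), 0.2)
    tau <- tau_norm * T_total
    delta <- cp["delta_intercept"] + cp["delta_slope"] * tau_norm +
      stats::rnorm(n, 0, cp["delta_sd"])
    ffd <- ifelse(
      oral,
      cp["ffd_oral_mean"] + stats::rnorm(n, 0, cp["ffd_sd"]),
      cp["ffd_silent_intercept"] + cp["ffd_silent_slope"] * tab$tau_mean[idx] +
        stats::rnorm(n, 0, cp["ffd_sd"])
    )
    ffd <- pmax(ffd, 40)
    fprt <- ffd + pmax(
      cp["fprt_extra"] + cp["fprt_rep_slope"] * (design$repetition - 1) +
        stats::rnorm(n, 0, cp["fprt_sd"]), 0)
    tft <- fprt + pmax(
      cp["tft_extra"] + cp["tft_rep_slope"] * (design$repetition - 1) +
        stats::rnorm(n, 0, cp["tft_sd"]), 0)
    unfixated <- stats::runif(n) < unfixated_rate
    mispronounced <- ifelse(oral, stats::runif(n) < mispronounce_rate, NA)
    multi_attempt <- ifelse(oral, stats::runif(n) < multi_attempt_rate, NA)
    out <- design
    out$ffd <- ffd
    out$fprt <- fprt
    out$tft <- tft
    out$delta <- ifelse(oral, delta, NA_real_)
    out$T <- ifelse(oral, T_total, NA_real_)
    out$tau <- ifelse(oral, tau, NA_real_)
    out$tau_norm <- ifelse(oral, tau_norm, NA_real_)
    out$unfixated <- unfixated
    out$mispronounced <- mispronounced
    out$multi_attempt <- multi_attempt
    out$ffd[unfixated] <- NA_real_
    out$fprt[unfixated] <- NA_real_
    out$tft[unfixated] <- NA_real_
    out
  })
}

#' Realise a fixation stream from target measures
#'
#' Inverse of the gaze bookkeeping: builds a fixation-event stream on one
#' AOI that, when scored by [compute_measures()], returns exactly the
#' requested FFD / FPRT / TFT. First-pass fixations on the target are
#' followed by a fixation on a neighbouring AOI (terminating the first
#' pass); any remaining total time returns as a re-reading fixation.
#'
#' @param ffd,fprt,tft Target measures in ms (`ffd <= fprt <= tft`).
#' @param layout A [screen_layout()].
#' @param target_aoi Target AOI id.
#' @param start_time Onset of the first fixation (s).
#' @param saccade_s Gap between successive fixations (s).
#' @return Fixation tibble (`onset, duration, x, y`).
#' @export
realize_fixations <- function(ffd, fprt, tft, layout, target_aoi = 2,
                              start_time = 0.5, saccade_s = 0.030) {
  if (!(ffd <= fprt && fprt <= tft) || ffd <= 0) {
    stop("inconsistent measures: need 0 < FFD <= FPRT <= TFT")
  }
  a <- layout$aois
  if (!target_aoi %in% a$aoi) stop("target AOI not in layout")
  other <- if (target_aoi < nrow(a)) target_aoi + 1L else target_aoi - 1L
  centre <- function(k) c(
    x = (a$x_min[a$aoi == k] + a$x_max[a$aoi == k]) / 2,
    y = (a$y_min[a$aoi == k] + a$y_max[a$aoi == k]) / 2
  )
  durs <- c(ffd)
  whos <- c(target_aoi)
  if (fprt > ffd) { durs <- c(durs, fprt - ffd); whos <- c(whos, target_aoi) }
  durs <- c(durs, 150)                 # leave the target: first pass ends
  whos <- c(whos, other)
  if (tft > fprt) { durs <- c(durs, tft - fprt); whos <- c(whos, target_aoi) }
  onsets <- start_time + cumsum(c(0, utils::head(durs, -1) / 1000 + saccade_s))
  xy <- t(vapply(whos, centre, numeric(2)))
  tibble::tibble(onset = onsets, duration = durs, x = xy[, 1], y = xy[, 2])
}

#' Realise a whole screen of fixations
#'
#' Left-to-right first-pass reading over the six AOIs, followed by
#' re-reading fixations carrying each AOI's residual total time, closed by
#' a short regressive fixation on the first (edge, later discarded) AOI so
#' that every first pass is properly terminated.
#'
#' @param measures Tibble with columns `aoi, ffd, fprt, tft` for AOIs 1-6.
#' @param layout A [screen_layout()].
#' @param start_time Onset of the first fixation (s).
#' @param saccade_s Gap between fixations (s).
#' @return Fixation tibble (`onset, duration, x, y`).
#' @export
realize_screen_fixations <- function(measures, layout, start_time = 0.5,
                                     saccade_s = 0.030) {
  stopifnot(all(1:6 %in% measures$aoi))
  m <- measures[order(measures$aoi), ]
  bad <- !(m$ffd <= m$fprt & m$fprt <= m$tft) | m$ffd <= 0
  if (any(bad, na.rm = TRUE)) stop("inconsistent measures on AOI(s) ",
                                   paste(m$aoi[bad], collapse = ", "))
  a <- layout$aois
  centre <- function(k) c((a$x_min[a$aoi == k] + a$x_max[a$aoi == k]) / 2,
                          (a$y_min[a$aoi == k] + a$y_max[a$aoi == k]) / 2)
  durs <- numeric(0); whos <- integer(0)
  for (k in m$aoi) {
    row <- m[m$aoi == k, ]
    if (is.na(row$ffd)) next                    # unfixated AOI: skip entirely
    durs <- c(durs, row$ffd); whos <- c(whos, k)
    if (row$fprt > row$ffd) { durs <- c(durs, row$fprt - row$ffd); whos <- c(whos, k) }
  }
  for (k in m$aoi) {
    row <- m[m$aoi == k, ]
    if (is.na(row$ffd)) next
    if (row$tft > row$fprt) { durs <- c(durs, row$tft - row$fprt); whos <- c(whos, k) }
  }
  durs <- c(durs, 80); whos <- c(whos, 1L)      # terminal regressive fixation
  onsets <- start_time + cumsum(c(0, utils::head(durs, -1) / 1000 + saccade_s))
  xy <- t(vapply(whos, centre, numeric(2)))
  tibble::tibble(onset = onsets, duration = durs, x = xy[, 1], y = xy[, 2])
}

#' Synthesise CCV audio with planted landmarks
#'
#' Test fixture for the landmark detectors: a low-frequency voiced buzz
#' from the vocal onset, brief (10 ms) broadband noise bursts at the
#' release landmarks, and a harmonic vowel tail to the utterance end,
#' over a configurable noise floor. All planted times are returned as
#' ground truth. Deterministic given the seed.
#'
#' @param vocal_onset Vocal onset time (s).
#' @param landmarks Two release-landmark times (s), both inside
#'   `[vocal_onset, vocal_onset + T_total]`.
#' @param T_total Utterance duration (s).
#' @param sample_rate Samples per second.
#' @param cluster_type Cluster type to emulate.
#' @param seed Integer seed.
#' @param noise_floor Noise-floor amplitude (0 disables; buzz amplitude is
#'   0.3, so `noise_floor = 0.03` gives roughly 20 dB SNR).
#' @param pad End padding after the utterance (s).
#' @return List: `samples`, `sample_rate`, and the planted `vocal_onset`,
#'   `landmarks`, `T_total`, `cluster_type`.
#' @export
synthesize_ccv_audio <- function(vocal_onset, landmarks, T_total = 0.490,
                                 sample_rate = 16000,
                                 cluster_type = "plosive-plosive",
                                 seed = 1, noise_floor = 0.002, pad = 0.15) {
  if (length(landmarks) != 2 || diff(landmarks) <= 0) {
    stop("need two increasing landmark times")
  }
  t_end <- vocal_onset + T_total
  if (any(landmarks < vocal_onset) || any(landmarks > t_end)) {
    stop("landmarks outside the utterance [vocal_onset, vocal_onset + T]")
  }
  n <- round((t_end + pad) * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  with_seed(seed, {
    wave <- stats::rnorm(n, 0, noise_floor)
    f0 <- 120
    seg <- function(from, to) tt >= from & tt < to
    # raised-cosine amplitude ramps avoid click transients at segment edges
    taper <- function(mask, ramp_s = 0.012) {
      n_seg <- sum(mask)
      k <- min(n_seg %/% 2, round(ramp_s * sample_rate))
      env <- rep(1, n_seg)
      if (k > 0) {
        r <- 0.5 * (1 - cos(pi * seq_len(k) / k))
        env[seq_len(k)] <- r
        env[n_seg - k + seq_len(k)] <- rev(r)
      }
      env
    }
    add_harmonics <- function(mask, amps) {
      env <- taper(mask)
      for (k in seq_along(amps)) {
        wave[mask] <<- wave[mask] +
          env * amps[k] * sin(2 * pi * k * f0 * tt[mask] + k)
      }
    }
    burst <- function(at, amp = 0.8, dur = 0.010) {
      mask <- seg(at, at + dur)
      wave[mask] <<- wave[mask] + amp * stats::rnorm(sum(mask))
    }
    if (cluster_type %in% c("plosive-plosive", "plosive-fricative")) {
      # voiced lead-in and transition buzz
      add_harmonics(seg(vocal_onset, landmarks[2]), c(0.20, 0.10, 0.05))
    }
    if (cluster_type == "plosive-plosive") {
      burst(landmarks[1]); burst(landmarks[2])
      add_harmonics(seg(landmarks[2] + 0.012, t_end),
                    c(0.28, 0.18, 0.10, 0.06, 0.04))
    } else if (cluster_type == "plosive-fricative") {
      burst(landmarks[1])
      fric <- seg(landmarks[2], min(landmarks[2] + 0.130, t_end))
      wave[fric] <- wave[fric] +
        taper(fric) * 0.4 * bandpass(stats::rnorm(sum(fric)), sample_rate,
                                     c(2000, 6000))
      add_harmonics(seg(min(landmarks[2] + 0.140, t_end), t_end),
                    c(0.28, 0.18, 0.10))
    } else if (cluster_type == "fricative-plosive") {
      fric <- seg(vocal_onset, landmarks[1])
      wave[fric] <- wave[fric] +
        taper(fric, 0.004) * 0.4 * bandpass(stats::rnorm(sum(fric)),
                                            sample_rate, c(2000, 6000))
      burst(landmarks[2])
      add_harmonics(seg(landmarks[2] + 0.012, t_end),
                    c(0.28, 0.18, 0.10, 0.06, 0.04))
    } else {
      stop("unsupported cluster type for synthesis: ", cluster_type)
    }
    list(samples = wave, sample_rate = sample_rate,
         vocal_onset = vocal_onset, landmarks = landmarks,
         T_total = T_total, cluster_type = cluster_type)
  })
}

#' Simulate a lip-accelerometer trace
#'
#' Oral traces ramp up from half a second before the vocal onset and peak
#' at the onset; `"silent"` traces are the same profile scaled by 1e-2
#' (two orders of magnitude down); `"silent_null"` traces sit at the
#' sensor noise floor (the null-activity subgroup of silent readers).
#'
#' @param modality `"oral"`, `"silent"` or `"silent_null"`.
#' @param vocal_onset Vocal onset time (s).
#' @param seed Integer seed.
#' @param rate Sampling rate (Hz).
#' @param duration Trace duration (s).
#' @param silent_scale Amplitude scale of silent relative to oral.
#' @param sensor_noise Additive sensor noise SD.
#' @return A [lip_trace()] (modality `"silent_null"` is stored as silent).
#' @export
simulate_lip_trace <- function(modality = c("oral", "silent", "silent_null"),
                               vocal_onset = 1.0, seed = 1, rate = 1000,
                               duration = 2.5, silent_scale = 1e-2,
                               sensor_noise = 5e-4) {
  modality <- match.arg(modality)
  with_seed(seed, {
    tt <- (seq_len(round(duration * rate)) - 1) / rate
    u <- tt - vocal_onset
    env <- ifelse(u < 0, exp(-u^2 / (2 * 0.18^2)), exp(-u^2 / (2 * 0.15^2)))
    env[u < -0.5] <- env[u < -0.5] * exp(-(u[u < -0.5] + 0.5)^2 / (2 * 0.05^2))
    amp <- switch(modality, oral = 1, silent = silent_scale, silent_null = 0)
    x <- amp * env * sin(2 * pi * 12 * tt) * (1 + 0.1 * stats::rnorm(length(tt))) +
      stats::rnorm(length(tt), 0, sensor_noise)
    lip_trace(x, rate = rate, t0 = 0,
              modality = if (modality == "oral") "oral" else "silent",
              vocal_onset = if (modality == "oral") vocal_onset else NA_real_)
  })
}
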