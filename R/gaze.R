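#' Screen layout for a 6-CCV line of text
#'
#' Six CCVs rendered in a monospaced font (24 px per character, so 72 px
#' per trigram) separated by 4 blank spaces (96 px), centred on a
#' 1024 x 768 screen. Each area of interest (AOI) is the trigram's
#' character box expanded horizontally by one character width per side
#' (the middle of each gap stays unassigned) and by +/- 24 px (about one
#' degree) vertically.
#'
#' @param n_aois Number of CCVs on the line.
#' @param char_px Character width in pixels.
#' @param n_chars Characters per CCV.
#' @param gap_chars Blank characters between CCVs.
#' @param resolution Screen `c(width, height)` in pixels.
#' @param margin_px Horizontal AOI expansion per side, in pixels.
#' @param v_margin_px Vertical AOI half-height beyond the text line.
#' @return A `screen_layout`: list with an `aois` tibble
#'   (`aoi, x_min, x_max, y_min, y_max`, left-to-right) and the resolution.
#' @export
screen_layout <- function(n_aois = 6, char_px = 24, n_chars = 3,
                          gap_chars = 4, resolution = c(1024, 768),
                          margin_px = char_px, v_margin_px = 24) {
  if (n_aois < 1) stop("empty layout")
  word_px <- char_px * n_chars
  gap_px <- char_px * gap_chars
  total <- n_aois * word_px + (n_aois - 1) * gap_px
  if (total > resolution[1]) stop("layout wider than the screen")
  x0 <- (resolution[1] - total) / 2
  lefts <- x0 + (seq_len(n_aois) - 1) * (word_px + gap_px)
  y_mid <- resolution[2] / 2
  aois <- tibble::tibble(
    aoi = seq_len(n_aois),
    x_min = lefts - margin_px,
    x_max = lefts + word_px + margin_px,
    y_min = y_mid - char_px / 2 - v_margin_px,
    y_max = y_mid + char_px / 2 + v_margin_px
  )
  if (any(aois$x_max[-n_aois] >= aois$x_min[-1])) {
    stop("AOIs overlap; reduce margin_px")
  }
  structure(list(aois = aois, resolution = resolution), class = "screen_layout")
}

#' Assign fixations to areas of interest
#'
#' Point-in-rectangle assignment: each fixation lands in at most one AOI;
#' fixations in gaps or margins stay unassigned (`NA`).
#'
#' @param fixations Tibble with at least `onset` (s), `duration` (ms),
#'   `x`, `y` (px), sorted by onset.
#' @param layout A [screen_layout()].
#' @return `fixations` with an added integer `aoi` column.
#' @export
assign_fixations <- function(fixations, layout) {
  stopifnot(inherits(layout, "screen_layout"))
  if (nrow(layout$aois) == 0) stop("empty layout")
  if (is.unsorted(fixations$onset)) stop("fixations must be sorted by onset")
  a <- layout$aois
  idx <- rep(NA_integer_, nrow(fixations))
  for (k in seq_len(nrow(a))) {
    hit <- fixations$x >= a$x_min[k] & fixations$x <= a$x_max[k] &
      fixations$y >= a$y_min[k] & fixations$y <= a$y_max[k]
    idx[hit & is.na(idx)] <- a$aoi[k]
  }
  fixations$aoi <- idx
  fixations
}

#' Reading-time measures for one AOI
#'
#' From the chronological fixation sequence of one screen: FFD is the
#' duration of the first fixation on the AOI; FPRT sums the fixations on
#' the AOI from that first entry until any *other* AOI is fixated
#' (unassigned fixations neither add to nor terminate the first pass); TFT
#' sums every fixation on the AOI. Hence `FFD <= FPRT <= TFT`. A first
#' fixation starting before `stimulus_onset` is clipped to it.
#'
#' @param assigned Tibble with `onset`, `duration` (ms) and `aoi`, sorted
#'   by onset (one screen).
#' @param target_aoi AOI id to score.
#' @param stimulus_onset Stimulus onset time (s) used for clipping.
#' @return One-row tibble: `aoi, ffd, fprt, tft, fixated,
#'   first_fixation_onset`.
#' @export
compute_measures <- function(assigned, target_aoi, stimulus_onset = -Inf) {
  on_target <- !is.na(assigned$aoi) & assigned$aoi == target_aoi
  if (!any(on_target)) {
    return(tibble::tibble(aoi = target_aoi, ffd = NA_real_, fprt = NA_real_,
                          tft = NA_real_, fixated = FALSE,
                          first_fixation_onset = NA_real_))
  }
  first_i <- which(on_target)[1]
  dur <- assigned$duration
  onset <- assigned$onset
  ffd <- dur[first_i]
  ffo <- onset[first_i]
  if (ffo < stimulus_onset) {
    # clip the part of the first fixation that precedes the stimulus
    ffd <- max(0, ffd - (stimulus_onset - ffo) * 1000)
    ffo <- stimulus_onset
  }
  other <- !is.na(assigned$aoi) & assigned$aoi != target_aoi
  leave <- which(other & seq_along(other) > first_i)
  pass_end <- if (length(leave)) leave[1] - 1L else nrow(assigned)
  in_pass <- which(on_target)
  in_pass <- in_pass[in_pass >= first_i & in_pass <= pass_end]
  fprt <- sum(dur[in_pass])
  if (first_i %in% in_pass) fprt <- fprt - dur[first_i] + ffd
  tft <- sum(dur[on_target]) - dur[first_i] + ffd
  tibble::tibble(aoi = target_aoi, ffd = ffd, fprt = fprt, tft = tft,
                 fixated = TRUE, first_fixation_onset = ffo)
}

#' Measures for every AOI of a screen
#'
#' @inheritParams compute_measures
#' @param layout A [screen_layout()] (defines the AOI set).
#' @return Tibble with one [compute_measures()] row per AOI, left to right.
#' @export
screen_measures <- function(assigned, layout, stimulus_onset = -Inf) {
  purrr::map_dfr(layout$aois$aoi, compute_measures, assigned = assigned,
                 stimulus_onset = stimulus_onset)
}

#' Discard screen-edge CCVs
#'
#' The first and last CCVs of each 6-item screen are dropped to avoid
#' screen-edge effects on the ocular variables; the four interior items
#' remain, order preserved.
#'
#' @param measures Tibble of per-AOI measures with an `aoi` column covering
#'   exactly AOIs 1-6.
#' @return The rows with `aoi` in 2-5.
#' @export
discard_edges <- function(measures) {
  ids <- sort(unique(measures$aoi))
  if (!identical(as.integer(ids), 1:6)) {
    stop("edge discard expects exactly 6 AOIs per screen")
  }
  measures[measures$aoi %in% 2:5, , drop = FALSE]
}
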