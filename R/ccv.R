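#' Consonant classes used to build the CCV stimulus set
#'
#' The stimuli are consonant-consonant-vowel (CCV) trigrams built from the
#' three most common Spanish fricatives (s, f, j), the voiced plosives
#' (b, d, g) and the unvoiced plosives (p, t, c), always ending in the
#' vowel /a/. "k" is accepted as an alias for the unvoiced velar "c".
#'
#' @name consonant-classes
#' @keywords internal
NULL

.fricatives <- c("s", "f", "j")
.voiced_plosives <- c("b", "d", "g")
.unvoiced_plosives <- c("p", "t", "c")
.plosives <- c(.voiced_plosives, .unvoiced_plosives)
.consonants <- c(.plosives, .fricatives)

# occlusion place as a fraction of tract length L, by place of articulation:
# bilabial at the lips (x = L), alveolar at 0.85 L, velar at 0.60 L
.occlusion_frac <- c(
  b = 1.00, p = 1.00,
  d = 0.85, t = 0.85,
  g = 0.60, c = 0.60
)

canonical_consonant <- function(x) {
  x <- tolower(as.character(x))
  x[x == "k"] <- "c"
  bad <- !(x %in% .consonants)
  if (any(bad)) {
    stop("unknown consonant symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

is_plosive <- function(x) canonical_consonant(x) %in% .plosives

consonant_voiced <- function(x) canonical_consonant(x) %in% .voiced_plosives

consonant_manner <- function(x) {
  x <- canonical_consonant(x)
  ifelse(x %in% .plosives, "plosive", "fricative")
}

#' Describe one CCV trigram
#'
#' Builds the per-CCV attribute record: consonant identities, voicing flags,
#' cluster type, occlusion places (as fractions of tract length, `NA` for
#' fricatives) and the intra-word frequency `f` from the packaged table.
#'
#' @param ccv A 3-character CCV label such as `"bda"` or `"gta"`, or the two
#'   consonants may be given separately via `c1`, `c2`.
#' @param c1,c2 Optional consonant symbols; used when `ccv` is missing.
#' @param frequency_table Per-CCV intra-word frequency lookup; defaults to the
#'   packaged synthetic table from [ccv_frequency_table()].
#' @return A one-row tibble with columns `ccv, c1, c2, vowel, voiced1,
#'   voiced2, cluster_type, x1_frac, x2_frac, f`.
#' @examples
#' ccv_spec("bda")
#' ccv_spec("gta")$voiced2
#' @export
ccv_spec <- function(ccv = NULL, c1 = NULL, c2 = NULL,
                     frequency_table = ccv_frequency_table()) {
  if (is.null(ccv)) {
    stopifnot(!is.null(c1), !is.null(c2))
    c1 <- canonical_consonant(c1)
    c2 <- canonical_consonant(c2)
  } else {
    ccv <- tolower(ccv)
    if (nchar(ccv) != 3L || substr(ccv, 3, 3) != "a") {
      stop("CCV label must be two consonants followed by 'a', got: ", ccv)
    }
    c1 <- canonical_consonant(substr(ccv, 1, 1))
    c2 <- canonical_consonant(substr(ccv, 2, 2))
  }
  if (c1 == c2) stop("CCVs repeating the same consonant are excluded: ", c1, c2, "a")
  label <- paste0(c1, c2, "a")
  m1 <- consonant_manner(c1)
  m2 <- consonant_manner(c2)
  cluster <- paste(m1, m2, sep = "-")
  f <- frequency_table$f[match(label, frequency_table$ccv)]
  tibble::tibble(
    ccv = label, c1 = c1, c2 = c2, vowel = "a",
    voiced1 = consonant_voiced(c1) | m1 == "fricative",
    voiced2 = consonant_voiced(c2) | m2 == "fricative",
    cluster_type = cluster,
    x1_frac = unname(.occlusion_frac[c1])[1] %|NA|% NA_real_,
    x2_frac = unname(.occlusion_frac[c2])[1] %|NA|% NA_real_,
    f = f
  )
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Full CCV inventory (72 trigrams)
#'
#' All ordered pairs of distinct consonants from the nine-consonant set,
#' followed by /a/: 9 x 8 = 72 CCVs.
#'
#' @inheritParams ccv_spec
#' @return A 72-row tibble, one [ccv_spec()] row per trigram.
#' @export
ccv_inventory <- function(frequency_table = ccv_frequency_table()) {
  pairs <- expand.grid(c1 = .consonants, c2 = .consonants,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$c1 != pairs$c2, ]
  # stable, readable order: by first then second consonant in class order
  pairs <- pairs[order(match(pairs$c1, .consonants), match(pairs$c2, .consonants)), ]
  out <- purrr::pmap_dfr(pairs, function(c1, c2) {
    ccv_spec(c1 = c1, c2 = c2, frequency_table = frequency_table)
  })
  out
}

#' The 15 plosive-plosive CCVs analysed for effort and timing
#'
#' The analysis set: a voiced plosive (b, d, g) followed by any other plosive.
#' Initial unvoiced plosives leave no spectral trace before their release and
#' are excluded.
#'
#' @inheritParams ccv_spec
#' @return A 15-row tibble of CCV records.
#' @export
analysis_ccvs <- function(frequency_table = ccv_frequency_table()) {
  inv <- ccv_inventory(frequency_table)
  dplyr::filter(
    inv,
    .data$cluster_type == "plosive-plosive",
    .data$c1 %in% .voiced_plosives
  )
}

#' Voicing subgroups of the 15 analysis CCVs
#'
#' `fully_voiced_ccvs()` returns the six CCVs whose folds vibrate throughout
#' (both plosives voiced); `devoiced_ccvs()` the nine with an unvoiced second
#' plosive, which require active glottal abduction (a devoicing effort).
#' `place_subgroups()` returns the consonant-interchanged place pair used for
#' the tract-effort asymmetry: (bda, bga, dga) vs (dba, gba, gda).
#'
#' @return Character vectors of CCV labels.
#' @export
fully_voiced_ccvs <- function() {
  c("bda", "bga", "dba", "dga", "gba", "gda")
}

#' @rdname fully_voiced_ccvs
#' @export
devoiced_ccvs <- function() {
  c("bca", "bta", "bpa", "dca", "dta", "dpa", "gca", "gta", "gpa")
}

#' @rdname fully_voiced_ccvs
#' @export
place_subgroups <- function() {
  list(
    forward = c("bda", "bga", "dga"),
    interchanged = c("dba", "gba", "gda")
  )
}

#' Packaged intra-word frequency table (synthetic)
#'
#' Corpus appearances per million words of each consonant pair inside Spanish
#' words. The values shipped here are a synthetic stand-in with the gross
#' structure of the real distribution: plosive-plosive pairs are uniformly
#' rare (f < 10, except "bta" which sits in the medium band), while
#' fricative-containing pairs span a much wider range. Users with corpus
#' counts can supply their own table to [ccv_spec()]/[ccv_inventory()].
#'
#' @return Tibble with columns `ccv` and `f` (per million words).
#' @export
ccv_frequency_table <- function() {
  pairs <- expand.grid(c1 = .consonants, c2 = .consonants,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$c1 != pairs$c2, ]
  label <- paste0(pairs$c1, pairs$c2, "a")
  m1 <- consonant_manner(pairs$c1)
  m2 <- consonant_manner(pairs$c2)
  both_plosive <- m1 == "plosive" & m2 == "plosive"
  # deterministic pseudo-frequencies: rare for plosive-plosive, wide otherwise
  h <- (match(pairs$c1, .consonants) * 7 + match(pairs$c2, .consonants) * 3) %% 11
  f <- ifelse(both_plosive, 0.2 + 0.5 * h, 2 + 18 * h)
  f[label == "bta"] <- 18      # the one plosive-plosive pair above the low band
  f[label %in% c("sta", "spa", "sca")] <- 120 + 40 * h[label %in% c("sta", "spa", "sca")]
  tibble::tibble(ccv = label, f = f)
}
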