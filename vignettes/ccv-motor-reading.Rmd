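---
title: "Linking silent-reading fixations to speech-motor effort: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking silent-reading fixations to speech-motor effort: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccvreading)
```

## The question and the design

When we read silently, how much of the speech-motor machinery is engaged?
One way to probe this is to present letter strings that are pronounceable
but essentially absent from the language — consonant-consonant-vowel
trigrams (CCVs) such as *bda* or *gta* — and to ask whether eye-movement
measures collected during **silent** reading covary with articulation
measures collected when the same items are read **aloud**.

`ccvreading` implements that analysis end to end: a biophysical model of
the vocal tract that turns each CCV into an articulatory-effort score; a
spectro-temporal landmark extractor that measures phonatory timing from
audio; standard reading measures from fixation events; the study's
exclusion cascade; and the regression battery that ties the blocks
together. A calibrated generator simulates the complete experiment so
that every stage is testable without any data download.

The design it emulates: 9 consonants (plosives *b d g p t c*, fricatives
*s f j*) give 9 × 8 = 72 CCVs (same-consonant pairs excluded). Each
block (oral, silent) presents 180 stimuli as 30 screens of 6 CCVs: the
15 *analysis* CCVs — a voiced plosive followed by any other plosive,
whose releases are sharply visible in a spectrogram — three times each,
and the other 57 CCVs two or three times (21 × 3 + 36 × 2 = 135, one
valid tiling of the "two or three times" rule). Thirty participants give
30 × 2 × 180 = 10,800 trials; discarding the two screen-edge items of
every 6-item line leaves 7,200 interior trials.

## The vocal-tract model and the effort functional

The tract is described by its cross-sectional area along the axis from
the glottal end (`x = 0`) to the lips (`x = L`):

$$A(x,t) = \frac{\pi}{4}\left[\Omega(x) + q_1(t)\varphi_1(x) +
q_2(t)\varphi_2(x)\right]^2 \prod_k \left[1 - c_k(x)\,m(t -
t_k)\right]$$

The squared factor is the vowel substrate: a neutral diameter profile
$\Omega(x)$ deformed along two spatial modes as the coefficients
$q_i(t)$ ramp linearly from 0 to the vowel /a/ targets over the
utterance duration $T$. Each plosive contributes an occlusion factor
whose spatial profile $c_k$ and temporal activation $m$ both reach 1 at
the occlusion place and time, closing the tract there exactly:
$A(x_k, t_k) = 0$.

The effort of an utterance adds a laryngeal and a tract term:

$$E = E_0 + \int_0^T \int_0^L \left|A(x,t) - A_\Omega(x)\right| \,
dx \, dt$$

with $E_0 > 0$ iff some phoneme is devoiced (the glottis must be
actively abducted to interrupt voicing) and
$A_\Omega = (\pi/4)\,\Omega^2$ the neutral area.

### Parameter choices

* **Geometry.** The empirical $\Omega, \varphi_1, \varphi_2$ come from
  an orthogonal decomposition of MRI data that is not publicly
  tabulated, so the package ships a parametric stand-in
  (`default_tract_geometry()`): $L = 17.5$ cm on 101 points,
  $\Omega(x) = 1.8 - 0.4\cos(\pi x/L)$ cm,
  $\varphi_1 = \cos(\pi x / L)$, $\varphi_2 = \cos(2\pi x/L)$, /a/
  targets $q_1 = 0.9$, $q_2 = 0.95$. These targets concentrate the
  vowel deformation in the velar region (the strong tongue-body
  constriction of /a/), leave a moderate alveolar deformation and keep
  the lips nearly neutral. That deformation gradient is what produces
  the place asymmetry — closing early at a place whose area will later
  deform a lot costs more than closing there late — and with it the
  orderings `E(bda) < E(dba)`, `E(bga) < E(gba)`, `E(dga) < E(gda)`.
  Any user geometry table can be swapped in via
  `read_tract_geometry()`.
* **Occlusion places.** Bilabial at the lips ($x = L$), alveolar at
  $0.85\,L$, velar at $0.60\,L$; both lie exactly on the packaged grid
  so closures are exact to machine precision.
* **Occlusion shape.** $m$ is a symmetric raised cosine of total width
  `w = 120` ms (only the unit peak is constrained by the physics; an
  asymmetric activation/deactivation split is a possible refinement),
  and $c_k$ a Gaussian of half-width `sigma = 1` cm.
* **Timing.** $T = 490$ ms (the mean CCV duration; we read the printed
  "490 s" as milliseconds), first closure at $t_1 = 100$ ms (only the
  inter-closure interval matters for the comparisons), inter-closure
  interval $\Delta t = 200$ ms by default, swept over 100-300 ms in
  25-ms steps to cover every degree of gesture overlap. Time step 1 ms.
* **Integration.** Trapezoidal rule on both axes; halving both grid
  steps moves the tract term by well under 0.1%.
* **Devoicing constant.** $E_0$ is not observable. It is calibrated
  once (`calibrate_devoicing_effort()`) so that the devoiced-group mean
  total effort exceeds the fully-voiced-group mean by the same ratio as
  the measured normalised-transition group means (41.3 vs 38.2 in
  $10^{-2}$ units). This is a calibration, not a measurement, and it
  only sets the scale of the laryngeal term relative to the tract
  integral.

## Phonatory timing from audio

Three variables are read off each oral utterance: the vocal onset, the
utterance duration $T$, and the consonantal transition $\tau$ between
the release landmarks of the two consonants, normalised to
$\tau' = \tau / T$ to wash out speech-rate differences. The
pre-phonatory delay $\Delta$ is the vocal onset minus the first-fixation
onset on the item.

The detectors work on a 25-ms Hann / 5-ms hop short-time spectrum (the
exact settings used in manual annotation are unspecified; these are
standard plosive-phonetics values and all thresholds are relative, so
detection is gain-invariant):

* **Vocal onset** — sustained low-band (75-300 Hz) RMS energy above an
  adaptive threshold between the record's noise floor and peak level,
  back-tracked to where the envelope left the floor. All-zero or
  noise-only records raise a `no-onset` error.
* **Plosive releases** — peaks of the broadband (1-8 kHz) spectral-flux
  onset function, refined at sample level to the half-maximum crossing
  of the high-band envelope; events closer than 30 ms merge. Search
  runs left to right from just after the vocal onset; ties break to the
  earliest time.
* **Fricatives** — sustained (≥ 50 ms) 2-6 kHz noise; the
  plosive-fricative transition ends at the noise onset, the
  fricative-plosive transition starts at its abrupt offset. No rule
  exists for fricative-fricative clusters, which error as unsupported.

Mispronunciations and multiple production attempts are metadata flags
(as in manual screening), not acoustic detections.

## Reading measures

Fixations are assigned to areas of interest (AOIs) by point-in-rectangle
lookup. The screen layout is 6 trigrams of 24-px monospaced characters
separated by 4 blank characters, centred at 1024 × 768. Each AOI is the
72-px character box expanded by one character width per side — expanding
by the full half-gap would make neighbouring AOIs touch, so the middle
two character widths of every gap stay unassigned — and ±24 px (≈ 1°)
vertically.

For a target item: **FFD** is the duration of the first fixation on it;
**FPRT** sums its fixations from first entry until any *other* item is
fixated (unassigned fixations neither extend nor terminate the first
pass); **TFT** sums all its fixations. Hence FFD ≤ FPRT ≤ TFT, and TFT
is FPRT plus re-reading time. A first fixation that begins before
stimulus onset is clipped to it. The first fixation is taken in
first-pass order (the standard definition). The first and last items of
each screen are discarded against edge effects.

## Quality control

The cascade runs in a fixed order, and its report conserves counts:

1. participants whose mispronounced fraction exceeds 45% *strictly* are
   removed entirely;
2. unfixated, mispronounced, and multi-attempt trials are removed;
3. a single (non-iterated) pass removes any trial with FFD, FPRT, TFT,
   $\Delta$ or $\tau'$ outside its participant's own
   $\bar{x} \pm 2s$ band, with $s$ the sample SD ($n-1$ denominator)
   and the bounds fixed before any removal. A zero SD keeps everything;
   fewer than 3 valid values skip that variable for that participant.

Intra-word frequency is discretised as low ($f < 10$ per million),
medium ($10 < f < 50$), high ($f > 50$); the boundary values go to the
lower bin (the source descriptions disagree between strict and
inclusive inequalities, and no analysis CCV sits on a boundary). The
packaged frequency table is synthetic — corpus mining is out of scope —
with the documented gross structure: plosive-plosive pairs uniformly
rare except *bta*, fricative-containing pairs wide-ranging.

## Statistics

All tests are two-sided at $\alpha = 0.01$ (chosen against multiple
comparisons; no further correction). The battery is: multiple OLS of
$\Delta$ and each ocular variable on $\tau'$ and repetition number
(oral block); OLS of each ocular variable on repetition (silent block);
one-way ANOVA across frequency levels; and, across blocks, weighted
least squares of per-CCV silent-block ocular means on oral-block
$\tau'$ means with weights $1/\mathrm{SEM}(y)^2$ — the stated weighting
is "by the statistical errors", and inverse variance of the dependent
means is the standard reading. With 15 CCVs the slope test has 13
degrees of freedom. The pooled two-sample t-test and the equal-variance
ANOVA are the classical forms (`var.equal = TRUE`).

## What the generator emulates — and what it does not

`build_design()` reproduces the trial arithmetic exactly;
`simulate_timing()` draws per-trial variables with the calibrated group
structure:

* per-CCV $\tau'$ means of 0.373 (*bda, bga, dga*), 0.390 (*dba, gba,
  gda*) and 0.413 (unvoiced second consonant) — subgroup means are the
  only observable constraint, so means are uniform within subgroups;
  users with trial-level data can refit the table;
* a trial-level $\tau'$ SD of 0.08, a compromise back-solved from the
  printed group standard errors at the study's sample sizes (different
  subgroups imply 0.067-0.111);
* $\Delta = 0.30 + 0.30\,\tau' + N(0, 0.15)$ s;
* silent-block $\mathrm{FFD} = -180 + 1100\,\tau' + N(0, 60)$ ms (mean
  ≈ 260 ms). The slope was calibrated so that the cross-block weighted
  regression recovers a positive, significant coupling in at least 90%
  of seeds at the study's sample size — the package's design target for
  the sign-recovery property — which makes the typical recovered
  t-statistic somewhat larger than the observed one;
* oral-block FFD flat at 260 ms (transitions do not feed back into
  oral eye timing), and first-pass / total-time extras of 130 / 110 ms
  shrinking 20 ms per repetition, truncated at zero so FFD ≤ FPRT ≤ TFT
  holds trial by trial; FFD carries no repetition effect;
* flag rates of 2% (unfixated), 2% (mispronounced), 1% (multi-attempt)
  — realistic light screening; the two excluded-participant events of
  the original cohort are not simulated by default.

`realize_fixations()` inverts the gaze bookkeeping (its streams score
back to the requested measures exactly), `synthesize_ccv_audio()`
plants landmarks in audio with a voiced buzz, 10-ms broadband bursts
and a harmonic vowel tail over a configurable noise floor, and
`simulate_lip_trace()` builds accelerometer envelopes that rise half a
second before phonation, peak at the vocal onset, and scale down two
orders of magnitude for silent reading (plus a null-activity subgroup).

What passing tests on these data do **not** show: the generator draws
independent Gaussian noise around linear couplings — real fixation
durations are right-skewed and serially dependent, real spectra contain
formant transitions and speaker variability that the buzz-and-burst
fixture does not, and the synthetic frequency table carries no corpus
structure. The generator validates the *machinery* (detectors,
bookkeeping, filters, inference), not the empirical claims.

## Numerical and degenerate-input conventions

* Occlusion factors are clamped at 1 so the area stays non-negative for
  any gesture set; closures on-grid are exact zeros.
* `tau = T` normalises to 1 with a warning; negative $\Delta$ is
  returned with its sign (a QC flag, not an error); missing timestamps
  propagate `NA` so the trial is excluded later.
* The envelope window shrinks at trace edges (no zero padding), so
  constant traces are preserved; non-unique alignment maxima use the
  earliest, with a warning.
* Equal-SEM weighted regression reduces to OLS at machine precision;
  infinite SEMs contribute zero weight; zero SEMs are errors.
* Binocular recordings are reduced to the eye with more valid samples
  per trial before fixation events reach the package.

## Problem sizes used by the test suite

The suite exercises the full design (30 × 2 × 180) where arithmetic is
asserted exactly, and smaller cohorts (6-28 participants) where only
distributional structure matters: 200 synthetic utterances for landmark
recovery at 20 dB SNR, 10,000 null pairs for the t-test type-I rate,
500 random triples for the fixation round trip, and 10-20 seeds for
sign-recovery properties. The acceptance script regenerates a 28 × 3
oral block and reports the four $\tau'$ group means on the printed
$10^{-2}$ scale.

## Known limitations

* The anatomical modes are parametric stand-ins; modelled effort values
  are meaningful for signs and orderings, not absolute magnitudes, and
  the headline effort-transition correlation magnitude on the real
  data is therefore out of reach by construction.
* Effort is defined only for plosive-plosive CCVs (no closure model
  for fricatives).
* No forced alignment, phone recognition or f0 tracking: the detectors
  answer exactly the three timing questions above.
* The deposited-dataset replication entry point
  (`replicate_deposited_analysis()`) expects the public dataset
  converted to the package's trial-table format; it is not bundled.

## A worked micro-example

```{r example, eval = FALSE}
design <- build_design(n_subjects = 28, seed = 1)
records <- simulate_timing(design, default_calibration(), seed = 1)
clean <- qc_cascade(records)$records

aggregates <- cross_block_aggregates(clean)
wls_regression(aggregates, "ffd", "tau_norm")

cfg <- default_effort_config()
effort_table(analysis_ccvs(), cfg)
```
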