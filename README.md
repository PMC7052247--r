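# ccvreading

Does silent reading engage the speech-motor system? `ccvreading` is an
analysis pipeline for experiments that probe this with pronounceable but
essentially non-occurring letter strings: consonant-consonant-vowel
trigrams (CCVs) such as *bda* or *gta*, read once aloud and once in
silence while eye movements, audio and lip acceleration are recorded.
The package is written for psycholinguists and speech scientists who
want to run, simulate, or audit this kind of cross-block analysis.

## What it computes

**Articulatory effort.** The vocal tract is modelled by its
cross-sectional area from the glottal end (x = 0) to the lips (x = L),

    A(x,t) = (pi/4) [Omega(x) + q1(t) phi1(x) + q2(t) phi2(x)]^2
             * prod_k [1 - c_k(x) m(t - t_k)]

a vowel substrate deformed along two spatial modes, times one occlusion
factor per plosive that closes the tract exactly at the occlusion place
and time (A(x_k, t_k) = 0). The effort of an utterance is

    E = E0 + \int_0^T \int_0^L | A(x,t) - A_Omega(x) | dx dt

with a laryngeal constant E0 > 0 iff a phoneme is devoiced, plus the
integrated deformation of the tract away from its neutral shape
A_Omega = (pi/4) Omega^2.

**Phonatory timing.** From each oral recording: the vocal onset
(sustained low-band energy), the utterance duration T, and the
consonantal transition tau between the two release landmarks (broadband
spectral-flux bursts; cluster-specific rules for fricatives), rate
normalised to tau' = tau / T. The onset delay Delta is vocal onset minus
first-fixation onset.

**Reading measures.** First fixation duration (FFD), first-pass reading
time (FPRT) and total fixation time (TFT) per CCV, from fixation events
assigned to areas of interest, with screen-edge items discarded.

**Inference.** The study's exclusion cascade (strict 45% mispronunciation
cut, flagged-trial removal, per-participant mean ± 2 SD outlier filter),
then OLS regressions per block, frequency ANOVAs, and the cross-block
SEM-weighted regression of per-CCV silent-block ocular means on
oral-block tau' means — all two-sided at alpha = 0.01.

**Synthetic experiments.** A calibrated generator reproduces the full
design (72 CCVs, 6 per screen, two blocks, 10,800 trials) and the
published group structure of tau', so every stage runs and is tested
without any data download. See the methods vignette
(`vignettes/ccv-motor-reading.Rmd`) for every parameter and its
rationale.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a
thin script over the package functions, writing tab-separated tables
under `results/`:

```sh
Rscript analysis/01_simulate.R        # design + calibrated trial table
Rscript analysis/02_extract_timing.R  # landmark detectors vs planted truth
Rscript analysis/03_qc.R              # exclusion cascade
Rscript analysis/04_stats.R           # regression battery
Rscript analysis/05_effort.R          # effort model + closure-interval sweep
Rscript analysis/06_lip_dynamics.R    # oral vs silent lip amplitudes
```

A reference run (seed 20200302) prints, among others:

```
generated 10800 trials (30 subjects x 2 blocks x 180 stimuli)
tau recovery: median |error| = 0.44 ms, max = 1.18 ms
        stage                                reason n_removed n_remaining
 participants             mispronounced > threshold         0       10800
       trials unfixated/mispronounced/multi-attempt       380       10420
     outliers     outside participant mean +/- 2 SD      1386        9034
cross-block SEM-weighted regressions (silent ocular vs oral tau'):
 response     term estimate  se statistic df        p significant
      ffd tau_norm      735 120      6.13 13 3.59e-05        TRUE
     fprt tau_norm      455 133      3.42 13 4.53e-03        TRUE
      tft tau_norm      460 153      3.01 13 1.00e-02       FALSE
tau' on E_total (SEM-weighted): t(13) = 7.96, p = 2.4e-06
oral/silent amplitude ratio: 99.4 (median), 99.5 (mean)
```

Reading this: the acoustic detectors recover planted transitions to
sub-millisecond accuracy; the cascade retains 9,034 of 10,800 trials;
silent-block first fixations rise with the oral-block consonantal
transition (positive weighted slope on 13 degrees of freedom), the
strongest coupling among the ocular measures; modelled effort and
measured transitions agree in sign across the whole closure-interval
sweep; and silent-reading lip movement sits two orders of magnitude
below oral reading.

Programmatic equivalent:

```r
library(ccvreading)
bundle <- run_analysis(pipeline_config(seed = 7, n_subjects = 30))
bundle$cross_block      # weighted FFD/FPRT/TFT vs tau' slopes
bundle$effort_vs_tau    # modelled effort vs measured transitions
write_results_bundle(bundle, "results")
```

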