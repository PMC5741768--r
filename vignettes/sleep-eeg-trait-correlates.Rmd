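---
title: "Mapping sleep-EEG spectral correlates of a cognitive trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sleep-EEG spectral correlates of a cognitive trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepspectra)
library(dplyr)
```

## The analysis problem

Full-night polysomnography yields, per subject, a multichannel EEG, a
hypnogram (one sleep-stage code per 20 s epoch) and an artifact mask (one
flag per 4 s segment). The question this package addresses is
mass-univariate: at which scalp derivations and in which frequency bands is
sleep EEG spectral power associated with a psychometric trait score — here a
composite nonverbal intelligence score on the Raven APM scale (RES) — and
does that association differ between the sexes?

The pipeline is:

1. **Calibration.** Each recording device colors the spectrum with its analog
   frequency response. Feeding known sinusoids (40 and 355 µV, on a grid from
   0.05 to 100 Hz) through the device and comparing recorded to generated
   amplitude yields an *amplitude reduction rate* per frequency; a natural
   cubic spline interpolates between probed frequencies and power is
   corrected by `1/rate(f)^2`. The amplitude of a recorded calibration tone
   is estimated by a least-squares sinusoid fit at the known frequency
   rather than an FFT peak read, so probe frequencies that fall between FFT
   bins are estimated without leakage bias.
2. **Spectra.** Artifact-free 4 s windows (2 s steps) of the requested state
   (NREM pools NREM2 and slow-wave sleep; REM stands alone) are mean-detrended,
   Hann-tapered, Fourier-transformed, and the one-sided periodogram densities
   averaged. A 4 s window makes 0.25 Hz bins the native resolution; the
   analysis grid is fixed at 1.00–40.00 Hz inclusive, 157 bins. Per
   electrode, power is divided by total 1–40 Hz power and log10-transformed
   (*relative log power*), which cancels global gain and lets subjects with
   different amplifier scales be compared.
3. **Scoring.** Raven APM raw scores are used as-is; CFT raw scores pass
   through pluggable norm tables (CFT raw + age → IQ → normal percentile →
   APM raw equivalent); when both tests are available the two values are
   averaged. Real norm tables are copyrighted, so the package ships clearly
   labelled synthetic monotone tables for testing.
4. **Correlation mapping.** For each sex and state, the age-partial Pearson
   correlation between RES and relative log power is computed in every
   electrode × bin cell: both variables are residualized on age and the
   residuals correlated, with two-tailed p from
   `t = r * sqrt((n-3)/(1-r^2))` on `n − 3` degrees of freedom. Subjects
   missing an electrode are excluded cell-wise for that electrode only.
5. **Multiple comparisons.** Two complementary corrections:
   the Rüger-area decision procedure over contiguous frequency runs of
   nominally significant cells, and a seeded max-statistic permutation test.
6. **Dimorphism.** At the maximal-association cell of every area of
   potential significance, the female and male correlations are compared
   with Fisher's r-to-z test,
   `z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`.

## Design choices that were genuinely open

**Window geometry.** Analysis windows never cross an epoch boundary, a stage
change or an artifacted 4 s segment: the artifact grid is 4 s, so a window
bridging two segments would be partially contaminated, and bridging epochs
would mix stages. A clean 20 s epoch therefore yields 9 windows (starts at
0, 2, …, 16 s); an epoch with its middle segment rejected yields 3 + 3.

**Rüger-area fractions.** An area of potential significance is a maximal
contiguous run of bins with at least one cell at `p < 0.05`; areas narrower
than 4 bins (1 Hz) or with all significant cells on one electrode are
discarded as narrow-band artifacts. The area is declared significant when at
least 50% of its cells reach `p < 0.025` or at least one third reach
`p < 0.05/3` (the exact fraction, not its 0.016 rounding). The fractions
are taken over **all** cells of the area, not only the nominally significant
ones. This is deliberate and load-bearing: conditional on `p < 0.05`, null
p-values are uniform on (0, 0.05), so the fraction below 0.025 among
significant cells is 1/2 in expectation *regardless of the data*, and a
significant-cells denominator would declare pure-noise areas significant
about half the time. With the all-cells denominator, Markov's inequality
bounds the null probability that a fraction `1/k` of cells passes
`p < alpha/k` by `alpha`, which is what makes the rule a test. Our null
simulations confirm the difference: decided areas in essentially every null
cohort under the first reading, none under the second.

**Permutation family.** The max-statistic correction residualizes trait and
spectra on age, permutes subject labels of the trait residuals, and records
the per-permutation maximum |r| within a family; corrected
`p = (1 + #{max ≥ |r_obs|}) / (n_perm + 1)`, which is never zero and floors
at `1/(n_perm+1)`. The default family is *electrodes within a frequency
bin* (the correction is run separately per bin); a whole-grid family is
available and is uniformly stricter. The permutation engine requires a seed;
identical seeds reproduce corrected p-values bit-exactly.

**Channel imputation.** The permutation step needs a complete matrix, so
spectra are first restricted to the 12 non-temporal channels and missing
ones imputed on the relative log-power scale: Fz from mean(F3, F4), Cz from
mean(C3, C4), anything else from the average of its available neighbours in
an editable adjacency table (`inst/extdata/neighbors_1020.csv`). The
temporal arc (F7, F8, T3, T4, T5, T6) is dropped rather than imputed — those
channels have neighbours on one side only. Imputed series are means of log
values, so their antilogs need not sum to exactly 1; the spectra validator
makes normalization checking optional for that reason.

**Fisher variance.** The r-to-z comparison uses the ordinary `n − 3`
variance even though the correlations are age-partial; an option subtracts
the covariate count from each `n` for users who prefer the stricter
accounting. The difference is negligible at these sample sizes.

**Degenerate inputs.** Zero-variance residuals mark a cell missing rather
than erroring; all-zero PSDs are an error; zero bins inside an otherwise
positive PSD are floored at a configurable epsilon (default 1e−12 relative
power) with a warning before the log.

## What the synthetic cohorts emulate

`generate_cohort()` draws cohorts with known ground truth. Defaults mirror
the study conditions the pipeline targets: 68 females and 83 males, ages
uniform on 17–69, the 18-channel 10–20 montage, and an electrode-failure
pattern matching the reported failure counts (26 lost electrode series
across subjects, concentrated on Fp1). Spectra are generated directly in
relative log-power space: a per-state 1/f baseline shape (with a sigma bump
in NREM), plus a smooth Gaussian field with exponentially decaying
correlation across electrodes (length 1.5 montage steps) and frequency
(length 2 Hz), scaled to a between-subject SD of 0.15 log10 units; age loads
negatively on slow and positively on fast power (max |r| 0.25) and
negatively on the trait (r = −0.3), so the partial-correlation machinery is
actually exercised. Planted effects add a trait loading ρ at chosen
state × band × electrode cells; the default plants the female-only effect
structure of the motivating study — REM delta/theta negative and REM beta
positive fronto-centro-parietally, NREM alpha/sigma positive posteriorly —
at ρ = 0.45, a simulation operating point giving good power at n = 68, with
males null everywhere.

Two technical notes. Planted ρ is the *model-implied age-partial
correlation*: the construction adds `ρ·e` (e the age-independent trait
component) plus `sqrt(1−ρ²)` units of field noise, so the partial
correlation is exactly ρ before closure. Because relative power must sum to
one, each electrode's values are renormalized after sampling; this
compositional closure would attenuate planted correlations by several
percent, so the noise field is projected orthogonal to the first-order
direction of the closure normalizer, after which the attenuation is second
order and empirically below 0.01 in r units. The planted band's electrode
sets are wide (12 of 18 channels for the REM effects) because the all-cells
Rüger fractions of a focal effect dilute below the 1/3 threshold — matching
the widespread topography the method is designed to detect.

What the generator does **not** emulate: realistic sleep architecture,
non-Gaussian or heavy-tailed power distributions, spindle events or other
transients, inter-night variability, and any male effect. Passing tests
demonstrate that the statistical machinery recovers what it is designed to
recover under a smooth Gaussian compositional model — not that the
biological findings themselves replicate.

## Operating characteristics, at the sizes we run them

The test suite and the acceptance script verify, among other things:

- the window planner equals a brute-force enumerator on 1000 random
  stage/mask configurations;
- the Rüger area finder equals an exhaustive oracle on every pattern of a
  3-electrode × 4-bin grid plus thousands of random 3 × 8 patterns;
- grid-family permutation FWER on null cohorts (n = 60, 10 electrodes × 157
  bins, 1000 permutations) lands at 5% ± 2 percentage points over 400 null
  cohorts, in both the test suite and the acceptance script;
- with the default planted cohorts, the female REM beta effect is flagged by
  *both* corrections in well over 80% of cohorts while decided male areas
  stay at or near zero (100 cohorts in the suite, 40 in the script);
- a device-colored white-noise spectrum, corrected by a curve estimated from
  synthetic sweeps, is flat within 5% in 5 Hz bands; the analytic
  correct-after-apply round trip is exact to 1e−9.

These problem sizes are the package's chosen simulation scale: large enough
for the stated tolerances (binomial SE at 400 cohorts is about 1.1 points),
small enough to run routinely.

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(states = "REM"), seed = 42)
report <- run_pipeline(co$spectra, co$res, co$subjects,
                       states = "REM", n_perm = 1000, seed = 43)
report            # Rüger areas, permutation ranges, dimorphism tests
plot_spectrocorrelogram(report$corrmaps$REM_F)
autoplot(report$perm$REM_F)
```

## Known limitations

- EDF support is classic EDF only (16-bit, no EDF+ annotations).
- Spectra must arrive on the 157-bin grid; recordings whose 4 s window is
  not an integer number of samples are rejected rather than resampled.
- The Rüger procedure is a decision rule, not a p-value; only the
  permutation branch yields corrected per-cell p-values.
- Norm tables shipped with the package are synthetic and non-normative;
  real scoring requires the user's licensed tables in the documented CSV
  schemas.
- The generator's Gaussian copula cannot express asymmetric or heavy-tailed
  trait-power couplings.
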