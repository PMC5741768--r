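# sleepspectra

Mass-univariate analysis of full-night sleep-EEG power spectra against a
psychometric trait score, with device calibration, sex-stratified
age-partial correlation mapping and two families of multiple-comparisons
control.

## What it does, for whom

Sleep researchers relating quantitative EEG to a stable trait (here a
composite nonverbal intelligence score, RES, on the Raven APM scale) face a
chain of nuisances before the statistics even start: amplifier frequency
responses differ between devices, spectra must come only from artifact-free
epochs of the right sleep state, test scores arrive on different instruments
(Raven APM, CFT), and the resulting electrode × frequency grid of tests —
12–18 electrodes × 157 bins of 0.25 Hz between 1 and 40 Hz — is massively
multiple and spatially/spectrally correlated. `sleepspectra` implements that
whole chain as composable, data-frame-first functions returning tibbles.

The statistical core, per sleep state (NREM = NREM2 + SWS, and REM) and per
sex:

- **Age-partial correlation map.** For each electrode *e* and bin *f*,
  r(e, f) is the Pearson correlation of the age-residualized trait and the
  age-residualized relative log power, with two-tailed p from
  t = r·√((n−3)/(1−r²)) on n − 3 degrees of freedom.
- **Rüger areas.** A contiguous run of bins with at least one cell at
  p < 0.05 (discarding runs < 1 Hz wide or confined to one electrode) is
  declared significant when ≥ 50% of its cells reach p < α/2 or ≥ 1/3 reach
  p < α/3 — a Markov-bound global test over the area.
- **Max-statistic permutation.** Trait residuals are permuted across
  subjects; each permutation's maximum |r| over a family (electrodes within
  a bin, or the whole grid) yields corrected
  p = (1 + #{max ≥ |r_obs|})/(n_perm + 1), on spectra first imputed onto a
  complete 12-channel montage (Fz ← mean(F3, F4), Cz ← mean(C3, C4),
  others from configured neighbours).
- **Sexual dimorphism.** At each area's maximal-association cell, female
  and male correlations are compared with Fisher's r-to-z:
  z = (atanh(r₁) − atanh(r₂))/√(1/(n₁−3) + 1/(n₂−3)).

A seeded synthetic-cohort generator with planted effects (and a realistic
missing-electrode pattern) makes every stage testable without clinical data.

## Worked example

```r
library(sleepspectra)

co <- generate_cohort(cohort_spec(states = "REM"), seed = 42)  # 68 F / 83 M
report <- run_pipeline(co$spectra, co$res, co$subjects,
                       states = "REM", n_perm = 1000, seed = 43)
report
```

Abridged output of that exact call:

```
<sleep_run_report>
  states: REM | sexes: F+M | n_perm=1000 seed=43 family=bin
  Rueger areas:
    REM/F 2.25-6.00 Hz: 138 sig cells on 14 electrodes, p<a/2 42.7%, p<a/3 39.9% -> significant (max |r| -0.55 at Fp2 5.25 Hz)
    REM/F 12.25-26.00 Hz: 455 sig cells on 17 electrodes, p<a/2 41.4%, p<a/3 39.3% -> significant (max |r| 0.71 at F4 15.75 Hz)
    REM/F 27.25-28.25 Hz: 7 sig cells on 3 electrodes, p<a/2 2.2%, p<a/3 1.1% -> not significant (max |r| 0.30 at F4 27.50 Hz)
    REM/M 7.25-9.50 Hz: 12 sig cells on 8 electrodes, p<a/2 3.3%, p<a/3 2.2% -> not significant (max |r| -0.35 at O1 8.75 Hz)
  permutation-significant ranges:
    REM/F 2.25-5.25 Hz (C3, C4, Cz, F3, F4, Fp1, Fp2, Fz, P3, P4)
    REM/F 12.25-19.75 Hz (C3, C4, Cz, F3, F4, Fp1, Fp2, Fz, O1, O2, P3, P4)
  sexual-dimorphism tests (Fisher r-to-z):
    REM Fp2 5.25 Hz: r_F=-0.55 (n=67) vs r_M=-0.05 (n=81), z=-3.39, p=0.0007
    REM F4 15.75 Hz: r_F=0.71 (n=68) vs r_M=0.29 (n=81), z=3.52, p=0.0004
```

Reading it: the generator planted female-only effects (REM delta/theta
negative, REM beta positive, ρ = 0.45). Both planted bands surface as
Rüger-significant female areas (the p<α/2 and p<α/3 percentages are the
stricter-threshold fractions over all cells of each area) and as
multi-channel permutation-significant ranges matching the planted bands;
the handful of narrow male and high-frequency female areas of potential
significance are all rejected by the decision rule. The Fisher tests at
each area's maximal-association cell show the female-dominant effect
sizes. `tidy()`/`glance()` extract
the tables; `plot_spectrocorrelogram()` and `autoplot()` draw the
per-electrode correlation curves (with the critical-r line at p = 0.05) and
the corrected-p map.

Lower-level stages are ordinary functions: `read_edf()`,
`read_hypnogram()`, `plan_windows()`, `compute_psd()`,
`relative_log_power()`, `estimate_reduction_rate()`, `build_curve()`,
`correct_psd()`, `score_subjects()`, `build_corrmap()`,
`find_ruger_areas()`, `permutation_correct()`, `fisher_compare()`.

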