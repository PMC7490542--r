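# hairspec

Spectral analysis of longitudinal hair cortisol, and mechanistic models of
why cortisol wanders on a timescale of a year.

## The problem

Hair grows about 1 cm per month and passively records circulating
cortisol, so a 12-cm hair sample cut into six 2-cm segments is a
retrospective, two-month-resolution record of roughly one year of a
person's cortisol. Using it quantitatively requires dealing with a strong
systematic decline of measured cortisol along the hair and with tens-fold
between-person baseline differences. `hairspec` is for researchers who
have (or simulate) such segment-resolved cohorts and want to ask: after
correcting the decline, do cortisol fluctuations carry excess power at
slow frequencies — and can a feedback model of the HPA
(hypothalamus–pituitary–adrenal) axis explain it?

## What the package computes

* **Decline correction** — per individual *i*, OLS in log space,
  `ln C_ij = ln B_i − α_i t_ij + r_ij`, giving the baseline `B_i`, decline
  coefficient `α_i` (1/year) and decline-corrected residuals `r_ij`; also
  a non-parametric (cohort-median-profile) variant.
* **Fluctuation size** — per-participant CV of the normalized series,
  cohort-averaged, with assay noise removed in quadrature:
  `cv_corr = sqrt(cv² − cv_assay²)`.
* **Fourier spectrum** — one-sided DFT amplitudes at 1, 2, 3 cycles/year
  (`A_k = 2|X_k|/N`, Nyquist `|X_{N/2}|/N`), cohort means with bootstrap
  SEM, a shuffled-segment null re-run through the identical correction
  (power-preserving, so the band is calibrated), permutation and normal
  p-values, Cohen's d, Cliff's delta, and the 1-vs-3 amplitude ratio.
* **Seasonality** — pooled 12-month cosinor of the corrected residuals
  with projection-corrected regressors (unbiased despite the per-person
  detrend), and its removal.
* **HPA models** — stochastic simulation of the classic hormonal cascade
  and of the gland-mass model, where secreting-tissue masses `P`
  (corticotrophs) and `A` (adrenal cortex) turn over on a timescale
  `1/b` of weeks. The slow subsystem's eigenvalues
  `(b/3)(−3 ± i√3)/2` give a damped oscillation of period `4π√3/b`
  (≈ 370 days at a 17-day turnover): period = 2π/frequency turns
  week-scale biology into a year-scale resonance. `virtual_hair()` cuts
  simulated cortisol into segments so model output flows through the
  identical analysis pipeline.
* **Synthetic cohorts** — `generate_cohort()` emulates the full
  statistical structure (30-fold baselines, exponential decline, 14%
  assay noise, 15% seasonality, 22% slow fluctuations with selectable
  spectrum) so everything is testable without any data download.

## Worked example

```r
library(hairspec)

cohort <- generate_cohort(cohort_params(rng_seed = 2))   # 55 participants
fits   <- fit_cohort_decline(cohort)

su <- cohort_decline_summary(fits)
fl <- fluctuation_cv(fits, assay_cv = 0.14)
spec <- cohort_spectrum(fits, n_boot = 1000, n_shuffle = 1000, seed = 3)
cf <- fit_cosinor(fits)
lin <- linearize_hpa(hpa_params())
```

Formatted with `sprintf`, those objects print:

```
mean alpha  : 2.09 +/- 0.12 /year
baseline spread: 50-fold
fluctuation CV: 18% raw, 11% noise-corrected
amplitude ratio 1/3: 2.56 +/- 0.30
1/yr vs null: p = 0.001 (permutation), d = 4.9, delta = 0.99
seasonality: 15% peaking at month 1.4
gland-mass resonance: period 370 days (damping 0.87)
```

Reading this: the fitted decline (2.09 ± 0.12 /year) and the ~15%
seasonal amplitude recover the generator's truth (2.2, 15%); the 1/year
Fourier bin towers over the shuffled null (permutation p ≈ 0.001, Cliff's
delta ≈ 0.99) because the default synthetic cohort carries
low-frequency-heavy (`1/f`) biological fluctuations; and the linearized
gland-mass model places its resonance at 370 days, i.e. the year-scale
rhythm that makes such fluctuations mechanistically plausible. An
end-to-end run — cohort (CSV, synthetic, or simulated hormones) →
correction → spectrum → cosinor → JSON report — is one call:
`run_pipeline(run_config(...))`, or the thin CLI in
`inst/scripts/hairspec-cli.R`.

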