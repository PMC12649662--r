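---
title: "Subject-specific HRFs for task fMRI: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-specific HRFs for task fMRI: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrf)
```

## The problem

Task fMRI estimates neural activity by regressing the BOLD signal on a
predicted response: the stimulus train convolved with a hemodynamic
response function (HRF). The standard choice is a fixed "canonical"
double-gamma shape, usually flanked by its temporal and dispersion
derivatives to absorb small shifts in onset and width. But the HRF is a
vascular quantity. Aging and vascular risk factors (hypertension, diabetes,
obesity, arterial stiffening) change its peak amplitude, timing, and width,
so a fixed shape misattributes vascular differences to neural ones —
particularly worrying for studies comparing age or risk groups.

The alternative this package implements end to end is the *subject-specific
HRF* (sHRF): estimate each person's response empirically from a strong
sensory stimulus (a flashing checkerboard), then substitute that curve for
the canonical basis in the first-level GLM of the task of interest (here, a
two-run associative memory encoding task with subsequent-memory labels).
Because no raw data from the motivating study are available, the package is
driven entirely by a synthetic-data generator that reproduces the study's
cohort structure, acquisition parameters, and signal model, so every stage
is testable.

## Models

### HRF family

The canonical HRF is the difference of two gamma densities (peak delay 6 s,
undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6) on a 32 s
support, rescaled to unit maximum. These shape parameters are the de facto
standard defaults of the software ecosystem the approach targets; the
temporal derivative is a finite difference with respect to a 1 s onset
shift and the dispersion derivative a finite difference with respect to the
peak-dispersion parameter (step 0.01).

Ground-truth subject HRFs use the same double-gamma template, re-parameterized
so the simulated metrics are direct functions of the parameters: the
template is time-warped and scaled such that the curve's maximum equals
`peak_amplitude`, its argmax equals `peak_time`, and its FWHM scales
linearly with `width_scale`. This makes parameter recovery checkable by
round-trip through `hrf_metrics()` rather than by comparing gamma
parameters.

### FIR estimation of the sHRF

The checkerboard run is deconvolved with a finite impulse response model:
12 free coefficients spanning a 21 s post-stimulus window (bin width
1.75 s), plus an intercept and outlier-volume regressors. A joint F-test
over the 12 coefficients (extra sum of squares against the nuisance-only
model) screens voxels at a liberal p < .05 within the occipital mask; the
peak-F voxel's coefficients are the sHRF, placed at bin centers
(`t0 = 0.875` s). Ties are broken to the lowest voxel index for
determinism. The estimate is ordinary least squares without prewhitening;
the F-test's size under the generator's AR(1) + drift noise is verified by
simulation rather than assumed.

Two consequences of the binning are worth knowing. First, the FIR
coefficient is an average of the response over a 1.75 s window, so the
estimated peak is attenuated by a deterministic, phase-dependent amount (up
to about 5% for typical widths); the tests bound this by the worst-case
window-average loss computed from the true curve instead of a round number.
Second, whether the study's window used exactly 1.75 s bins or TR-locked
1.72 s bins is not stated; `fir_spec()` exposes both.

### Substitution and the encoding GLM

Stimulus sticks are placed on a microtime grid of 16 bins per TR and
convolved with each basis function; regressors are read out at reference
bin 8 (mid-acquisition). The same convolution routine generates the
synthetic BOLD signal, so the generator and the model agree exactly on the
intra-TR sampling phase — this is what makes the forward/inverse
consistency check (noiseless recovery of region multipliers to 1e-6) an
exact identity rather than an approximation, and it makes the FIR
bin-center convention self-consistent (the mid-TR readout offset of
~0.86 s matches the 0.875 s bin-center label).

`substitute_basis()` resamples the 12-point sHRF onto the microtime grid
over the full 32 s support, anchoring it at zero before the first bin
center and after the last sample, and rescales to unit maximum so that
parameter estimates are on a common scale across basis kinds. Substituting
the canonical curve itself reproduces the canonical-only fit to machine
precision (a regression test). The substituted model uses a single sHRF
regressor per condition — whether the original analysis retained
derivatives alongside the sHRF is unstated, and the single-regressor
reading matches the substitution of the basis matrix itself; derivatives
can be re-added by building a custom `basis_set`.

The correct-trials-versus-baseline contrast takes the remembered
condition's primary basis column only (derivatives treated as nuisance),
the standard convention when single parameter estimates are compared across
analyses.

### Dampening: two mechanisms, one direction

The motivating observation is that sHRF-based estimates are closer to zero
than canonical ones in both task-positive and task-negative regions. In the
simulation this arises through two distinguishable mechanisms:

1. **Model misfit.** When true HRFs deviate substantially from canonical in
   latency and width, an *accurately specified* subject curve explains more
   variance than canonical + derivatives (the Taylor expansion the
   derivatives embody breaks down for shifts beyond roughly a second). The
   residual-variance comparison in the acceptance suite plants latency
   6.5–7.5 s and width 1.2–1.4 for this reason; for small deviations the
   derivative flexibility compensates and the comparison is a wash.
2. **Estimation shrinkage.** The *estimated* sHRF carries shape noise,
   which inflates the regressor's norm after unit-maximum rescaling and
   shrinks the fitted betas — dampening. This is the mechanism that
   operates at the cohort's default noise level, and it also implies the
   estimated-sHRF model does *not* beat canonical + derivatives on residual
   variance (the derivatives' extra degrees of freedom win); the package
   reports both rather than conflating them.

### Vascular risk scores

Indicators (4 binary diagnoses, 8 continuous biometrics, plus obesity
derived as BMI > 30) are factor-analyzed with principal-axis extraction
(iterated communalities from squared multiple correlations) and direct
oblimin rotation (gamma = 0, gradient-projection algorithm). Binary
indicators enter the Pearson correlation matrix; tetrachoric correlations
are a known alternative not implemented. Factor scores are loading-weighted
averages of standardized indicators, normalized by the sum of absolute
loadings, so protective indicators (negative loadings, e.g. physical
activity) reduce the risk score. Both the extraction and the rotation are
implemented in the package because no installed dependency provides them;
they are validated by recovery of planted loading structures and planted
inter-factor correlations, and by the invariance of communalities under
oblique rotation.

**Factor retention.** The retention rule compares observed
correlation-matrix eigenvalues with those of same-shape independent normal
data. The classical comparison against the *mean* simulated eigenvalue is
not calibrated: on pure noise the observed and mean-simulated first
eigenvalues are draws from the same distribution, so a spurious factor is
retained about half the time. `parallel_analysis()` therefore defaults to
the 95th-percentile reference (retaining 0 factors on noise and 3 on a
planted 3-factor cohort), with `reference = "mean"` available as the
classical reading.

### Group statistics

The mixed ANCOVA (analysis type within subject; age, risk, and age x risk
between) is implemented by the mean/difference decomposition, exact for two
within-subject levels: between effects are tested on subject means, within
effects on canonical-minus-sHRF differences, each with centered continuous
covariates. With no covariates the analysis-type F equals the squared
paired t identically, which the tests assert. Effect sizes are partial eta
squared, `SS_effect / (SS_effect + SS_error)`. Whole-brain comparisons use
per-voxel paired t-maps thresholded at voxel p < .001 with a 100-voxel
extent rule over 26-connected components (6-connectivity is available);
the cluster labeling is checked exactly against an independent flood-fill.
ROI analyses use alpha = .05 uncorrected, as in the motivating design. The
reported per-group simple slopes are evaluated at user-specified ages since
the original cut points are not stated.

## What the generator emulates — and what it does not

The generator reproduces: three age groups (20–30, 50–62, 63–74 years,
group sizes 19/24/20); risk-indicator prevalences and biometric
means/SDs per group from the published participant table (young
hypertension prevalence is exactly zero, as observed); a latent 3-factor
risk structure with configurable inter-factor correlations (defaults 0.39,
0.53, 0.68, inside the reported range — age acts on indicator
means/thresholds directly so the configured correlations are exactly the
generating ones); an age slope of −0.004 per year on HRF peak amplitude
with between-subject SD 0.15 (chosen so that the slope's standard error at
n = 63 matches the reported 0.001); peak time 5.5 ± 0.8 s and width
1 ± 0.15 (the between-subject variability reported for healthy adults);
memory accuracy 0.57/0.39/0.31 ± 0.17/0.14/0.07 by group; checkerboard
timing (20 × 1 s events, uniform 8–16 s ITIs at TR 1.72 s); encoding
timing (2 runs × 32 × 3 s trials, 1.72–17.20 s jitter, 279 volumes per run,
558 total); task-positive and task-negative region multipliers on a small
labeled grid (10 voxels per region); and AR(1) (coefficient 0.3, innovation
SD 0.15) + sinusoidal drift + rare global spikes recorded as outlier
volumes.

It does **not** emulate: spatial anatomy, smoothing, or normalization
(voxels are exchangeable within regions, so cluster analyses on this grid
are demonstrations of the machinery, not of spatial inference); motion or
field artifacts beyond global spikes; regional HRF heterogeneity within a
subject (every region shares the subject's HRF, which is exactly why the
true-curve substitution fits best — in real data the occipital estimate
may transfer imperfectly to other regions); and any coupling between
memory accuracy and trial-level neural amplitude beyond their shared age
dependence, so brain-behavior correlations are weaker here than in real
data. Passing tests therefore establish that the estimation and inference
machinery is correct under the stated signal model, not that the
scientific conclusions transfer to any particular dataset.

One stated acquisition detail is internally inconsistent: a 20-trial run
with mean 12 s ITIs spans roughly 260 s, which cannot fit the stated "73
volumes over two minutes". The generator follows the trial structure and
derives the volume count from the generated timings plus the 21 s
estimation window (about 165–180 volumes).

## Numerical choices and degenerate inputs

* Latency ties break to the earliest sample; FWHM uses linear interpolation
  between samples and errors (or returns `NA` under
  `undefined_fwhm = "na"`) when the curve does not cross half-maximum on
  both sides of the peak.
* All times are seconds; voxel and volume indices are 1-based.
* Event onsets snap to the nearest microtime bin (TR/16 ≈ 0.1075 s).
* Peak-voxel selection errors explicitly when no occipital voxel passes the
  F threshold; `run_pipeline()` excludes such subjects with a logged
  reason (mirroring motion exclusions in real studies) rather than
  aborting or silently dropping them.
* Rank-deficient designs error with the offending column names.
* The oblimin rotation runs gradient projection to a 1e-6 gradient norm
  with step halving; principal-axis iteration stops at a 1e-7 communality
  change and errors with diagnostics if 200 iterations do not converge.
* Welch's t-test is used for the within- vs cross-subject alpha comparison
  (the variance of 72 ordered cross pairs differs from that of 9 within
  values); both groups need at least two values, since a sample variance is
  undefined at n = 1.
* Cronbach's alpha errors on zero total-score variance (e.g. exact
  sign-reversed runs) rather than returning an infinity.

## Problem sizes

The test suite and the acceptance script run the full method at reduced but
non-trivial sizes chosen to keep Monte-Carlo error well below the asserted
tolerances: 10,000 generated designs for the ITI mean, 10,000 noise voxels
for the F-test size, 2,000–4,000 simulations for model-term null rates, 50
subjects for FIR recovery and for the misfit/dampening comparison, 600
subjects for age-slope recovery, 300 for factor retention, and the study's
own 19/24/20 cohort for the end-to-end workflow in `analysis/`.

## Known limitations

* The sHRF is estimated at a single occipital voxel and assumed to apply
  brain-wide; the simulation shares one HRF across regions and so cannot
  probe regional transfer error.
* The residual-variance advantage of the sHRF holds when the substituted
  curve is accurate; with the single-run FIR estimate at default noise the
  canonical + derivatives model fits better by that metric even while its
  estimates are systematically larger in magnitude.
* Estimation noise attenuates the age effect on the *estimated* HRF peak at
  n = 63 relative to the generating slope; the acceptance suite verifies
  slope recovery on realized true curves at n = 600.
* Pearson correlations for binary indicators; no tetrachoric option.
* No permutation-based cluster inference; the extent rule is the stated
  fixed threshold.
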