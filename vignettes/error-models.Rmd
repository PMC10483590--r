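---
title: "Calibrating intensity uncertainties for 3D electron diffraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating intensity uncertainties for 3D electron diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsigma)
```

## The model

An integrated reflection intensity from a pixelated detector carries a
counting-statistics uncertainty. Per pixel, `edsigma` uses the variance
model

    var(c) = gamma * G * c + psi

with gain `G` (counts per incident electron), cascade factor `gamma >= 1`
(intensity-dependent excess over Poisson) and pixel factor `psi` (the
variance of a dark image, in counts²). Propagating independent pixels
through background-subtracted integration `I = sum_S c_i - n_S * mean(rim)`
gives

    Var(I) = sum_S var(c_i) + (n_S / n_rim)^2 * sum_rim var(b_j).

These Poisson-based e.s.u.'s systematically understate the scatter actually
observed among symmetry-equivalent 3D ED intensities, whose dominant
"errors" under a kinematical refinement are dynamical-scattering effects,
radiation damage and instrument drift. The calibration therefore inflates
them with the three-parameter SDFAC/SDB/SDADD correction

    sigma'(I_hl) = s_fac * sqrt( sigma_hl^2 + s_B * max(I_ref, 0) + (s_add * I_ref)^2 )

where `I_ref` is either the unweighted inclusive mean of the group of
equivalents (model 2) or its largest member intensity (model 3). `s_fac`
is a dimensionless scale absorbing intensity-independent errors such as
gain miscalibration; `s_B` (counts) absorbs errors proportional to the
intensity; `s_add` (dimensionless) is a fractional term with no direct
physical meaning, kept for flexibility. Negative references contribute
nothing to the linear term, so background-overshoot intensities cannot
produce negative variances. In model 3 the maximum enters **only** the
sigma correction; deviations are always measured from the mean — measuring
them from the maximum would make every deviation non-positive, which no
symmetric quantile sequence could match.

Model 0 applies no adjustment. Model 1 replaces the counting e.s.u. by the
Bessel-corrected sample standard deviation of the n equivalents, with a
lookup table (ten equal-count intensity bins × 0.2 Å⁻¹ resolution shells,
cell value = arithmetic mean of member e.s.u.'s, nearest populated shell in
the same intensity decile as fallback) for reflections measured once.
Model 1 needs high redundancy; on low-redundancy data its n = 2 groups pin
half the deviations at ±1/√2 — the constant steps visible in normal
probability plots — and the refinement degrades accordingly.

## Normalized deviations and the fitting objective

The normalized deviation of measurement l of reflection h is the plain
ratio

    delta_hl = (I_hl - <I>_h) / sigma'_hl,

zero by convention for reflections measured once (the inclusive mean makes
the numerator vanish). `normalized_deviations()` implements exactly this
quantity, and for a two-fold group under model 1 it gives ±1/√2 to machine
precision.

The plain deltas are *not* standard normal even with perfect e.s.u.'s: the
empirical reference mean is correlated with the measurement, so delta_hl
is Gaussian with null standard deviation

    c_hl = sqrt( 1 - 2/n + sum_j sigma'_hj^2 / (n^2 sigma'_hl^2) )

(1/√2 at n = 2 with equal sigmas; analogous closed forms hold for the
exclusive and inverse-variance-weighted reference means, both available as
`reference_mode` options). Matching the pooled order statistics of the
plain deltas to N(0,1) quantiles would therefore place the optimum away
from the generating parameters whenever redundancy is low — the very
regime the method targets. The fit consequently standardizes every delta
by its exact null scale, and the calibration's reported plot shows these
standardized deviations; at n = 5000 groups the post-fit best-fit line has
slope 1.00 and intercept 0.00.

The misfit is

    D = sum_i ( z_(i) - q_i )^2,   q_i = qnorm( (i - 0.5) / N ),

with the `(i - 0.5)/N` plotting position by default (`i/(N + 1)`
available). Minimization runs over the decoupled variance composition
`u = s_fac²`, `v = s_fac²·s_B`, `w = (s_fac·s_add)²` — a bijection that
straightens the curved s_fac-vs-s_B valley the simplex would otherwise
track poorly — with a Nelder-Mead simplex and re-sorting supercycles:
minimize at fixed ordering, re-sort, repeat. Re-sorting can only lower D
(rearrangement inequality), so D never increases across accepted steps.

Two numerical choices matter and are deliberate:

- **Initialization.** By default the simplex starts from a restricted
  maximum-likelihood estimate of (u, v, w) computed from the within-group
  residual likelihood (group means profiled out, with the REML term for
  the estimated mean). The quantile misfit is nearly flat along
  u ↔ v when counting variances are close to proportional to intensity,
  and a pooled order-statistic objective is insensitive to minority
  subpopulations, so a consistent start decides which valley the polish
  lands in. Explicit starting values are honoured when supplied
  (`calibration_config(init = ...)`); convergence from (1, 0, 0) is also
  robust in well-identified settings.
- **Convergence.** Supercycles stop when the relative change of D falls
  below `tol_d` (default 1e-7), with a 12-cycle default budget; ordering
  stability is judged through D because near-tied deviations can swap
  ranks indefinitely without moving it, and D stationary to 0.1% per cycle
  is reported as converged. Re-sorts keep unlocking micro-improvements far
  below the statistical noise of the plot, so a larger budget changes the
  parameters by well under 1% of the corrected variance.

## Outlier rejection

Tukey's quartile rule flags deviations outside
`[Q1 - k*IQR, Q3 + k*IQR]` (type-7 interpolated quartiles, default
k = 1.5; both fences and flags are invariant under positive affine
transformations). For a group of exactly two equivalents a flagged member
drags its partner: with two measurements there is no telling which is
wrong. `esu_calibrate()` alternates fitting and rejection: the first pass
screens the uncorrected data, each fit excludes current outliers, the
fitted correction is applied to all measurements, and the fences are
re-evaluated until the parameters settle (to 1% on the corrected-variance
scale) and the number of outliers stops changing — count stability rather
than set identity, because equivalent borderline sets can oscillate
without information content.

When outliers are excluded, the surviving deviations are a fence-censored
sample. Matching them against complete-normal quantiles would push the fit
to deflate tail sigmas (stretching the censored extremes toward the
expected extremes of a full sample), and each rejection pass would then
flag more points than the last. The fit therefore matches survivors
against the quantiles of the normal truncated at the *nominal* fence
`z = qnorm(0.75) * (1 + 2k)` (≈ 2.70 at k = 1.5, per-side mass 0.35%). On
clean simulated data the procedure then flags ≈ 0.7% of measurements —
the nominal Tukey false-positive rate — and stops after two or three
passes; with 5% injected gross errors (20× inflation) it captures ≈ 85%
of them while recovering the generating parameters.

## What the synthetic generator emulates

`synthetic_spec()` encodes the study conditions under which the package
validates itself:

- true intensities follow the acentric Wilson (exponential) law, mean
  `wilson_scale = 1000` counts (a centric option exists);
- multiplicities are drawn from a distribution with substantial mass at
  n = 1 (0.25) and n = 2 (0.30), the low-redundancy profile typical of
  low-symmetry or incomplete 3D ED data sets where a quarter of unique
  reflections may be measured only twice;
- d* is uniform on 0.05–1.6 Å⁻¹, the usual resolution range of such data;
- counting sigmas follow `sqrt(max(I, 0) + 2500)`: Poisson in counts plus
  a 2500-counts² dark/readout floor (50-count rms, typical of integrating
  CCD/hybrid detectors). The floor also keeps `s_fac` and `s_B`
  statistically separable — with purely intensity-proportional counting
  variance the two are exactly collinear and no estimator could split
  them;
- measurement errors are Gaussian with standard deviation
  `corrected_sigma(sigma0, I_ref, true_params)`, where `I_ref` is the true
  intensity (`sigma_reference = "true"`, consistent with a mean-referenced
  correction) or, via a fixed-point iteration, the realized group maximum
  (`"max"`, the premise of model 3);
- a configurable fraction of measurements has its error draw multiplied by
  `outlier_inflation` (default 20), preserving sign symmetry.

Passing tests on these data shows that the calibration machinery is
self-consistent under its own assumptions. Real 3D ED errors are *not*
independent Gaussians — dynamical deviations are systematic, correlated
across equivalents and frames, and asymmetric — so recovery on synthetic
data does not by itself demonstrate accuracy on experimental data; it
demonstrates that failures there would come from the error structure, not
from the estimator.

Validation scales: recovery and comparison suites run at 5000 unique
reflections (≈ 13 000 usable measurements), chosen so that parameter
sampling noise is a few percent; Monte-Carlo checks of the integration
variance use 10⁵ draws, giving ≈ 0.5% standard error on a variance.

## Model 2 versus model 3

With identical parameters, model 3's e.s.u.'s are never smaller than
model 2's (I_max ≥ ⟨I⟩). After independent fitting the relationship
reverses in the regime that motivates model 3: when the within-group
spread is dominated by the fractional term (variance ∝ I², emulating
dynamical-scattering errors; R_int ≈ 20%), the fitted model-3 parameters
are elementwise below the model-2 ones and model 3 leaves more reflections
above the I > 3σ(I) threshold. When the spread is instead dominated by the
linear `s_B` term, the elementwise ordering of the *parameter triple* is
not reproduced here — model 3's misspecification residue is absorbed into
its constant term — even though the corrected sigma curves still order as
expected for strong reflections. The observed-count comparison is the
robust signature; parameter-by-parameter comparisons inherit the valley
degeneracy discussed above.

A caveat on "observed" counts: once e.s.u.'s are inflated beyond counting
statistics, I > 3σ(I) no longer means "visible in the pattern", and
obs-based statistics are not comparable across error models. All-data
statistics (wR(all), GOF) are; `r_factors()` reports both.

## Known limitations

- Laue-class operator tables use fixed settings (unique axis b for 2/m,
  hexagonal axes, the -3m1 setting); other settings must be supplied as
  explicit operator lists.
- No per-frame scaling, absorption or resolution-dependent error terms
  beyond the model-1 lookup; reflections are grouped globally, not per
  frame.
- The fitted parameter triple is reported as found; in flat-valley regimes
  users should compare corrected-variance curves (`predict()`), not
  individual parameters.
- `r_factors()` requires externally supplied calculated structure factors;
  refinement itself is out of scope.
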