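# edsigma

Calibration of estimated standard uncertainties (e.s.u.'s) of integrated
reflection intensities from 3D electron diffraction (3D ED / MicroED) data.

## The problem

Counting statistics underestimate the true uncertainty of 3D ED
intensities: dynamical scattering, radiation damage and instrument
instability put far more scatter among symmetry-equivalent measurements
than the Poisson model predicts, with merging residuals R_int of 20% or
more. Kinematical refinement weights reflections by 1/σ², so structure
quality depends directly on how honestly σ(I) describes that scatter.

`edsigma` implements four error models, calibrated against the spread of
symmetry-equivalent reflections:

- **model 0** — counting-statistics e.s.u.'s, unchanged;
- **model 1** — the Bessel-corrected sample standard deviation of the n
  equivalents, with a 10-decile × 0.2 Å⁻¹ binned lookup table supplying
  e.s.u.'s to reflections measured only once;
- **model 2** — the three-parameter correction
  σ′ = s_fac · sqrt(σ² + s_B·⟨I⟩ + (s_add·⟨I⟩)²)
  (SDFAC/SDB/SDADD), with the unweighted inclusive group mean ⟨I⟩ as
  reference intensity;
- **model 3** — the same correction with the **largest** equivalent
  intensity I_max as reference. Because I_max ≥ ⟨I⟩, smaller correction
  parameters suffice, strong reflections are not over-penalized, and more
  reflections stay above the I > 3σ(I) "observed" threshold — the regime
  where the equivalent-intensity spread is large, as in 3D ED.

The three parameters are fitted by linearizing the **normal probability
plot**: normalized deviations δ = (I − ⟨I⟩)/σ′ are sorted and matched to
standard-normal quantiles Φ⁻¹((i−0.5)/N), minimizing the squared misfit D
with a derivative-free simplex and re-sorting supercycles. Gross outliers
are removed by iterated **Tukey fences** [Q1 − k·IQR, Q3 + k·IQR]
(k = 1.5), with the partner rule for two-fold groups. The package also
provides hkl file I/O (SHELX-style fixed width and free format),
equivalence grouping for the 11 Laue classes, pixel-noise variance
propagation for peak integration, merging statistics (R_int, R(obs),
wR(all), GOF) and a synthetic-data generator with known ground truth.

## Worked example

```r
library(edsigma)

spec <- synthetic_spec(n_groups = 2000,
                       true_params = error_model_params(1.3, 10, 0.05),
                       outlier_fraction = 0.02, seed = 21)
sim <- simulate_reflections(spec)
sym <- symmetry_setting(operators = list(diag(3)), add_friedel = FALSE)
groups <- group_equivalents(sim$measurements, sym)

fit <- esu_calibrate(groups, model = 2)
print(fit)
#> Error-model calibration (model 2, inclusive_mean reference)
#>   s_fac = 1.431, s_B = 8.15718, s_add = 0.0341618
#>   normal plot: slope 0.9996, intercept 0.0000, D = 1.737 (N = 5082)
#>   outliers: 265 of 5862 measurements; converged after 12 supercycle(s), 6 rejection pass(es)

adjusted <- apply_error_model(groups, model = 2, params = fit$params)
merged <- merge_groups(adjusted)
cat(sprintf("R_int = %.2f%%; %d of %d unique reflections observed\n",
            r_int(groups), sum(merged$observed), nrow(merged)))
#> R_int = 16.54%; 1625 of 2000 unique reflections observed
```

The data were simulated with true parameters (1.3, 10, 0.05) plus 2% gross
outliers; the fit recovers (1.43, 8.2, 0.034) and a normal plot with slope
1.000 and intercept 0.000 — the corrected deviations are standard normal.
The individual parameters trade off along a nearly flat valley of the
misfit (s_fac² absorbs s_B when counting variance is roughly proportional
to intensity), so the recovered *variance curve* σ′(I) is much closer to
the truth than the worst single-parameter relative error suggests;
`recovery_report(spec$true_params, fit$params)` tabulates both views.

`plot(fit)` draws the normal probability plot. A command-line front end
covering simulate/calibrate/apply/merge/stats/integrate lives in
`inst/cli/edsigma`, and `run_pipeline()` chains the whole reduction from
one YAML config.

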