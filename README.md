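# lumitox

Mixture-toxicity prediction for whole-cell *Aliivibrio fischeri*
bioluminescence inhibition assays.

## The problem

Recirculating aquaculture systems (RAS) for Atlantic salmon must keep a set
of chemical stressors — nitrite, un-ionized ammonia, copper, aluminum and
zinc — below recommended limits, and these stressors act *together*: their
combined toxicity is not read off any single-substance threshold. A
luminescent bacterium (*A. fischeri*) serves as a broad-spectrum sensor: the
fractional dimming of its light over a 5-minute exposure, normalised against
negative controls, is the toxicity response. `lumitox` provides the complete
analysis stack for such assays, for assay analysts and for anyone building
an early-warning water-quality monitor on top of one:

* **Dose-response fitting.** Four-parameter log-logistic (logit) curves
  `y = A_L + (A_H − A_L) / (1 + 10^(p (log₁₀ x_c − log₁₀ x)))` fitted to
  control-normalised inhibition (`fit_logit()`, a classed model object with
  `coef`/`predict`/`plot`/`summary`/`residuals`/`simulate` methods), and the
  exact inversion to effect concentrations
  `log₁₀ ECx = log₁₀ x_c + log₁₀(E/(100−E))/p` (`ecx()`).
* **Mixture models.** Concentration addition
  `ECx_mix = (Σ pᵢ/ECxᵢ)⁻¹` (`ca_ecx()`), independent action
  `E% = 100 (1 − Π(1 − Fᵢ(pᵢC)/100))` (`ia_effect()`, inverted numerically by
  `ia_ecx()`), and their linearised forms LCA/LIA — an OLS regression of
  observed log effect concentrations on the model-predicted ones
  (`linearize()`, `model_ec50()`).
* **Evaluation.** Model deviation ratio (`mdr()`, both conventions),
  relative deviation, additive/synergistic/antagonistic behaviour
  classification under the assay's MDR mapping (`classify_behavior()`), RMSE
  and MAE (`error_summary()`), and limit-based early-warning checks against
  the recommended Atlantic-salmon RAS water limits (`limit_alert()`).
* **Design.** Good-lattice-point uniform designs `U_n(n^s)`
  (`uniform_design()`), fixed-ratio mixture rays built from single-stressor
  curves (`rays_from_design()`), and dilution series (`dilution_series()`).
* **Synthetic data.** A seeded generator of plate-luminescence datasets with
  the assay's statistical structure and configurable mixture interaction
  (`sim_config()`, `simulate_single_plates()`, `simulate_mixture_plates()`),
  used by the test suite to validate every pipeline stage end to end.
* **I/O.** CSV readers/writers for plate, curve, ray and evaluation tables,
  tolerant of typeset scientific notation ("3.66 × 10−6"), plus the
  orchestration helpers `fit_plate_curves()`, `evaluate_plates()` and
  `check_water_limits()`.

The published single-stressor curve parameters, the seven reference mixture
rays and the water-quality limits ship as built-in reference data
(`reference_curves()`, `reference_rays()`, `water_limits()`).

## A worked example

```r
library(lumitox)

curves <- reference_curves(as_curves = TRUE)
print(curves$ammonia)
#> Four-parameter logit dose-response curve: ammonia
#>   slope p = 3.741, log10(xc) = -0.24315 (mg/L), limits [0, 100] %
#>   EC50 = 0.5713 mg/L

ecx(curves$ammonia, 10)                      # EC10 in mg/L
#> [1] 0.3175215
10^as_molar_curve(curves$ammonia)$log_xc     # EC50 in mol/L
#> [1] 3.354361e-05
```

The ammonia curve crosses 10% inhibition at 0.32 mg/L and its centre
(EC50) is 0.571 mg/L = 3.35e-5 M. Simulating an additive mixture experiment
for reference ray 1 and evaluating both linearised models:

```r
rays <- reference_rays(as_rays = TRUE)
cfg  <- sim_config(true_curves = curves, rays = rays["1"],
                   interaction_lambda = 1, noise_cv = 0.05, seed = 1)
plate <- simulate_mixture_plates(cfg)
evaluate_plates(plate, rays, curves)
#>   ray_id model     b0    b1 pearson_r ec50_pred_M ec50_obs_M   mdr deviation_pct behavior
#> 1      1   LCA -0.771 0.862     0.791    7.41e-06   8.67e-06 0.854         14.60 additive
#> 2      1   LIA -1.487 0.758     0.776    8.95e-06   8.67e-06 1.033          3.25 additive
```

Each row is one ray × model: the regression coefficients of the
linearisation, the model-predicted and observed (fitted) mixture EC50 in
mol/L, their ratio (MDR, predicted/observed), the relative deviation in
percent, and the behaviour class — here additive, as simulated. Checking
spot measurements against the salmon RAS limits:

```r
limit_alert(c("nitrite", "zinc"), c(0.05, 9e-4), unit = c("mg/L", "mM"))
#>   substance concentration_mg_L status threshold_mg_L
#> 1   nitrite           0.050000     ok             NA
#> 2      zinc           0.058842  alarm          0.053
```

Nitrite is below its 0.1 mg/L limit; 9e-4 mM of zinc converts to
0.0588 mg/L, above the 0.053 mg/L limit, so the alarm fires and the
triggering threshold is cited.

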