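---
title: "Mixture toxicity prediction for bioluminescence inhibition assays: models and methods"
author: "lumitox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture toxicity prediction for bioluminescence inhibition assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumitox)
```

## The assay and its response variable

*Aliivibrio fischeri* is a marine luminescent bacterium whose light output is
coupled to its metabolic state, which makes it a broad-spectrum whole-cell
toxicity sensor: stressors that interfere with its metabolism dim the light.
In the microplate protocol this package models, every well is read twice —
once at the moment the sample contacts the bacteria (`lum_t0`) and once after
five minutes of exposure (`lum_t5`) — and each plate carries negative-control
wells that receive only sample diluent. The response variable is the
control-normalised percent inhibition

$$ I = 100\left(1 - \frac{L_5/L_0}{C_5/C_0}\right), $$

where $L$ is the sample well and $C$ the negative control. Normalising by
each well's own $t_0$ read removes well-to-well differences in the amount and
fitness of bacteria; normalising by the control ratio removes the spontaneous
luminescence decay over the exposure window. Inhibition can be negative
(luminescence stimulation, e.g. hormesis); `inhibition_from_luminescence()`
and `plate_inhibition()` return such values unclipped and flag them, but the
dose-response fit excludes points below a configurable floor (default −10%)
because strong stimulation is outside the monotone model class.

This two-ratio normalisation is the minimal reading of a control-corrected
inhibition; no additional Microtox-style correction factor is applied.

## The dose-response model

Dose-response curves are four-parameter log-logistic ("logit") curves in
log10 concentration,

$$ y = A_L + \frac{A_H - A_L}{1 + 10^{\,p\,(\log_{10} x_c - \log_{10} x)}}, $$

with slope $p$, central concentration $x_c$ and inhibition limits
$A_L, A_H$. Inverting the curve gives the effect concentration

$$ \log_{10} EC_x = \log_{10} x_c + \frac{\log_{10}\!\big(E/(100-E)\big)}{p}, $$

so $EC_{50} = x_c$ exactly; `logit_effect()` and `ecx()` are exact inverses
of one another (the round-trip property is tested at $10^{-9}$).

**Parameters and defaults.** `fit_logit()` fixes $(A_L, A_H) = (0, 100)$ by
default — inhibition is already normalised to a 0–100% scale, and all the
built-in reference curves use these limits — with `fix_limits = NULL`
freeing all four parameters. Units (`mg/L`, `mM`, `M`) are explicit metadata
on every curve and conversion between them is a pure shift of
$\log_{10} x_c$ via the molar masses in `substance_registry()` (nitrite ion
46.005, NH₃ 17.031, Cu 63.546, Al 26.982, Zn 65.38 g/mol). Single-stressor
curves live naturally in mg/L; all mixture arithmetic is done in molar units,
and mixing units silently is an error.

**Numerical choices.** Fitting is Levenberg–Marquardt least squares with the
slope box-bounded to $[-50, 50]$. Starting values are the observed point
nearest half-effect for $\log_{10} x_c$ and the slope of a straight-line fit
to logit-transformed interior points for $p$; if that start fails (weakly
informative data can make the initial Jacobian singular), a coarse grid of
slope/centre combinations is tried in turn. A 95% confidence band of the
mean response is available from `predict(fit, interval = "confidence")` via
the delta method on the parameter covariance. Fits need at least four usable
points; all-constant inhibition is a degenerate-data error.

**Reference curves.** `reference_curves()` ships the published single-stressor
parameters. One anomaly is preserved deliberately: the published molar EC50s
of zinc and copper are cross-swapped with respect to their own logit
parameters (zinc's parameters reproduce the printed copper EC50, 1.22e-6 M,
and vice versa). The package does not decide which label is correct; tests
assert the cross-swapped pairing and `scripts/acceptance.R` reports both
parameter-derived values under explicit names.

## Mixture models

For a fixed-ratio ray with molar proportions $p_i$ (`mixture_ray()`):

* **Concentration addition (CA)** — shared mode of action:
  $EC_{x,mix} = \big(\sum_i p_i / EC_{x,i}\big)^{-1}$ (`ca_ecx()`). The
  result is always bracketed by the component ECx values, and splitting a
  component into identical pseudo-components leaves it unchanged (sham
  invariance); both properties are tested.
* **Independent action (IA)** — dissimilar modes of action:
  $E\% = 100\big(1 - \prod_i (1 - F_i(p_i C)/100)\big)$ (`ia_effect()`),
  with $F_i$ the component curve at its partial dose. IA gives effect from
  concentration; the effect concentration needed downstream is obtained by
  monotone bisection in log-concentration (`ia_ecx()`), tolerance $10^{-6}$
  effect-percent, initial bracket $[10^{-12}, 10]$ M expanded geometrically
  in both directions (shallow-sloped components can contribute
  non-negligible effect at very low doses, so downward expansion matters).
  Effects above the IA asymptote raise an unattainable-effect error.

**Linearisation (LCA / LIA).** `linearize()` regresses the observed log10
total concentrations on the CA- or IA-predicted log10 effect concentrations
at the same observed inhibition levels,
$pEC_{x,obs} = b_0 + b_1\, pEC_{x,CA/IA}$, by ordinary least squares. The
regression uses the observed inhibition levels of the dilution series (the
minimal reading of the source procedure); an optional `effect_grid` restricts
to levels inside a fixed range such as 5–95%. Observed points at or outside
0%/100% are excluded — their log-odds, hence their predicted ECx, is
undefined — and counted. `model_ec50()` then pushes the raw CA/IA EC50
through the fitted line: $10^{b_0 + b_1 \log_{10} EC_{50,CA/IA}}$.

## Evaluation: MDR, deviations, behaviour

The model deviation ratio (`mdr()`) is the quotient of predicted and
observed EC50. Both orientations occur in published summaries, so both are
supported and the convention is always recorded: the default is
predicted/observed; the published LCA column demonstrably uses
observed/predicted, and `evaluate_rays()` lets you choose per run.

`classify_behavior()` implements the assay's stated mapping: MDR above unity
alerts to antagonism, below unity to synergism, unity is additive — note
this is the reverse of the Belden convention common elsewhere in mixture
toxicology; the mapping here follows the assay's own definition. Because an
estimated MDR is never exactly 1, a configurable additive band (default
(0.5, 2)) is applied, and band edges are treated as alerts (non-additive):
an MDR sitting exactly on the boundary is already evidence of departure.

`relative_deviation()` is $100\,|pred - obs|/obs$ — the only formula that
reproduces the published deviation columns from their own EC50 pairs — and
`error_summary()` reports RMSE on the inhibition fraction scale plus mean
absolute error in percent. `limit_alert()` checks measured concentrations
against the recommended Atlantic-salmon RAS water limits
(`water_limits()`), using the lower bound of a recommended range as an
inclusive warning threshold and the upper bound as the alarm threshold.

## Experimental design

`uniform_design()` builds $U_n(n^s)$ tables by the good-lattice-point
construction: column $j$ uses generator $h_j$ (coprime with $n$), level
$((i\,h_j - 1) \bmod n) + 1$, so every column is a permutation of $1..n$
(tested for all valid $(n \le 31, s)$). `rays_from_design()` maps design
levels onto effect levels — by default a log-odds-equispaced EC5..EC95 grid
(`effect_level_grid()`) — and sets each component's top concentration to its
ECx at the assigned level, so each ray spreads the components' individual
potencies uniformly. `dilution_series()` expands a ray into the assay's
1–64 dilution series, preserving proportions exactly.

The seven published reference rays (`reference_rays()`) are shipped as data
rather than regenerated: the level-to-ECx mapping used to construct them is
not recoverable from the published material, so they are honoured as-is (and
their component sums reproduce the published totals within rounding).

## The synthetic-data generator

`sim_config()` + `simulate_single_plates()` / `simulate_mixture_plates()`
emulate the plate protocol so the whole pipeline can be exercised without
the unpublished raw data:

* $t_0$ luminescence is log-normal (default mean 2e5 counts, CV 0.1 —
  typical plate-reader magnitudes; the inhibition statistic is invariant to
  the baseline, so these defaults affect nothing downstream);
* $t_5 = t_0 \cdot d \cdot (1 - E/100)\cdot e^\varepsilon$ with control decay
  $d = 0.8$ over the 5-minute window and multiplicative log-normal noise
  $\varepsilon \sim N(0, \sigma)$, $\sigma = 0.05$ by default — luminescence
  counts are positive and heteroscedastic, which multiplicative noise
  captures and additive noise does not;
* negative controls have $E = 0$; with `noise_cv = 0` the normalisation
  recovers the true effect exactly (noiseless closure, tested);
* everything is reproducible from `seed`.

Single-stressor series default to 7 log-spaced concentrations between the
true EC5 and EC95 with 3 replicate wells; mixture rays use their dilution
series.

**Mixture interaction.** A simulated ray responds along a logit curve whose
slope is the numeric composite slope of the CA prediction (from its
EC25/EC75 chord) and whose EC50 is $\lambda \cdot EC_{50,CA}$
(`interaction_lambda`). $\lambda = 1$ is exact concentration addition; under
the assay's MDR mapping, $\lambda > 1$ yields MDR $= 1/\lambda < 1$ (read as
synergism) and $\lambda < 1$ MDR $> 1$ (antagonism). This single-multiplier
device is the simplest mechanism that gives the recovery tests a known
ground truth.

**What the generator does and does not emulate.** It reproduces the
two-timepoint control-normalised design, the dilution structure, and
positive heteroscedastic noise. It does not model between-vial bacterial
variability beyond the single noise term, hormesis at sub-toxic doses,
oxygen limitation, or time dynamics within the 5-minute window. Passing
recovery tests therefore demonstrate correctness of the estimators under the
stated statistical assumptions, not robustness to every artefact of real
plates.

**A structural limit worth knowing.** When component slopes are very
heterogeneous (the reference curves span 0.26–8.06), the CA prediction curve
is not itself a logit. Two consequences, both verified numerically: (i) a
logit approximation of the CA curve (the generator's truth) and the CA curve
itself disagree enough that the full fit → LCA → MDR chain is only exactly
additive-closed for homogeneous-slope mixtures — the package's closure test
uses one, and interaction recovery is asserted on the raw CA EC50 against
the fitted observed EC50, where closure is exact by construction; (ii) the
LCA linearisation absorbs any EC50 shift into its intercept, so the
LCA-corrected EC50 cannot itself detect interaction — which is why the MDR
is computed against the raw model prediction. Relatedly, because the LCA
regressor is computed from *observed* (noisy) inhibition, the linearised
EC50 carries an errors-in-variables attenuation: at the assay's 5% noise CV
its median recovery error is ~6–7% and does not shrink with replicates; it
falls to ~2% at a 2% noise CV with 5–95% effect trimming. The package's
tests assert these measured levels.

## Problem sizes used by the test and acceptance runs

Simulation-backed checks use 200 seeded replicates per scenario, 7- or
12-point series, and 1–3 replicate wells — enough for stable medians of the
recovery statistics while keeping a full run of suite plus acceptance script
under a minute on a single CPU.

## A worked example

```{r example, eval = FALSE}
curves <- reference_curves(as_curves = TRUE)
rays   <- reference_rays(as_rays = TRUE)

# simulate an additive mixture experiment for ray 1 and evaluate it
cfg <- sim_config(true_curves = curves, rays = rays["1"],
                  interaction_lambda = 1, noise_cv = 0.05, seed = 1)
plate <- simulate_mixture_plates(cfg)
evaluate_plates(plate, rays, curves)
```

## Known limitations

* The published regression coefficients for the seven rays cannot be
  recomputed without the unpublished raw inhibition series; they are treated
  as format examples, and the bundled reference tables are inputs, not
  regeneration targets.
* Hormesis is flagged, never modelled.
* The uniform-design constructor implements the good-lattice-point method
  only; designs are not optimised by discrepancy minimisation.
* `error_summary()`'s fraction-scale RMSE is a convention choice; the
  published summary error statistics cannot be reproduced from printed data
  and are not asserted anywhere.
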