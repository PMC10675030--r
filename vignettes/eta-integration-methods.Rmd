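---
title: "From aerial snapshots to seasonal evapotranspiration integrals: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From aerial snapshots to seasonal evapotranspiration integrals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etintegral)
```

## The estimation problem

A genotype screening trial flies a UAV a handful of times per season.
Each flight gives, per plot, RGB-derived biophysical observables and —
on the thermal dates — component temperatures of canopy and soil. The
quantity of agronomic interest is not the flux at flight time but the
season integral of daily actual evapotranspiration (ETa), split into the
vegetative phase (sowing to heading, GS55) and grain filling (heading to
physiological maturity, GS87), because grain filling is where
Mediterranean water limitation bites and where variety differences in
water use matter for selection.

The pipeline chains five models. Each is available as a standalone
function; `run_pipeline()` wires them together.

## 1. Biophysical observables from imagery

`compute_vari()` implements `(G − R)/(G + R − B)` on mean digital
numbers. The index needs no radiometric calibration, which is why an
RGB-only workflow is viable; its weakness is an undefined value where
`G + R = B` (flagged as an error, or masked in grid mode).
`compute_fc()` linearly rescales VARI between a bare-soil and a
pure-vegetation reference. The references are site- and sensor-specific
configuration — there is no universal value — and noisy references can
push the ratio outside [0, 1], so the result is clamped by default.
`plant_height()` is the masked mean of DSM − DTM with negative cells
floored at zero (terrain noise cannot make a canopy negative).

Thermal grids are calibrated with `calibrate_thermal()`, a two-point (or
least-squares) linear map through ground-target readings; this corrects
the bulk atmospheric and drift component and is idempotent once the
references match. Canopy and soil temperatures are separated by
thresholding the VARI grid. We use Otsu's histogram threshold
(`otsu_threshold()`, 256 bins) rather than a trained classifier: it is
deterministic, training-free, and testable against the definitional
optimum (the split maximising between-class variance). This replaces a
supervised classification step whose training data a reusable tool
cannot assume.

## 2. LAI: calibration and seasonal carrier

`fit_lai_regression()` searches all non-empty subsets of {PH, VARI, fc}
(seven OLS fits) and keeps the lowest BIC, defined as
`n ln(RSS/n) + k ln(n)` with `k` counting the intercept — the standard
profile-likelihood form; ties favour the smaller subset. Exhaustive
enumeration is exact and trivially cheap at three candidates, so no
stepwise heuristic is needed. Calibration data are ground LAI
measurements on a subset of plots; `run_pipeline()` holds out a random
validation set (default 8 observations, mirroring a 36:8 split of 44
micro-plots) and reports honest holdout R² and RMSE. Negative LAI
predictions are retained by default for model transparency; flooring at
0 is an option.

The seasonal carrier is the logistic curve
`LAI(DAS) = c / (1 + exp(−a (DAS − b)))` fitted per variety × treatment
to the flight-date LAI estimates (`fit_sigmoid_lai()`). Initialisation
is deterministic: `c₀` = maximum observation, `b₀` by inverse
interpolation at `c₀/2`, `a₀ = 4 / (t₈₀ − t₂₀)` from the 20–80% rise
interval. The Levenberg–Marquardt fit is bounded
(`a ∈ [1e-5, 5]`, `c ≤ 10·max(LAI)`) and retried from a fixed sequence
of perturbed starts before failing with diagnostics; because the
perturbations are a fixed grid, the fit is seed-insensitive. A logistic
carrier assumes no senescence decline in LAI; late-season ETa reduction
is carried by the stress coefficient instead (see §4), which is the main
structural assumption of the pipeline.

## 3. Potential and reference evapotranspiration

One full-form Penman–Monteith engine serves both roles, with
`Δ(Rn − G)` available energy, vapour-pressure-deficit aerodynamic term
`ρ cp VPD / ra`, and denominator `Δ + γ(1 + rs/ra)`; λ = 2.45 MJ kg⁻¹,
net radiation from the shortwave input with the FAO-56 net-longwave
parameterisation against the clear-sky envelope (latitude and day of
year are therefore inputs). `reference_et0()` evaluates it at the
reference surface (rs = 70 s m⁻¹, 0.12 m grass, albedo 0.23);
`potential_et()` at the actual canopy with `rs = rl / (0.5·LAI_eff)`,
`rl = 100 s m⁻¹`, `LAI_eff = max(LAI, 0.1)` (the floor keeps bare plots
finite), and aerodynamic resistance from the FAO log profile of the
actual height (`d = 2/3 PH`, `z_om = 0.123 PH`, `z_oh = 0.1 z_om`,
sensors at 2 m with a 0.5 m minimum margin above the canopy). Wind is
floored at 0.5 m s⁻¹ for resistance stability. By construction,
`potential_et()` at LAI = 20/7 and PH = 0.12 m *is* `reference_et0()`;
the implementation is cross-checked in the tests against an
independently transcribed FAO-56 oracle (agreement within 0.01 mm on
benchmark days).

## 4. Snapshot ETa: two-source energy balance and upscaling

`tseb_component_fluxes()` implements the TSEB variant that uses both
measured component temperatures (TSEB-2T). We chose it over the
Priestley–Taylor-initialised single-temperature variant because
high-resolution thermal imagery of small plots yields T_C and T_S
directly; the PT path is out of scope. Choices, all exposed as
arguments:

- radiation: single composite net radiation (albedo 0.23, emissivity
  0.98, incoming longwave estimated from air temperature and humidity
  when not measured), partitioned by exponential extinction
  `Rn_s = Rn exp(−κ LAI / √(2 cos θ))` with κ = 0.45 — the full
  four-stream canopy radiative transfer is deliberately folded into one
  Rn for desk-scale clarity;
- soil heat flux `G = 0.35 · Rn_s`;
- series resistance network: aerodynamic resistance with Monin–Obukhov
  stability (Dyer–Businger ψ functions, stable ζ capped at 1), canopy
  boundary-layer resistance `90/LAI · √(s/u_c)` with leaf size
  s = 0.02 m for wheat, soil-surface resistance `1/(0.004 + 0.012 u_s)`
  with the within-canopy wind decayed exponentially;
- the within-canopy aerodynamic temperature is the
  resistance-weighted mean of air, canopy and soil temperatures; H_c and
  H_s follow from the gradients, and LE_c, LE_s are budget residuals, so
  closure `(Rn_c + Rn_s) = H + LE + G` holds to machine precision on
  every run. Negative residual LE (non-physical midday condensation) is
  floored at 0 with the excess returned to the sensible term, preserving
  closure.
- the Obukhov length is iterated with 50:50 damping until it changes by
  < 1e-3 (or the inverse length by < 1e-6), capped at 50 iterations with
  a convergence flag.

`instantaneous_to_daily_eta()` upscales the snapshot latent heat by the
ratio of daily to flight-hour FAO-56 reference ET, with a
temperature-dependent latent heat of vaporization. The ET0-ratio method
(rather than constant evaporative fraction) is consistent with the
stress-coefficient framework: it assumes the crop/reference ratio at
flight time holds for the day.

## 5. Stress-coefficient interpolation and integration

`Ks = ETa/ETp` per flight (`crop_stress_coefficient()`). Ks is *not*
capped at 1 by default: snapshot energy-balance ETa can legitimately
exceed the Penman–Monteith potential (advection, ETp model bias), and a
silent cap would hide it; a cap is available as an argument.

`interpolate_ks()` assumes Ks = 1 from sowing to DAS 100 (early-season
water needs fulfilled; flights at or before 100 are rejected) and then,
by default, holds each flight's Ks piecewise-constant between the
floored inter-flight midpoints, the last flight's value running to
maturity. The midpoint convention is symmetric and deterministic; the
heading day belongs to the vegetative integral (the partition
`ETa_VEG + ETa_GF = ETa_total` must be exact, so the boundary convention
is fixed). The alternative `method = "linear"` interpolates Ks between
flights and continues the terminal inter-flight trend beyond the last
flight (floored at 0), on the premise that stress keeps progressing
through late grain fill; it is the better choice when the underlying
stress trajectory is believed smooth. Water productivity divides yield
by the season total (`GY / (10 · ETa)`), not a stage total.

## The synthetic-trial generator

`simulate_trial()` emulates a Mediterranean winter-wheat screening
season: 22 varieties × 2 water regimes × 3 blocks by default, December
sowing at 41.7° N, and the flight calendar of such trials — RGB at DAS
61, 81, 119, 131, 170 and thermal at 119, 131, 170 (mid-jointing,
around anthesis, grain filling). Weather is a seasonal sinusoid (mean
14 °C, amplitude 8.5 °C, coldest mid-January) with AR(1) noise,
humidity declining with temperature, autocorrelated cloudiness under the
clear-sky envelope, and sparse rainfall events rescaled to a 130 mm
season total; the implied season reference ET0 lands near 450 mm,
consistent with semi-arid Ebro-valley conditions. Sigmoid LAI parameters
(asymptote 4.8–7.5), heading at DAS 121–131 (GS55 precedes anthesis at
~131), maturity at DAS 172–182 and maximum height 0.7–1.0 m are drawn
per variety.

Stress truth is piecewise-linear: Ks = 1 up to heading, declining to a
variety-specific end value at maturity — 0.9–1.0 under full irrigation,
0.35–0.6 rainfed. Observations invert the pipeline's own maps: PH and fc
are deterministic functions of true LAI and VARI is solved from the
configured linear LAI map, so at zero noise the regression recovers the
truth exactly. Canopy temperature has two modes: `"linear"` (default)
raises T_C by 5 °C per unit (1 − Ks) — a minimal model adequate for
arithmetic checks of the observation model — while `"consistent"`
root-finds T_C so that the full snapshot chain (two-source balance plus
ET0-ratio upscaling) reproduces `Ks_truth · ETp` exactly. The consistent
mode exists because generator/pipeline consistency cannot hold through a
nonlinear energy balance with a linear temperature map; the zero-noise
recovery test uses it, paired with the linear interpolation scheme whose
function class matches the piecewise-linear truth. At the test sizes (6
varieties × 2 blocks), worst-plot recovery error of season cumulative
ETa is a few tenths of a percent, dominated by the discretisation of the
stress-onset kink between flights; the step scheme against the same
truth stays within the 5% discretisation bound checked separately.

Yields respond asymptotically to grain-filling ETa,
`GY = Ymax (1 − exp(−k (ETa_GF − offset))) · variety_effect + noise`,
with k = 0.008 mm⁻¹ and offset = 150 mm on the generator's own ETa_GF
scale so the response is neither linear nor saturated; TKW and grain
number share the saturating dependence.

What the generator does *not* emulate: spatial structure within the
field (no spatially correlated soil or microclimate), senescence
decline of LAI, Ks > 1 advective episodes, year-to-year weather
variance (one season per call), or measurement dropout. Passing tests
therefore certify the estimation chain's internal consistency and its
statistical behaviour under idealised noise — not robustness to the
full messiness of field campaigns.

## Trial statistics

Variance components use the ANOVA method of moments:
`σ²g = max(0, (MS_variety − MS_error)/r)` from the block + variety
model, and with ≥ 2 environments `σ²ge = max(0, (MS_V×E − MS_E)/r)`,
`σ²g = max(0, (MS_V − MS_V×E)/(r·e))`. Negative moment estimates are
truncated at zero, so H² is bounded in [0, 1]. REML was deliberately
omitted to keep the module dependency-light; at the balanced designs
targeted here the moment estimator is unbiased (verified by simulation
in the tests). Broad-sense heritability defaults to the
single-environment form `σ²g / (σ²g + σ²/r)`; the multi-environment
denominator `σ²g + σ²ge/e + σ²/(r·e)` sits behind `multi_env = TRUE`
since published trial tables commonly print the simple form even when
environments are defined. Percent treatment reductions are reported to
the nearest integer (full precision retained); water productivity cells
in summary tables are computed as means of per-plot ratios, not ratios
of means — the two differ and the choice is documented because bundled
summary tables are not always consistent with either convention.

## Numerical choices and problem sizes

- OLS via `lm.fit`; BIC ties break toward the smaller subset by
  enumeration order.
- Sigmoid fits: `minpack.lm::nlsLM`, 200 iterations, bounded, fixed
  restart grid; non-convergence is an explicit error carrying the
  starts.
- TSEB: wind floored at 0.5 m s⁻¹, canopy height floored at 0.05 m,
  in-canopy wind floored at 0.01 m s⁻¹; near-zero total sensible heat
  (< 0.1 W m⁻²) short-circuits to the neutral limit to avoid Obukhov
  blow-up.
- The consistent-mode generator brackets T_C in air temperature ± (−12,
  +25) °C and takes the boundary when the target daily ETa is outside
  the attainable range.
- Test and acceptance problem sizes are kept small — trials of 3–10
  varieties × 2–3 blocks, 100-replicate noise studies, 500-replicate
  variance-component simulations — chosen as the smallest sizes at which
  the statistical assertions are stable.

## Known limitations

The logistic LAI carrier cannot represent senescence; stage integrals
inherit any error in field-scored phenology; the ET0-ratio upscaling
assumes a stable diurnal crop/reference ratio, which fails under
afternoon advection; component-temperature separation degrades at full
canopy closure (no soil pixels — the caller must then fall back or
skip); and the piecewise-constant Ks default is a coarse carrier when
flights are sparse relative to the stress dynamics, which is exactly the
regime quantified by the 5% discretisation bound in the test suite.
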