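# etintegral

Season-long **cumulative actual evapotranspiration (ETa) integrals for
crop genotype trials**, estimated from a handful of aerial RGB and
thermal snapshots.

Surface-energy-balance models driven by UAV thermal imagery deliver ETa
at discrete flight dates only. For variety screening — ranking wheat
genotypes by water use and water productivity — what matters is the
*integral* of daily ETa over the season and over developmental stages
(vegetative vs grain filling). `etintegral` implements a complete
pipeline that carries a few snapshots across the whole season, plus a
synthetic-trial generator with known ground truth so that every stage is
testable without field data. It is aimed at crop physiologists,
phenotyping platforms and breeders working on drought adaptation.

## The method

For each plot and flight date, RGB imagery yields three biophysical
observables:

- greenness index `VARI = (G − R) / (G + R − B)` from the mean digital
  numbers;
- fractional cover `fc = (VARI_i − VARI_soil) / (VARI_veg − VARI_soil)`,
  clamped to [0, 1];
- plant height `PH` as the mean DSM − DTM difference over the plot.

Leaf area index is calibrated against ground truth with a multiple
regression selected by exhaustive BIC search over predictor subsets,
e.g. (a published calibration of this form)

```
LAI = 5.063 PH + 5.451 VARI − 1.661 fc − 1.071
```

and carried through the season with a logistic growth curve
`LAI(DAS) = c / (1 + exp(−a (DAS − b)))` fitted per variety ×
treatment. Daily **potential ET** uses Penman–Monteith with
canopy-dependent resistances (`rs = 100 / (0.5 LAI)`, aerodynamic
resistance from the log profile of the actual height); at `rs = 70
s m⁻¹` and 0.12 m height it reduces exactly to the FAO-56 grass
reference ET0.

Snapshot **actual ET** comes from a two-source energy balance with
measured component temperatures (TSEB-2T): net radiation is split
between canopy and soil by exponential extinction, soil heat flux is a
fraction of the soil net radiation, sensible heat is solved on a series
resistance network with Monin–Obukhov stability iteration, and latent
heat is the budget residual of each source (energy closure holds by
construction). The instantaneous flux is upscaled to a daily total with
the ET0-ratio method.

The **crop stress coefficient** `Ks = ETa / ETp` computed at each flight
is interpolated across the season (Ks = 1 over the unstressed 0–100 DAS
window; piecewise-constant between inter-flight midpoints by default,
linear as an alternative), giving daily `ETa = Ks · ETp`, cumulative
integrals split at heading (GS55) into vegetative and grain-filling
totals, water productivity `WP = GY / (10 · ETa)` (kg m⁻³), and
broad-sense heritability `H² = σ²g / (σ²g + σ²/r)` from ANOVA variance
components.

## Worked example

```r
library(etintegral)

cfg   <- trial_config(n_varieties = 6, n_blocks = 3)
trial <- simulate_trial(cfg, seed = 42)
trial
#> Synthetic wheat trial: 6 varieties x 2 treatments x 3 blocks, season 185 days
#>   RGB flights at DAS 61, 81, 119, 131, 170; thermal flights at DAS 119, 131, 170
#>   season rainfall 130 mm, season ET0 465 mm

fit <- run_pipeline(trial)
summary(fit)
#> Cumulative-ETa estimation pipeline
#> LAI regression model
#>   LAI = +3.782*ph +5.884*vari -2.086
#>   calibration: n = 28, R2 = 0.896, RMSE = 0.263, BIC = -64.78
#>   validation (n = 8): R2 = 0.916, RMSE = 0.331
#>   mean cumulative ETa by treatment (mm):
#>        treatment eta_total  eta_veg   eta_gf
#>  full_irrigation  537.2826 150.7787 386.5039
#>          rainfed  482.8747 147.0037 335.8711
#>   mean yield (kg/ha) and water productivity (kg/m3) by treatment:
#>        treatment       gy        wp
#>  full_irrigation 7769.197 1.4453489
#>          rainfed 4489.538 0.9199148
```

The fitted LAI model kept the height and VARI predictors (BIC dropped
`fc`, which is nearly collinear with them at this noise level) and
explains 92% of the held-out LAI variance. Rainfed plots lose ~50 mm
less water over the season, almost entirely during grain filling, and
pay for it with lower yield and water productivity. Heritability of
water productivity across the two water regimes:

```r
vc <- variance_components(fit$performance, "wp", env = "treatment")
broad_sense_heritability(vc, multi_env = TRUE)
#> [1] 0.2189209
```

The bundled two-year trial summary (22 commercial winter-wheat
varieties, full irrigation vs rainfed) reproduces the headline
treatment effect:

```r
tm <- variety_trial_means("treatment")
treatment_reduction(tm$eta_gf[1], tm$eta_gf[2], digits = 0)
#> [1] 52
```

i.e. rainfed plots accumulated 52% less ETa during grain filling.

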