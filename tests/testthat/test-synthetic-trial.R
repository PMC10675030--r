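test_that("trial configuration validates its invariants", {
  expect_s3_class(trial_config(), "trial_config")
  expect_error(trial_config(n_varieties = 1), ">= 2")
  expect_error(trial_config(flight_das_thermal = c(90, 120, 150)),
               "after DAS 100")
  expect_error(trial_config(flight_das_thermal = c(130, 120, 150)),
               "increasing")
  expect_error(trial_config(noise = list(temp = -1)), ">= 0")
  expect_error(trial_config(bogus = 1), "unknown")
})

test_that("weather generation is deterministic and respects physical invariants", {
  cfg <- trial_config(n_varieties = 2, n_blocks = 2)
  w1 <- generate_weather(cfg, seed = 5)
  w2 <- generate_weather(cfg, seed = 5)
  expect_identical(w1, w2)
  w3 <- generate_weather(cfg, seed = 6)
  expect_false(identical(w1, w3))
  expect_true(all(w1$tmin <= w1$tmax))
  expect_true(all(w1$rh_mean >= 0 & w1$rh_mean <= 100))
  expect_true(all(w1$rainfall >= 0))
  expect_true(all(is.finite(w1$et0)) && all(w1$et0 >= 0))
})

test_that("zero weather noise yields the smooth seasonal sinusoid", {
  cfg <- trial_config(n_varieties = 2, noise = list(weather = 0))
  w <- generate_weather(cfg, seed = 3)
  tmean <- (w$tmin + w$tmax) / 2
  expected <- cfg$t_base + cfg$t_amp * sin(2 * pi * (w$doy - cfg$t_phase) / 365)
  expect_equal(tmean, expected, tolerance = 1e-12)
  expect_true(all(w$tmin <= w$tmax))
})

test_that("season rainfall hits the configured target", {
  cfg <- trial_config(n_varieties = 2, rainfall_total = 130)
  w <- generate_weather(cfg, seed = 11)
  expect_equal(sum(w$rainfall), 130, tolerance = 1e-9)
  cfg2 <- trial_config(n_varieties = 2, rainfall_total = 260)
  expect_equal(sum(generate_weather(cfg2, seed = 11)$rainfall), 260,
               tolerance = 1e-9)
})

test_that("zero-noise RGB observations invert the LAI map exactly", {
  cfg <- zero_noise_config()
  truth <- generate_variety_truth(cfg, seed = 2)
  weather <- generate_weather(cfg, seed = 2)
  obs <- generate_flight_observations(truth, weather, cfg, seed = 2)
  m <- lai_model(cfg$lai_map[["intercept"]], ph = cfg$lai_map[["ph"]],
                 vari = cfg$lai_map[["vari"]], fc = cfg$lai_map[["fc"]])
  lai_hat <- predict(m, ph = obs$rgb$ph, vari = obs$rgb$vari, fc = obs$rgb$fc)
  tr <- truth[match(obs$rgb$variety, truth$variety), ]
  lai_true <- tr$c / (1 + exp(-tr$a * (obs$rgb$das - tr$b)))
  expect_equal(lai_hat, lai_true, tolerance = 1e-9)
  # ground-truthed calibration plots exist and match the truth at zero noise
  cal <- obs$rgb[!is.na(obs$rgb$measured_lai), ]
  expect_gt(nrow(cal), 0)
  tr_cal <- truth[match(cal$variety, truth$variety), ]
  expect_equal(cal$measured_lai,
               tr_cal$c / (1 + exp(-tr_cal$a * (cal$das - tr_cal$b))),
               tolerance = 1e-9)
})

test_that("linear canopy-temperature mode follows the stress gain arithmetic", {
  cfg <- zero_noise_config()
  cfg$tc_unstressed <- 24
  truth <- generate_variety_truth(cfg, seed = 4)
  weather <- generate_weather(cfg, seed = 4)
  obs <- generate_flight_observations(truth, weather, cfg, seed = 4,
                                      tc_mode = "linear")
  th <- obs$thermal
  # first flight (DAS 119) precedes every heading date: Ks = 1 everywhere,
  # so T_C equals the configured unstressed canopy temperature
  first <- th[th$das == min(th$das), ]
  expect_true(all(first$ks_true == 1))
  expect_equal(first$t_c, rep(24, nrow(first)), tolerance = 1e-12)
  # between treatments, the T_C difference is gain * Ks gap
  last <- th[th$das == max(th$das), ]
  irr <- last[last$treatment == "full_irrigation", ]
  rain <- last[last$treatment == "rainfed", ]
  irr <- irr[order(irr$variety, irr$block), ]
  rain <- rain[order(rain$variety, rain$block), ]
  expect_equal(rain$t_c - irr$t_c,
               cfg$tc_gain * (irr$ks_true - rain$ks_true),
               tolerance = 1e-10)
})

test_that("soil runs hotter than the canopy and responds to stress", {
  cfg <- zero_noise_config()
  truth <- generate_variety_truth(cfg, seed = 4)
  weather <- generate_weather(cfg, seed = 4)
  obs <- generate_flight_observations(truth, weather, cfg, seed = 4,
                                      tc_mode = "linear")
  expect_true(all(obs$thermal$t_s > obs$thermal$t_c))
})

test_that("yields saturate in grain-filling ETa and preserve its ordering", {
  # at the offset, deterministic yield is exactly zero
  expect_equal(generate_yield(10, offset = 10)$gy, 0)
  # asymptote
  y_inf <- generate_yield(1e5, ymax = 11000, variety_effect = 0.95)$gy
  expect_equal(y_inf, 11000 * 0.95, tolerance = 1e-6)
  # monotone at zero noise
  eta_gf <- c(20, 45, 60, 95, 140)
  y <- generate_yield(eta_gf)$gy
  expect_true(all(diff(y) > 0))
  expect_true(all(diff(generate_yield(eta_gf)$tkw) > 0))
  expect_error(generate_yield(50, ymax = -1), "positive")
  expect_error(generate_yield(-5), ">= 0")
})

test_that("irrigation schedule replaces the unmet crop demand weekly", {
  # Kc = 1, ET0 = 5 mm/day, no rain: 35 mm per week
  expect_equal(irrigation_schedule(rep(5, 28), rep(1, 28), rep(0, 28)),
               rep(35, 4))
  # rainfall covering demand: zero irrigation
  expect_equal(irrigation_schedule(rep(5, 14), rep(1, 14), rep(6, 14)),
               rep(0, 2))
  # rainfed treatment: all-zero schedule
  expect_equal(irrigation_schedule(rep(5, 14), rep(1, 14), rep(0, 14),
                                   treatment = "rainfed"), rep(0, 2))
  expect_error(irrigation_schedule(rep(5, 10), rep(1, 9), rep(0, 10)),
               "same length")
  expect_error(irrigation_schedule(rep(5, 7), rep(-1, 7), rep(0, 7)), ">= 0")
})

test_that("a full simulated trial is bit-identical under a fixed seed", {
  cfg <- trial_config(n_varieties = 3, n_blocks = 2)
  t1 <- simulate_trial(cfg, seed = 9)
  t2 <- simulate_trial(cfg, seed = 9)
  expect_identical(t1$weather, t2$weather)
  expect_identical(t1$truth, t2$truth)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$thermal, t2$thermal)
  expect_identical(t1$agronomy, t2$agronomy)
})

test_that("truth stress trajectories are unstressed early and piecewise-linear", {
  cfg <- trial_config(n_varieties = 3)
  truth <- generate_variety_truth(cfg, seed = 13)
  for (i in seq_len(nrow(truth))) {
    das <- 0:truth$maturity_das[i]
    ks <- ks_truth(das, truth[i, ], "rainfed")
    expect_true(all(ks[das <= 100] == 1))
    expect_true(all(diff(ks) <= 0))
    expect_equal(ks[length(ks)], truth$ks_end_rainfed[i], tolerance = 1e-12)
    expect_gt(truth$heading_das[i], 100)
    expect_gt(truth$maturity_das[i], truth$heading_das[i])
  }
})
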