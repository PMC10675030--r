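# shared fixtures and independent oracles

# independently transcribed FAO-56 daily reference ET (simplified form,
# 900 coefficient, aerodynamic resistance 208/u2 folded in); used only as
# a cross-check oracle, never as the implementation
fao56_oracle_et0 <- function(tmin, tmax, rh, u2, rs, doy, lat, z) {
  t <- (tmin + tmax) / 2
  P <- 101.3 * ((293 - 0.0065 * z) / 293)^5.26
  g <- 0.000665 * P
  e0 <- function(x) 0.6108 * exp(17.27 * x / (x + 237.3))
  D <- 4098 * e0(t) / (t + 237.3)^2
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- rh / 100 * es
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  de <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(-tan(phi) * tan(de))
  Ra <- 24 * 60 / pi * 0.082 * dr *
    (ws * sin(phi) * sin(de) + cos(phi) * cos(de) * sin(ws))
  Rso <- (0.75 + 2e-5 * z) * Ra
  Rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * min(rs / Rso, 1) - 0.35)
  Rn <- 0.77 * rs - Rnl
  (0.408 * D * Rn + g * 900 / (t + 273) * u2 * (es - ea)) /
    (D + g * (1 + 0.34 * u2))
}

# a plausible clear spring day for ET computations
bench_day <- function(tmin = 12.3, tmax = 21.5, rh = 63.5, u2 = 2.78,
                      rs = 22.07, doy = 187) {
  data.frame(tmin = tmin, tmax = tmax, rh_mean = rh, wind_2m = u2,
             solar_rad = rs, doy = doy)
}

# midday instantaneous weather for TSEB runs
bench_instant <- function(t_air = 25, rh = 45, wind = 2, sw_in = 800,
                          zenith = 0.4) {
  list(t_air = t_air, rh = rh, wind = wind, sw_in = sw_in, zenith = zenith)
}

# energy-closure residual of a flux partition
closure_residual <- function(fl) {
  (fl$rn_c + fl$rn_s) - (fl$h_c + fl$h_s + fl$le_c + fl$le_s + fl$g)
}

# small zero-noise trial configuration (kept small for test runtime)
zero_noise_config <- function(n_varieties = 4, n_blocks = 2)
  trial_config(n_varieties = n_varieties, n_blocks = n_blocks,
               noise = list(vari = 0, ph = 0, fc = 0, temp = 0,
                            lai = 0, weather = 1, yield = 0))
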