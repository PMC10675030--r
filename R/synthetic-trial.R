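# Synthetic multi-variety wheat trials with known ground truth: seasonal
# weather, sigmoid LAI trajectories, treatment-dependent stress
# trajectories, noisy flight observations and yields responding
# asymptotically to grain-filling ETa. Every downstream stage of the
# pipeline can be tested against the generator's truth.

# evaluate under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of a synthetic wheat trial
#'
#' All generator constants are configurable; the defaults emulate a
#' Mediterranean winter-wheat screening trial: 22 varieties, full
#' irrigation vs rainfed, 3 blocks, December sowing (day of year 348) at
#' 41.7 degrees N, RGB flights on five dates and thermal flights on the
#' three late dates (all after the unstressed 0-100 DAS window).
#'
#' @param ... Named overrides of the defaults, e.g.
#'   `trial_config(n_varieties = 6, noise = list(temp = 0))`. The `noise`
#'   list (sd of VARI, PH m, fc, temperatures degC, LAI, and a weather
#'   noise multiplier) is merged element-wise.
#' @return Object of class `trial_config` (a validated list).
#' @export
trial_config <- function(...) {
  cfg <- list(
    n_varieties = 22L,
    n_blocks = 3L,
    treatments = c("full_irrigation", "rainfed"),
    season_length = 185L,
    sowing_doy = 348L,
    lat = 41.7,
    elevation = 250,
    flight_das_rgb = c(61L, 81L, 119L, 131L, 170L),
    flight_das_thermal = c(119L, 131L, 170L),
    noise = list(vari = 0.02, ph = 0.02, fc = 0.02, temp = 0.5,
                 lai = 0.3, weather = 1, yield = 250),
    # weather generator: seasonal sinusoid + AR(1) noise, sparse rainfall
    t_base = 14, t_amp = 8.5, t_phase = 106, diurnal_range = 10,
    wind_mean = 2, rain_prob = 0.12, rainfall_total = 130,
    # observation model: linear LAI map inverted for VARI, linear
    # stress -> canopy temperature gain
    lai_map = c(intercept = -1.071, ph = 5.063, vari = 5.451, fc = -1.661),
    tc_mode = "linear",
    tc_gain = 5, tc_unstressed = NULL,
    ts_offset = 8, ts_gain = 4,
    # asymptotic yield response to grain-filling ETa
    ymax = 11500, yield_rate = 0.008, yield_offset = 150
  )
  dots <- list(...)
  if ("noise" %in% names(dots)) {
    cfg$noise[names(dots$noise)] <- dots$noise
    dots$noise <- NULL
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$n_varieties < 2) stop("n_varieties must be >= 2")
  if (cfg$season_length < 1) stop("season_length must be >= 1")
  if (any(diff(cfg$flight_das_thermal) <= 0) || any(diff(cfg$flight_das_rgb) <= 0))
    stop("flight days must be strictly increasing")
  if (any(cfg$flight_das_thermal <= 100))
    stop("thermal (ET) flights must all be after DAS 100")
  if (any(cfg$flight_das_thermal > cfg$season_length) ||
      any(cfg$flight_das_rgb > cfg$season_length))
    stop("flights must fall within the season")
  if (any(unlist(cfg$noise) < 0)) stop("noise sd must be >= 0")
  class(cfg) <- "trial_config"
  cfg
}

#' Generate a season of daily weather
#'
#' Deterministic given the seed: a sinusoidal seasonal temperature cycle
#' with AR(1) noise, humidity declining with temperature, autocorrelated
#' cloudiness scaling the clear-sky radiation envelope, and sparse
#' rainfall events rescaled so the season total matches the configured
#' target. The derived FAO-56 reference ET0 is appended.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return Data frame, one row per DAS `0:season_length`, columns `das`,
#'   `doy`, `tmin`, `tmax`, `rh_mean`, `wind_2m`, `solar_rad`, `rainfall`,
#'   `et0`.
#' @export
generate_weather <- function(config = trial_config(), seed = 1) {
  if (config$season_length < 1) stop("season_length must be >= 1")
  .with_seed(seed, {
    das <- seq.int(0, config$season_length)
    n <- length(das)
    doy <- ((config$sowing_doy - 1 + das) %% 365) + 1
    w <- config$noise$weather
    ar <- function(sd, rho = 0.7) {
      e <- numeric(n)
      if (sd > 0) for (i in seq_len(n))
        e[i] <- if (i == 1) stats::rnorm(1, 0, sd)
        else rho * e[i - 1] + stats::rnorm(1, 0, sd * sqrt(1 - rho^2))
      e
    }
    tmean <- config$t_base +
      config$t_amp * sin(2 * pi * (doy - config$t_phase) / 365) + ar(1.8 * w)
    tmax <- tmean + config$diurnal_range / 2
    tmin <- tmean - config$diurnal_range / 2
    rh <- pmin(98, pmax(30, 75 - 1.2 * (tmean - 10) + ar(5 * w)))
    wind <- pmin(8, pmax(0.5, config$wind_mean + ar(0.6 * w)))
    ra <- extraterrestrial_radiation(doy, config$lat)
    kt <- pmin(0.78, pmax(0.2, 0.68 + ar(0.1 * w)))
    solar <- kt * ra
    rain <- numeric(n)
    wet <- stats::runif(n) < config$rain_prob
    if (any(wet)) {
      amounts <- stats::rexp(sum(wet), rate = 1 / 8)
      rain[wet] <- amounts / sum(amounts) * config$rainfall_total
    }
    out <- data.frame(das = das, doy = doy, tmin = tmin, tmax = tmax,
                      rh_mean = rh, wind_2m = wind, solar_rad = solar,
                      rainfall = rain)
    out$et0 <- reference_et0(out, lat = config$lat,
                             elevation = config$elevation)
    out
  })
}

#' Generate per-variety ground truth
#'
#' Draws sigmoid LAI growth parameters, phenology, maximum plant height,
#' yield-response parameters and the treatment-specific end-of-season
#' stress level of each variety. Stress trajectories are piecewise-linear
#' in DAS: Ks = 1 up to heading (always after the unstressed 0-100 DAS
#' window), then a linear decline to `ks_end` at maturity — mild under
#' full irrigation, pronounced under rainfed.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return Data frame with one row per variety: sigmoid `a`, `b`, `c`,
#'   `ph_max`, `heading_das`, `maturity_das`, `ks_end_full_irrigation`,
#'   `ks_end_rainfed`, yield `variety_effect`.
#' @export
generate_variety_truth <- function(config = trial_config(), seed = 1) {
  .with_seed(seed + 1000L, {
    nv <- config$n_varieties
    data.frame(
      variety = paste0("V", sprintf("%02d", seq_len(nv))),
      a = stats::runif(nv, 0.08, 0.13),
      b = stats::runif(nv, 95, 112),
      c = stats::runif(nv, 4.8, 7.5),
      ph_max = stats::runif(nv, 0.7, 1.0),
      heading_das = round(stats::runif(nv, 121, 131)),
      maturity_das = round(stats::runif(nv, 172,
                                        min(182, config$season_length))),
      ks_end_full_irrigation = stats::runif(nv, 0.9, 1.0),
      ks_end_rainfed = stats::runif(nv, 0.35, 0.6),
      variety_effect = stats::runif(nv, 0.88, 1.05)
    )
  })
}

#' True stress-coefficient trajectory of a variety
#'
#' @param das Days after sowing (vectorised).
#' @param truth_row One row of [generate_variety_truth()].
#' @param treatment Treatment label.
#' @return Ks at each day: 1 up to heading, then linear to the
#'   treatment's `ks_end` at maturity.
#' @export
ks_truth <- function(das, truth_row, treatment) {
  onset <- max(truth_row$heading_das, 101)
  ks_end <- truth_row[[paste0("ks_end_", treatment)]]
  frac <- pmin(1, pmax(0, (das - onset) / (truth_row$maturity_das - onset)))
  1 + frac * (ks_end - 1)
}

# truth daily series (LAI, PH, ETp, Ks, ETa) for one variety x treatment
.truth_series <- function(truth_row, treatment, weather, config) {
  days <- seq.int(0, truth_row$maturity_das)
  w <- weather[match(days, weather$das), ]
  lai <- truth_row$c / (1 + exp(-truth_row$a * (days - truth_row$b)))
  ph <- truth_row$ph_max * lai / truth_row$c
  etp <- potential_et(w, lai, ph, lat = config$lat,
                      elevation = config$elevation)
  ks <- ks_truth(days, truth_row, treatment)
  data.frame(das = days, lai = lai, ph = ph, etp = etp, ks = ks,
             eta = ks * etp, cum_eta = cumsum(ks * etp))
}

# instantaneous (flight-time, ~noon) weather from a daily record
.instant_weather <- function(wrow, config) {
  phi <- config$lat * pi / 180
  delta <- 0.409 * sin(2 * pi * wrow$doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  n_daylight <- 24 * ws / pi
  sw_noon <- wrow$solar_rad * 1e6 * pi / (2 * n_daylight * 3600)
  list(t_air = wrow$tmax - 1,
       rh = max(20, wrow$rh_mean - 15),
       wind = wrow$wind_2m,
       sw_in = sw_noon,
       zenith = abs(phi - delta),
       pressure = .pressure_kpa(config$elevation))
}

# daily ETa implied by a canopy temperature through the full snapshot
# chain: TSEB fluxes -> ET0-ratio upscaling
.snapshot_daily_eta <- function(t_c, t_s, lai, fc, ph, iw, wrow, config) {
  fl <- tseb_component_fluxes(t_c, t_s, lai, fc, ph, iw)
  et0_h <- hourly_et0(iw$t_air, iw$rh, iw$wind, iw$sw_in, iw$zenith,
                      elevation = config$elevation)
  instantaneous_to_daily_eta(fl$le_c + fl$le_s, iw$t_air, et0_h, wrow$et0)
}

#' Generate flight observations for every plot
#'
#' RGB flights yield VARI, plant height and fractional cover consistent
#' with the true LAI: PH and fc are deterministic functions of LAI and
#' VARI is obtained by inverting the configured linear LAI map, so at
#' zero noise the LAI regression recovers the truth exactly. Thermal
#' flights yield component temperatures; the canopy temperature either
#' rises linearly with stress (`tc_mode = "linear"`, gain
#' `config$tc_gain` degC per unit `1 - Ks`) or is root-found so that the
#' full snapshot energy-balance chain reproduces `Ks * ETp` exactly
#' (`tc_mode = "consistent"`), which makes the generator and pipeline
#' consistent at zero noise. Ground-truth LAI measurements are attached
#' to block-1 plots on the thermal flight dates (the calibration
#' micro-plots).
#'
#' @param truth Variety truth table from [generate_variety_truth()].
#' @param weather Daily weather from [generate_weather()].
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @param tc_mode Overrides `config$tc_mode`.
#' @return List with data frames `rgb` (one row per plot x RGB flight)
#'   and `thermal` (one row per plot x thermal flight, with the
#'   instantaneous weather used).
#' @export
generate_flight_observations <- function(truth, weather,
                                         config = trial_config(), seed = 1,
                                         tc_mode = NULL) {
  if (is.null(tc_mode)) tc_mode <- config$tc_mode
  if (any(config$flight_das_rgb < 0)) stop("flight before sowing")
  .with_seed(seed + 2000L, {
    plots <- expand.grid(variety = truth$variety,
                         treatment = config$treatments,
                         block = seq_len(config$n_blocks),
                         stringsAsFactors = FALSE)
    plots$plot_id <- with(plots, paste(variety, treatment, block, sep = "_"))
    lm_ <- config$lai_map
    nz <- config$noise

    rgb <- do.call(rbind, lapply(config$flight_das_rgb, function(d) {
      tr <- truth[match(plots$variety, truth$variety), ]
      lai <- tr$c / (1 + exp(-tr$a * (d - tr$b)))
      ph <- tr$ph_max * lai / tr$c
      fc <- pmin(0.98, 1 - exp(-0.55 * lai))
      vari <- (lai - lm_[["intercept"]] - lm_[["ph"]] * ph -
                 lm_[["fc"]] * fc) / lm_[["vari"]]
      n <- nrow(plots)
      cal <- plots$block == 1 & d %in% config$flight_das_thermal
      data.frame(plot_id = plots$plot_id, variety = plots$variety,
                 treatment = plots$treatment, block = plots$block, das = d,
                 vari = vari + stats::rnorm(n, 0, nz$vari),
                 ph = pmax(0, ph + stats::rnorm(n, 0, nz$ph)),
                 fc = pmin(1, pmax(0, fc + stats::rnorm(n, 0, nz$fc))),
                 measured_lai = ifelse(cal,
                                       pmax(0, lai + stats::rnorm(n, 0, nz$lai)),
                                       NA_real_))
    }))

    thermal <- do.call(rbind, lapply(config$flight_das_thermal, function(d) {
      wrow <- weather[weather$das == d, ]
      iw <- .instant_weather(wrow, config)
      tr <- truth[match(plots$variety, truth$variety), ]
      lai <- tr$c / (1 + exp(-tr$a * (d - tr$b)))
      ph <- tr$ph_max * lai / tr$c
      fc <- pmin(0.98, 1 - exp(-0.55 * lai))
      ks <- vapply(seq_len(nrow(plots)), function(i)
        ks_truth(d, tr[i, ], plots$treatment[i]), numeric(1))
      t_s <- iw$t_air + config$ts_offset + config$ts_gain * (1 - ks)
      t_c <- if (tc_mode == "linear") {
        base <- if (!is.null(config$tc_unstressed)) config$tc_unstressed
        else iw$t_air - 2
        base + config$tc_gain * (1 - ks)
      } else {
        vapply(seq_len(nrow(plots)), function(i) {
          etp_d <- potential_et(wrow, lai[i], ph[i], lat = config$lat,
                                elevation = config$elevation)
          target <- ks[i] * etp_d
          f <- function(tc) .snapshot_daily_eta(tc, t_s[i], lai[i], fc[i],
                                                ph[i], iw, wrow, config) - target
          lo <- iw$t_air - 12; hi <- iw$t_air + 25
          flo <- f(lo); fhi <- f(hi)
          if (flo < 0) lo                         # target above attainable range
          else if (fhi > 0) hi
          else stats::uniroot(f, c(lo, hi), tol = 1e-7)$root
        }, numeric(1))
      }
      n <- nrow(plots)
      data.frame(plot_id = plots$plot_id, variety = plots$variety,
                 treatment = plots$treatment, block = plots$block, das = d,
                 t_c = t_c + stats::rnorm(n, 0, nz$temp),
                 t_s = t_s + stats::rnorm(n, 0, nz$temp),
                 t_air = iw$t_air, rh_inst = iw$rh, wind_inst = iw$wind,
                 sw_in = iw$sw_in, zenith = iw$zenith,
                 et0_daily = wrow$et0, ks_true = ks)
    }))
    list(rgb = rgb, thermal = thermal)
  })
}

#' Yields with an asymptotic response to grain-filling ETa
#'
#' `GY = Ymax * (1 - exp(-rate * max(0, ETa_GF - offset))) * variety_effect
#' + noise`; thousand-kernel weight and grain number share the monotone
#' saturating dependence.
#'
#' @param eta_gf Cumulative grain-filling ETa per plot (mm, >= 0).
#' @param ymax Asymptotic yield (kg ha-1, > 0).
#' @param rate Response rate per mm.
#' @param offset ETa offset (mm) below which no yield accrues.
#' @param variety_effect Multiplicative variety effect (recycled).
#' @param noise_sd Yield noise sd (kg ha-1); TKW noise scales with it.
#' @return Data frame with `gy` (kg ha-1), `tkw` (g), `grain_number`
#'   (grains m-2).
#' @export
generate_yield <- function(eta_gf, ymax = 11500, rate = 0.03, offset = 10,
                           variety_effect = 1, noise_sd = 0) {
  if (any(ymax <= 0)) stop("Ymax must be positive")
  if (any(eta_gf < 0)) stop("ETa_GF must be >= 0")
  sat <- 1 - exp(-rate * pmax(0, eta_gf - offset))
  n <- length(sat)
  gy <- pmax(0, ymax * sat * variety_effect + stats::rnorm(n, 0, noise_sd))
  tkw <- pmax(5, (22 + 28 * sat) * variety_effect +
                stats::rnorm(n, 0, noise_sd / 100))
  data.frame(gy = gy, tkw = tkw, grain_number = 100 * gy / tkw)
}

#' Weekly irrigation schedule from the crop-coefficient water balance
#'
#' The weekly dose replaces the crop's unmet demand:
#' `max(0, sum(Kc * ET0) - sum(rainfall))` over each 7-day window.
#' Rainfed treatments receive no irrigation (all-zero schedule).
#'
#' @param et0 Daily reference ET series (mm day-1).
#' @param kc Daily crop coefficients (>= 0), same length.
#' @param rainfall Daily rainfall (mm), same length.
#' @param treatment Treatment label; anything other than `"rainfed"` is
#'   irrigated.
#' @return Numeric vector of weekly irrigation doses (mm), one per
#'   started 7-day window.
#' @export
irrigation_schedule <- function(et0, kc, rainfall,
                                treatment = "full_irrigation") {
  if (length(et0) != length(kc) || length(et0) != length(rainfall))
    stop("et0, kc and rainfall must have the same length")
  if (any(kc < 0)) stop("Kc must be >= 0")
  week <- (seq_along(et0) - 1) %/% 7
  if (identical(treatment, "rainfed"))
    return(rep(0, length(unique(week))))
  demand <- tapply(kc * et0, week, sum)
  rain <- tapply(rainfall, week, sum)
  as.numeric(pmax(0, demand - rain))
}

#' Simulate a complete synthetic trial
#'
#' Generates weather, variety truth, the truth daily ET series per
#' variety and treatment, flight observations for every plot, phenology
#' and agronomy (yields responding to the truth grain-filling ETa), all
#' deterministically from one seed.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @param tc_mode Optional override of the canopy-temperature generation
#'   mode (see [generate_flight_observations()]).
#' @return Object of class `wheat_trial`: `config`, `weather`, `truth`,
#'   `truth_series` (named list of per-variety-x-treatment data frames
#'   with the true daily LAI/ETp/Ks/ETa and cumulative ETa), `snapshots`
#'   (RGB), `thermal`, `phenology`, `agronomy`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1,
                           tc_mode = NULL) {
  weather <- generate_weather(config, seed)
  truth <- generate_variety_truth(config, seed)
  truth_series <- list()
  for (i in seq_len(nrow(truth)))
    for (tr in config$treatments)
      truth_series[[paste(truth$variety[i], tr, sep = "_")]] <-
    .truth_series(truth[i, ], tr, weather, config)
  obs <- generate_flight_observations(truth, weather, config, seed,
                                      tc_mode = tc_mode)
  phenology <- truth[, c("variety", "heading_das", "maturity_das")]
  plots <- unique(obs$rgb[, c("plot_id", "variety", "treatment", "block")])
  truth_gf <- vapply(seq_len(nrow(plots)), function(i) {
    ser <- truth_series[[paste(plots$variety[i], plots$treatment[i], sep = "_")]]
    h <- truth$heading_das[truth$variety == plots$variety[i]]
    unname(stage_integrals(ser$eta, h, max(ser$das))[["eta_gf"]])
  }, numeric(1))
  agronomy <- .with_seed(seed + 3000L, {
    ve <- truth$variety_effect[match(plots$variety, truth$variety)]
    cbind(plots,
          generate_yield(truth_gf, ymax = config$ymax,
                         rate = config$yield_rate,
                         offset = config$yield_offset,
                         variety_effect = ve,
                         noise_sd = config$noise$yield),
          eta_gf_true = truth_gf)
  })
  structure(list(config = config, weather = weather, truth = truth,
                 truth_series = truth_series, snapshots = obs$rgb,
                 thermal = obs$thermal, phenology = phenology,
                 agronomy = agronomy),
            class = "wheat_trial")
}

#' @export
print.wheat_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic wheat trial: %d varieties x %d treatments x %d blocks, season %d days\n",
    x$config$n_varieties, length(x$config$treatments), x$config$n_blocks,
    x$config$season_length))
  cat(sprintf("  RGB flights at DAS %s; thermal flights at DAS %s\n",
              paste(x$config$flight_das_rgb, collapse = ", "),
              paste(x$config$flight_das_thermal, collapse = ", ")))
  cat(sprintf("  season rainfall %.0f mm, season ET0 %.0f mm\n",
              sum(x$weather$rainfall), sum(x$weather$et0)))
  invisible(x)
}
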