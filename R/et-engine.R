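# Penman-Monteith reference/potential ET and the two-source energy balance.
# Units follow agro-meteorological convention: daily fluxes in MJ m-2 day-1,
# instantaneous fluxes in W m-2, vapour pressure in kPa, ET in mm.

# saturation vapour pressure (kPa) at air temperature T (degC)
.svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

# slope of the saturation vapour pressure curve (kPa degC-1)
.svp_slope <- function(t) 4098 * .svp(t) / (t + 237.3)^2

# barometric pressure (kPa) from elevation (m)
.pressure_kpa <- function(elevation) 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation for a given day of year and latitude,
#' needed for the clear-sky envelope in net-longwave estimation.
#'
#' @param doy Day of year (1-365), vectorised.
#' @param lat Latitude in decimal degrees.
#' @return Extraterrestrial radiation in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(doy, lat) {
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

# daily net radiation (MJ m-2 day-1) over a surface with given albedo
.net_radiation_daily <- function(tmin, tmax, ea, solar_rad, doy, lat, elevation,
                                 albedo = 0.23) {
  ra <- extraterrestrial_radiation(doy, lat)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rel <- ifelse(rso > 0, pmin(solar_rad / rso, 1), 0)
  sigma <- 4.903e-9
  tk4 <- ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2
  rnl <- sigma * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  (1 - albedo) * solar_rad - rnl
}

# FAO-56 log-profile aerodynamic resistance (s m-1) for measurement height
# zm (wind) and zh (humidity/temperature) above a crop of height h
.aero_resistance_fao <- function(wind_2m, crop_height, zm = 2, zh = 2) {
  u <- pmax(wind_2m, 0.5)            # floor for resistance stability
  h <- pmax(crop_height, 0.01)
  zm <- pmax(zm, h + 0.5)            # minimum height margin above the canopy
  zh <- pmax(zh, h + 0.5)
  d <- 2 / 3 * h
  zom <- 0.123 * h
  zoh <- 0.1 * zom
  log((zm - d) / zom) * log((zh - d) / zoh) / (0.41^2 * u)
}

# full-form daily Penman-Monteith engine (mm day-1)
.pm_daily <- function(tmin, tmax, rh_mean, wind_2m, solar_rad, doy, lat,
                      elevation, rs_surface, crop_height, g = 0, rn = NULL,
                      albedo = 0.23) {
  tmean <- (tmin + tmax) / 2
  if (any(tmin > tmax)) stop("tmin must not exceed tmax")
  if (any(!is.finite(c(rh_mean, solar_rad)))) stop("missing humidity or radiation")
  p <- .pressure_kpa(elevation)
  gamma <- 0.000665 * p
  delta <- .svp_slope(tmean)
  es <- (.svp(tmax) + .svp(tmin)) / 2
  ea <- pmin(rh_mean, 100) / 100 * es
  vpd <- pmax(es - ea, 0)
  if (is.null(rn))
    rn <- .net_radiation_daily(tmin, tmax, ea, solar_rad, doy, lat, elevation,
                               albedo = albedo)
  ra <- .aero_resistance_fao(wind_2m, crop_height)
  rho <- p / (1.01 * (tmean + 273) * 0.287)   # kg m-3, virtual-temp approx
  cp <- 1.013e-3                              # MJ kg-1 degC-1
  lambda <- 2.45                              # MJ kg-1
  num <- delta * (rn - g) + 86400 * rho * cp * vpd / ra
  den <- delta + gamma * (1 + rs_surface / ra)
  pmax(num / den / lambda, 0)
}

#' FAO-56 reference evapotranspiration (daily)
#'
#' Penman-Monteith ET of the reference surface: a well-watered 0.12 m grass
#' with bulk surface resistance 70 s m-1 and albedo 0.23. This is the ET0
#' that drives irrigation scheduling and the ratio used to upscale
#' instantaneous latent-heat flux to daily totals.
#'
#' @param weather Data frame with columns `tmin`, `tmax` (degC), `rh_mean`
#'   (%), `wind_2m` (m s-1), `solar_rad` (MJ m-2 day-1) and `doy`
#'   (day of year).
#' @param lat Latitude (decimal degrees).
#' @param elevation Site elevation (m).
#' @param rn Optional externally supplied net radiation (MJ m-2 day-1)
#'   overriding the internal radiation balance.
#' @return ET0 in mm day-1 (floored at 0), one value per weather row.
#' @export
reference_et0 <- function(weather, lat = 41.7, elevation = 250, rn = NULL) {
  .pm_daily(weather$tmin, weather$tmax, weather$rh_mean, weather$wind_2m,
            weather$solar_rad, weather$doy, lat, elevation,
            rs_surface = 70, crop_height = 0.12, rn = rn)
}

#' Potential evapotranspiration of an actual canopy (daily)
#'
#' Penman-Monteith with canopy-dependent resistances: bulk surface
#' resistance `rs = rl / (0.5 * max(LAI, 0.1))` with stomatal resistance
#' `rl = 100 s m-1`, and aerodynamic resistance from the FAO-56 log profile
#' of the actual plant height (`d = 2/3 PH`, `z_om = 0.123 PH`, sensors at
#' 2 m with a minimum margin above the canopy). With LAI = 20/7 (rs = 70)
#' and PH = 0.12 m it reduces exactly to [reference_et0()].
#'
#' @inheritParams reference_et0
#' @param lai Leaf area index (>= 0, floored internally at 0.1), recycled
#'   over weather rows.
#' @param ph Plant height in m, recycled.
#' @param rl Leaf stomatal resistance, s m-1 (default 100).
#' @return ETp in mm day-1.
#' @export
potential_et <- function(weather, lai, ph, lat = 41.7, elevation = 250,
                         rl = 100, rn = NULL) {
  if (any(lai < 0)) stop("LAI must be >= 0")
  if (any(ph < 0)) stop("plant height must be >= 0")
  lai_eff <- pmax(lai, 0.1)
  .pm_daily(weather$tmin, weather$tmax, weather$rh_mean, weather$wind_2m,
            weather$solar_rad, weather$doy, lat, elevation,
            rs_surface = rl / (0.5 * lai_eff), crop_height = ph, rn = rn)
}

#' FAO-56 hourly reference evapotranspiration
#'
#' Hourly formulation of the grass-reference Penman-Monteith, used at the
#' flight time in the ET0-ratio upscaling of snapshot latent-heat flux.
#' Net radiation is built from the instantaneous shortwave flux and an
#' hourly net-longwave term bounded by the clear-sky envelope at the given
#' solar zenith angle.
#'
#' @param temp Air temperature at flight time (degC).
#' @param rh Relative humidity (%).
#' @param wind_2m Wind speed at 2 m (m s-1).
#' @param sw_in Incoming shortwave radiation (W m-2).
#' @param zenith Solar zenith angle (radians).
#' @param elevation Site elevation (m).
#' @return Reference ET for the hour around the snapshot, mm h-1.
#' @export
hourly_et0 <- function(temp, rh, wind_2m, sw_in, zenith, elevation = 250) {
  p <- .pressure_kpa(elevation)
  gamma <- 0.000665 * p
  delta <- .svp_slope(temp)
  es <- .svp(temp)
  ea <- pmin(rh, 100) / 100 * es
  rs_h <- sw_in * 0.0036                      # MJ m-2 h-1
  rso_h <- pmax((0.75 + 2e-5 * elevation) * 1367 * cos(zenith), 0) * 0.0036
  rel <- if (rso_h > 0) min(rs_h / rso_h, 1) else 0.5
  rnl_h <- 2.043e-10 * (temp + 273.16)^4 *
    (0.34 - 0.14 * sqrt(max(ea, 0))) * (1.35 * rel - 0.35)
  rn_h <- (1 - 0.23) * rs_h - rnl_h
  g_h <- 0.1 * rn_h                           # daytime soil heat flux
  u2 <- pmax(wind_2m, 0.5)
  num <- 0.408 * delta * (rn_h - g_h) + gamma * 37 / (temp + 273) * u2 * (es - ea)
  den <- delta + gamma * (1 + 0.34 * u2)
  max(num / den, 0)
}

#' Latent heat of vaporization of water
#'
#' @param temp Temperature in degC.
#' @return Latent heat in J kg-1.
#' @export
latent_heat_vaporization <- function(temp) (2.501 - 2.361e-3 * temp) * 1e6

#' Upscale an instantaneous latent-heat flux to a daily ET total
#'
#' ET0-ratio method: the snapshot flux is converted to an equivalent
#' hourly depth and multiplied by the ratio of daily reference ET to the
#' hourly reference ET at flight time, assuming the crop/reference ratio
#' is preserved over the day. Consistent with the stress-coefficient
#' framework (Ks applies to daily totals).
#'
#' @param le_inst Instantaneous latent-heat flux (W m-2); negative values
#'   are floored at 0 before upscaling.
#' @param air_temp Air temperature at flight time (degC), used for the
#'   temperature-dependent latent heat of vaporization.
#' @param et0_hourly Hourly reference ET at flight time (mm h-1), > 0.
#' @param et0_daily Daily reference ET of the flight day (mm day-1).
#' @return Daily actual evapotranspiration, mm day-1.
#' @export
instantaneous_to_daily_eta <- function(le_inst, air_temp, et0_hourly, et0_daily) {
  if (!all(is.finite(le_inst))) stop("LE must be finite")
  if (any(et0_hourly <= 0)) stop("hourly reference ET at flight time must be positive")
  mm_per_hour <- pmax(le_inst, 0) * 3600 / latent_heat_vaporization(air_temp)
  mm_per_hour * et0_daily / et0_hourly
}

# Dyer-Businger stability corrections; zeta = z/L
.psi_m <- function(zeta) {
  zeta <- pmin(zeta, 1)
  ifelse(zeta >= 0, -5 * zeta, {
    x <- (1 - 16 * pmin(zeta, 0))^0.25
    2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
  })
}
.psi_h <- function(zeta) {
  zeta <- pmin(zeta, 1)
  ifelse(zeta >= 0, -5 * zeta, {
    x <- (1 - 16 * pmin(zeta, 0))^0.25
    2 * log((1 + x^2) / 2)
  })
}

#' Two-source energy balance with measured component temperatures (TSEB-2T)
#'
#' Partitions the surface energy balance between the soil and canopy
#' sources using component temperatures retrieved from high-resolution
#' thermal imagery. Net radiation is split by exponential extinction
#' through the canopy, soil heat flux is a fraction of the soil net
#' radiation, and the sensible-heat fluxes are solved on a series
#' resistance network (aerodynamic resistance with Monin-Obukhov stability
#' correction, canopy boundary-layer resistance, soil-surface resistance)
#' for the within-canopy aerodynamic temperature. Latent heat of each
#' source is obtained as the residual of its budget, so energy closure
#' holds by construction; non-physical negative residuals are floored at 0
#' with the excess returned to the sensible term.
#'
#' @param t_c Canopy temperature (degC).
#' @param t_s Soil temperature (degC).
#' @param lai Leaf area index (> 0).
#' @param fc Fractional vegetation cover in `[0, 1]`, used for the
#'   composite radiometric temperature in the radiation balance.
#' @param ph Canopy height (m).
#' @param weather List with instantaneous conditions: `t_air` (degC),
#'   `rh` (%), `wind` (m s-1 at height `z_u`), `sw_in` (W m-2), optional
#'   `lw_in` (W m-2; estimated from air temperature and humidity when
#'   missing), optional `pressure` (kPa), `zenith` (radians, default 0.52),
#'   `z_u` (default 2 m).
#' @param kappa Radiation extinction coefficient (default 0.45).
#' @param c_g Soil-heat-flux fraction of soil net radiation (default 0.35).
#' @param albedo Surface shortwave albedo (default 0.23).
#' @param emissivity Surface emissivity (default 0.98).
#' @param leaf_size Mean leaf width (m) in the canopy boundary-layer
#'   resistance (default 0.02 for wheat).
#' @param rss_a,rss_b Coefficients of the soil-surface resistance
#'   `1 / (a + b * u_s)` (defaults 0.004 and 0.012).
#' @param max_iter Cap on Monin-Obukhov iterations (default 50).
#' @param floor_negative_le Floor negative residual latent heat at 0,
#'   returning the excess to the sensible term (default `TRUE`).
#' @return Object of class `energy_fluxes`: `rn_c`, `rn_s`, `g`, `h_c`,
#'   `h_s`, `le_c`, `le_s` (W m-2), the aerodynamic temperature `t_ac`,
#'   friction velocity `u_star`, Obukhov length `obukhov`, `converged`
#'   flag and `iterations`.
#' @export
tseb_component_fluxes <- function(t_c, t_s, lai, fc, ph, weather,
                                  kappa = 0.45, c_g = 0.35, albedo = 0.23,
                                  emissivity = 0.98, leaf_size = 0.02,
                                  rss_a = 0.004, rss_b = 0.012,
                                  max_iter = 50, floor_negative_le = TRUE) {
  if (is.na(t_c) || is.na(t_s))
    stop("both component temperatures are required (TSEB-2T); ",
         "a missing class must be resolved by the caller")
  if (!is.finite(lai) || lai <= 0) stop("LAI must be positive")
  fc <- min(1, max(0, fc))
  ta <- weather$t_air
  u <- max(weather$wind, 0.5)
  z_u <- if (is.null(weather$z_u)) 2 else weather$z_u
  zen <- if (is.null(weather$zenith)) 0.5236 else weather$zenith
  p <- if (is.null(weather$pressure)) .pressure_kpa(250) else weather$pressure
  tk <- ta + 273.16
  ea <- if (!is.null(weather$ea)) weather$ea else
    min(weather$rh, 100) / 100 * .svp(ta)
  rho <- p * 1000 / (287.05 * tk / (1 - 0.378 * ea / p))
  cp <- 1013
  sigma <- 5.67e-8

  # radiation balance on the composite surface, then extinction partition
  lw_in <- if (!is.null(weather$lw_in) && is.finite(weather$lw_in)) weather$lw_in
  else 1.24 * (10 * ea / tk)^(1 / 7) * sigma * tk^4
  t_rad4 <- fc * (t_c + 273.16)^4 + (1 - fc) * (t_s + 273.16)^4
  rn <- (1 - albedo) * weather$sw_in + emissivity * lw_in -
    emissivity * sigma * t_rad4
  rn_s <- rn * exp(-kappa * lai / sqrt(2 * max(cos(zen), 0.05)))
  rn_c <- rn - rn_s
  g <- c_g * rn_s

  h <- max(ph, 0.05)
  z_u <- max(z_u, h + 0.5)
  d <- 2 / 3 * h
  zom <- 0.123 * h
  kv <- 0.41
  grav <- 9.81

  obukhov <- Inf
  converged <- FALSE
  iter <- 0
  h_c <- h_s <- 0
  u_star <- kv * u / log((z_u - d) / zom)
  t_ac <- ta
  repeat {
    iter <- iter + 1
    zeta <- if (is.finite(obukhov)) (z_u - d) / obukhov else 0
    zeta0 <- if (is.finite(obukhov)) zom / obukhov else 0
    log_m <- log((z_u - d) / zom) - .psi_m(zeta) + .psi_m(zeta0)
    log_h <- log((z_u - d) / zom) - .psi_h(zeta) + .psi_h(zeta0)
    log_m <- max(log_m, 0.1); log_h <- max(log_h, 0.1)
    u_star <- kv * u / log_m
    ra <- log_h / (kv * u_star)
    u_c <- max(u_star / kv * log((h - d) / zom), 0.1)  # wind at canopy top
    rx <- 90 / lai * sqrt(leaf_size / u_c)
    a_ext <- 0.28 * lai^(2 / 3) * h^(1 / 3) * leaf_size^(-1 / 3)
    u_s <- max(u_c * exp(-a_ext * (1 - 0.05 / h)), 0.01)
    rss <- 1 / (rss_a + rss_b * u_s)
    t_ac <- (ta / ra + t_c / rx + t_s / rss) / (1 / ra + 1 / rx + 1 / rss)
    h_c <- rho * cp * (t_c - t_ac) / rx
    h_s <- rho * cp * (t_s - t_ac) / rss
    h_tot <- h_c + h_s
    l_new <- if (abs(h_tot) < 0.1) Inf else
      -rho * cp * u_star^3 * tk / (kv * grav * h_tot)
    dl <- if (is.infinite(l_new) && is.infinite(obukhov)) 0 else
      if (is.infinite(l_new) || is.infinite(obukhov)) Inf else
        abs(l_new - obukhov)
    if (dl < 1e-3 || (is.finite(l_new) && is.finite(obukhov) &&
                      abs(1 / l_new - 1 / obukhov) < 1e-6)) {
      obukhov <- l_new
      converged <- TRUE
      break
    }
    obukhov <- if (is.finite(l_new) && is.finite(obukhov))
      0.5 * obukhov + 0.5 * l_new else l_new
    if (iter >= max_iter) break
  }

  le_c <- rn_c - h_c
  le_s <- rn_s - g - h_s
  if (floor_negative_le) {
    if (le_c < 0) { h_c <- rn_c; le_c <- 0 }
    if (le_s < 0) { h_s <- rn_s - g; le_s <- 0 }
  }
  out <- list(rn = rn, rn_c = rn_c, rn_s = rn_s, g = g,
              h_c = h_c, h_s = h_s, le_c = le_c, le_s = le_s,
              t_ac = t_ac, u_star = u_star, obukhov = obukhov,
              converged = converged, iterations = iter)
  class(out) <- "energy_fluxes"
  out
}

#' @export
print.energy_fluxes <- function(x, ...) {
  cat("Two-source energy balance (W m-2)\n")
  cat(sprintf("  Rn = %.1f (canopy %.1f, soil %.1f), G = %.1f\n",
              x$rn, x$rn_c, x$rn_s, x$g))
  cat(sprintf("  H  = %.1f (canopy %.1f, soil %.1f)\n",
              x$h_c + x$h_s, x$h_c, x$h_s))
  cat(sprintf("  LE = %.1f (canopy %.1f, soil %.1f)\n",
              x$le_c + x$le_s, x$le_c, x$le_s))
  cat(sprintf("  converged: %s in %d iterations\n", x$converged, x$iterations))
  invisible(x)
}
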