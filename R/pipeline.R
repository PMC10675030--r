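# End-to-end estimation: flight observations -> LAI model -> sigmoid
# growth curves -> daily ETp -> snapshot TSEB ETa -> Ks interpolation ->
# stage-wise cumulative ETa integrals and water productivity.

#' Run the full cumulative-ETa estimation pipeline on a trial
#'
#' Takes the observation tables of a trial (as produced by
#' [simulate_trial()], or assembled from real data in the same layout)
#' and estimates, per plot, the daily ETa series and its season and
#' stage-wise cumulative integrals:
#'
#' 1. the LAI multiple regression is calibrated by BIC subset selection
#'    on the ground-truthed plots (random calibration/validation split);
#' 2. LAI is predicted for every plot and flight, averaged over blocks
#'    and fitted to a logistic growth curve per variety x treatment;
#' 3. plant height is modelled as a linear function of LAI from the
#'    flight observations, giving daily PH alongside daily LAI;
#' 4. daily potential ET is computed with the canopy Penman-Monteith;
#' 5. each thermal snapshot is run through the two-source energy balance
#'    and upscaled to a daily ETa with the ET0-ratio method, giving a
#'    per-flight crop stress coefficient Ks = ETa/ETp;
#' 6. Ks is interpolated across the season (piecewise-constant between
#'    flight midpoints, Ks = 1 before DAS 100) and integrated into
#'    cumulative, vegetative and grain-filling ETa and water
#'    productivity.
#'
#' @param trial A `wheat_trial` (or a list with the same components:
#'   `config`, `weather`, `snapshots`, `thermal`, `phenology`,
#'   `agronomy`).
#' @param n_validation Number of ground-truthed observations held out for
#'   validation of the LAI regression (default 8, as a 36:8 split of 44
#'   calibration plots; clipped to the data at hand).
#' @param split_seed Seed of the calibration/validation split.
#' @param ks_cap Optional upper cap on Ks (default `Inf`).
#' @param ks_method Interpolation scheme, `"constant"` or `"linear"`.
#' @return Object of class `eta_pipeline`: `lai_model`, `validation`
#'   (R2/RMSE on the held-out observations), `sigmoid_fits` (per
#'   variety x treatment growth parameters), `ks_flights` (per plot x
#'   flight Ks), `et_series` (long per-plot daily series), `performance`
#'   (per-plot integrals, yield and water productivity).
#' @export
run_pipeline <- function(trial, n_validation = 8, split_seed = 42,
                         ks_cap = Inf, ks_method = "constant") {
  config <- trial$config
  weather <- trial$weather
  snaps <- trial$snapshots

  # 1. LAI regression on the ground-truthed observations
  cal <- snaps[!is.na(snaps$measured_lai), ]
  if (nrow(cal) < 8) stop("too few ground-truthed observations to calibrate")
  cal$lai <- cal$measured_lai
  n_val <- min(n_validation, nrow(cal) - 8)
  val_idx <- .with_seed(split_seed,
                        sample(nrow(cal), max(0, n_val)))
  fit_set <- if (length(val_idx)) cal[-val_idx, ] else cal
  val_set <- if (length(val_idx)) cal[val_idx, ] else cal[0, ]
  model <- fit_lai_regression(fit_set)
  validation <- if (nrow(val_set) > 0) {
    pred <- predict(model, ph = val_set$ph, vari = val_set$vari,
                    fc = val_set$fc)
    list(n = nrow(val_set),
         r_squared = 1 - sum((val_set$lai - pred)^2) /
           sum((val_set$lai - mean(val_set$lai))^2),
         rmse = sqrt(mean((val_set$lai - pred)^2)))
  } else list(n = 0, r_squared = NA_real_, rmse = NA_real_)

  # 2. predicted LAI -> logistic growth curve per variety x treatment
  snaps$lai_hat <- predict(model, ph = snaps$ph, vari = snaps$vari,
                           fc = snaps$fc)
  group <- interaction(snaps$variety, snaps$treatment, drop = TRUE,
                       sep = "_")
  mean_lai <- stats::aggregate(lai_hat ~ variety + treatment + das,
                               data = snaps, FUN = mean)
  sigmoid_fits <- do.call(rbind, lapply(
    split(mean_lai, interaction(mean_lai$variety, mean_lai$treatment,
                                drop = TRUE)),
    function(g) {
      fit <- fit_sigmoid_lai(g$das, g$lai_hat)
      data.frame(variety = g$variety[1], treatment = g$treatment[1],
                 a = fit$coefficients[["a"]], b = fit$coefficients[["b"]],
                 c = fit$coefficients[["c"]], rmse = fit$rmse)
    }))
  rownames(sigmoid_fits) <- NULL

  # 3. plant height as a linear function of LAI, per variety (the
  # height/leaf-area allometry is a varietal trait)
  ph_fits <- lapply(split(snaps, snaps$variety),
                    function(g) stats::lm(ph ~ lai_hat, data = g))

  # 4.-6. per variety x treatment daily ETp, per plot Ks and integrals
  phen <- trial$phenology
  therm <- trial$thermal
  sig_key <- paste(sigmoid_fits$variety, sigmoid_fits$treatment, sep = "_")

  daily <- list()
  for (i in seq_len(nrow(sigmoid_fits))) {
    v <- sigmoid_fits$variety[i]; tr <- sigmoid_fits$treatment[i]
    mat <- phen$maturity_das[phen$variety == v]
    cf <- c(a = sigmoid_fits$a[i], b = sigmoid_fits$b[i],
            c = sigmoid_fits$c[i])
    ser <- daily_lai_series(cf, maturity_das = mat)
    ser$ph_hat <- pmax(0.01, stats::predict(
      ph_fits[[v]], newdata = data.frame(lai_hat = ser$lai)))
    w <- weather[match(ser$das, weather$das), ]
    ser$etp <- potential_et(w, ser$lai, ser$ph_hat, lat = config$lat,
                            elevation = config$elevation)
    daily[[paste(v, tr, sep = "_")]] <- ser
  }

  # snapshot ETa and Ks per plot x thermal flight
  ks_flights <- therm[, c("plot_id", "variety", "treatment", "block", "das")]
  ks_flights$eta_day <- NA_real_
  ks_flights$etp_day <- NA_real_
  for (j in seq_len(nrow(therm))) {
    row <- therm[j, ]
    key <- paste(row$variety, row$treatment, sep = "_")
    ser <- daily[[key]]
    if (row$das <= max(ser$das)) {
      lai_d <- ser$lai[ser$das == row$das]
      ph_d <- ser$ph_hat[ser$das == row$das]
      etp_d <- ser$etp[ser$das == row$das]
    } else {
      # flight after this variety's maturity: evaluate the fitted curve
      # at the flight day (its Ks still informs the final interval)
      i_s <- which(sigmoid_fits$variety == row$variety &
                     sigmoid_fits$treatment == row$treatment)
      cf <- c(a = sigmoid_fits$a[i_s], b = sigmoid_fits$b[i_s],
              c = sigmoid_fits$c[i_s])
      lai_d <- cf[["c"]] / (1 + exp(-cf[["a"]] * (row$das - cf[["b"]])))
      ph_d <- pmax(0.01, stats::predict(
        ph_fits[[row$variety]], newdata = data.frame(lai_hat = lai_d)))
      w <- weather[weather$das == row$das, ]
      etp_d <- potential_et(w, lai_d, ph_d, lat = config$lat,
                            elevation = config$elevation)
    }
    # same-day RGB fractional cover of this plot
    fc_d <- snaps$fc[snaps$plot_id == row$plot_id & snaps$das == row$das]
    if (!length(fc_d)) fc_d <- 1 - exp(-0.55 * lai_d)
    iw <- list(t_air = row$t_air, rh = row$rh_inst, wind = row$wind_inst,
               sw_in = row$sw_in, zenith = row$zenith,
               pressure = .pressure_kpa(config$elevation))
    fl <- tseb_component_fluxes(row$t_c, row$t_s, lai_d, fc_d[1], ph_d, iw)
    et0_h <- hourly_et0(iw$t_air, iw$rh, iw$wind, iw$sw_in, iw$zenith,
                        elevation = config$elevation)
    ks_flights$eta_day[j] <- instantaneous_to_daily_eta(
      fl$le_c + fl$le_s, iw$t_air, et0_h, row$et0_daily)
    ks_flights$etp_day[j] <- etp_d
  }
  ks_flights$ks <- crop_stress_coefficient(ks_flights$eta_day,
                                           ks_flights$etp_day, cap = ks_cap)

  # seasonal integration per plot
  plots <- unique(therm[, c("plot_id", "variety", "treatment", "block")])
  et_series <- vector("list", nrow(plots))
  perf <- plots
  perf$eta_total <- perf$eta_veg <- perf$eta_gf <- NA_real_
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    key <- paste(p$variety, p$treatment, sep = "_")
    ser <- daily[[key]]
    kf <- ks_flights[ks_flights$plot_id == p$plot_id, ]
    kf <- kf[order(kf$das), ]
    mat <- max(ser$das)
    ks_daily <- interpolate_ks(kf$das, kf$ks, maturity_das = mat,
                               method = ks_method)
    eta <- daily_eta_series(ks_daily, ser$etp)
    h <- phen$heading_das[phen$variety == p$variety]
    st <- stage_integrals(eta$eta, h, mat)
    perf$eta_total[i] <- st[["eta_total"]]
    perf$eta_veg[i] <- st[["eta_veg"]]
    perf$eta_gf[i] <- st[["eta_gf"]]
    et_series[[i]] <- data.frame(plot_id = p$plot_id, variety = p$variety,
                                 treatment = p$treatment, block = p$block,
                                 das = ser$das, lai = ser$lai,
                                 etp = ser$etp, ks = ks_daily,
                                 eta = eta$eta, cum_eta = eta$cum_eta)
  }
  et_series <- do.call(rbind, et_series)

  agro <- trial$agronomy
  perf <- merge(perf, agro[, c("plot_id", "gy", "tkw", "grain_number")],
                by = "plot_id", all.x = TRUE, sort = FALSE)
  perf$wp <- ifelse(is.na(perf$gy), NA_real_,
                    water_productivity(perf$gy, perf$eta_total))

  structure(list(lai_model = model, validation = validation,
                 sigmoid_fits = sigmoid_fits, ks_flights = ks_flights,
                 et_series = et_series, performance = perf),
            class = "eta_pipeline")
}

#' @export
print.eta_pipeline <- function(x, ...) {
  cat("Cumulative-ETa estimation pipeline\n")
  print(x$lai_model)
  if (x$validation$n > 0)
    cat(sprintf("  validation (n = %d): R2 = %.3f, RMSE = %.3f\n",
                x$validation$n, x$validation$r_squared, x$validation$rmse))
  agg <- stats::aggregate(cbind(eta_total, eta_veg, eta_gf) ~ treatment,
                          data = x$performance, FUN = mean)
  cat("  mean cumulative ETa by treatment (mm):\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
summary.eta_pipeline <- function(object, ...) {
  print(object)
  perf <- object$performance
  if (!all(is.na(perf$wp))) {
    agg <- stats::aggregate(cbind(gy, wp) ~ treatment, data = perf,
                            FUN = mean)
    cat("  mean yield (kg/ha) and water productivity (kg/m3) by treatment:\n")
    print(agg, row.names = FALSE)
  }
  invisible(object)
}
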