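# From per-flight ETa/ETp snapshots to daily stress coefficients,
# season-long cumulative ETa, stage integrals and water productivity.

#' Crop stress coefficient
#'
#' `Ks = ETa / ETp`; 1 means the canopy transpires at its potential rate.
#' Not capped above 1 by default: snapshot energy-balance ETa can exceed
#' the Penman-Monteith potential under advective conditions, and capping
#' is left as an explicit choice.
#'
#' @param eta Actual evapotranspiration (mm day-1), vectorised.
#' @param etp Potential evapotranspiration (mm day-1), > 0.
#' @param cap Optional upper cap on Ks (default `Inf`, i.e. none).
#' @return Ks (dimensionless, >= 0).
#' @export
crop_stress_coefficient <- function(eta, etp, cap = Inf) {
  if (any(etp <= 0)) stop("ETp must be positive to form Ks = ETa/ETp")
  pmin(pmax(eta, 0) / etp, cap)
}

#' Interpolate flight-date stress coefficients to a daily series
#'
#' Early in the cycle (DAS 0-100) water needs are assumed fulfilled and
#' Ks = 1. After that, each flight's Ks is held piecewise-constant over an
#' interval around the flight: from the (floored) midpoint with the
#' previous flight (or DAS 101 for the first flight) through the floored
#' midpoint with the next flight; the last flight's Ks is held to
#' maturity. A linear alternative interpolates Ks between flights and
#' continues the terminal inter-flight trend beyond the last flight
#' (floored at 0), on the premise that stress keeps progressing through
#' late grain fill.
#'
#' @param flight_das Strictly increasing flight days, all >
#'   `unstressed_until`.
#' @param ks Stress coefficient of each flight (>= 0).
#' @param maturity_das Last day of the series.
#' @param unstressed_until Last DAS of the assumed-unstressed window
#'   (default 100).
#' @param method `"constant"` (default, step intervals) or `"linear"`.
#' @return Numeric vector of daily Ks for DAS `0:maturity_das`. If no
#'   flights are supplied, an all-ones series with a warning and
#'   attribute `no_flights = TRUE`.
#' @export
interpolate_ks <- function(flight_das, ks, maturity_das,
                           unstressed_until = 100,
                           method = c("constant", "linear")) {
  method <- match.arg(method)
  das <- seq.int(0, maturity_das)
  if (length(flight_das) == 0) {
    warning("no flights: returning Ks = 1 for the whole season")
    return(structure(rep(1, length(das)), no_flights = TRUE))
  }
  if (length(flight_das) != length(ks)) stop("flight_das and ks lengths differ")
  if (any(diff(flight_das) <= 0)) stop("flight_das must be strictly increasing")
  if (any(flight_das <= unstressed_until))
    stop("flights at or before DAS ", unstressed_until,
         " are rejected: Ks is fixed at 1 there")
  if (any(!is.finite(ks) | ks < 0)) stop("Ks values must be finite and >= 0")

  out <- rep(1, length(das))
  stressed <- das > unstressed_until
  if (method == "constant") {
    nf <- length(flight_das)
    # segment upper bounds: floored midpoints, last held to maturity
    upper <- c(if (nf > 1) floor((flight_das[-nf] + flight_das[-1]) / 2),
               maturity_das)
    lower <- c(unstressed_until + 1, upper[-length(upper)] + 1)
    for (i in seq_len(nf)) {
      seg <- das >= lower[i] & das <= upper[i]
      out[seg] <- ks[i]
    }
  } else {
    out[stressed] <- stats::approx(flight_das, ks, xout = das[stressed],
                                   rule = 2)$y
    # beyond the last flight, continue the terminal inter-flight trend
    # (stress keeps progressing through late grain fill), floored at 0
    nf <- length(flight_das)
    if (nf >= 2) {
      slope <- (ks[nf] - ks[nf - 1]) / (flight_das[nf] - flight_das[nf - 1])
      tail_idx <- das > flight_das[nf]
      out[tail_idx] <- pmax(0, ks[nf] + slope * (das[tail_idx] - flight_das[nf]))
    }
  }
  out
}

#' Daily actual evapotranspiration and its cumulative integral
#'
#' `ETa[d] = Ks[d] * ETp[d]`, with the cumulative series as prefix sums.
#'
#' @param ks Daily stress coefficients.
#' @param etp Daily potential ET (mm day-1), same length.
#' @return Data frame with columns `eta` and `cum_eta` (mm).
#' @export
daily_eta_series <- function(ks, etp) {
  if (length(ks) != length(etp)) stop("ks and etp must have equal length")
  eta <- ks * etp
  data.frame(eta = eta, cum_eta = cumsum(eta))
}

#' Stage-wise cumulative evapotranspiration integrals
#'
#' Splits the daily ETa series at heading: the vegetative integral covers
#' sowing through the heading day inclusive (DAS 0..heading), the
#' grain-filling integral the days after heading through maturity.
#'
#' @param eta Daily ETa for DAS `0:maturity_das`
#'   (length `maturity_das + 1`).
#' @param heading_das Heading day (GS55), `0 <= heading < maturity`.
#' @param maturity_das Physiological maturity day (GS87).
#' @return Named vector `c(eta_total, eta_veg, eta_gf)` in mm;
#'   `eta_veg + eta_gf == eta_total`.
#' @export
stage_integrals <- function(eta, heading_das, maturity_das) {
  if (length(eta) != maturity_das + 1)
    stop("eta must cover DAS 0..maturity_das (length maturity_das + 1)")
  if (heading_das < 0 || heading_das >= maturity_das)
    stop("phenology outside the series: need 0 <= heading < maturity")
  veg <- sum(eta[seq_len(heading_das + 1)])
  gf <- sum(eta[(heading_das + 2):(maturity_das + 1)])
  c(eta_total = veg + gf, eta_veg = veg, eta_gf = gf)
}

#' Water productivity
#'
#' Grain produced per cubic metre of evapotranspired water:
#' `WP = GY / (10 * cumulative ETa)`, since 1 mm of water over 1 ha is
#' 10 m3.
#'
#' @param gy Grain yield (kg ha-1), vectorised.
#' @param cum_eta Season cumulative ETa (mm), > 0.
#' @return WP in kg m-3.
#' @export
water_productivity <- function(gy, cum_eta) {
  if (any(cum_eta <= 0)) stop("cumulative ETa must be positive")
  if (any(gy < 0)) stop("grain yield must be >= 0")
  gy / (10 * cum_eta)
}
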