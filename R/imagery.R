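#' Visible Atmospherically Resistant Index (VARI)
#'
#' Greenness index computed from mean RGB digital numbers,
#' `(G - R) / (G + R - B)`. VARI highlights vegetation in the visible
#' spectrum while damping illumination and atmospheric differences, which
#' makes it usable from plain RGB cameras without radiometric calibration.
#'
#' @param dn_red,dn_green,dn_blue Mean digital numbers of the red, green and
#'   blue bands (dimensionless, non-negative). Vectors are recycled to a
#'   common length.
#' @param na_on_degenerate If `TRUE`, pixels whose denominator
#'   `G + R - B` is zero return `NA` instead of raising an error (grid
#'   mode). Default `FALSE`: a zero denominator is an error.
#' @return Numeric vector of VARI values.
#' @examples
#' compute_vari(100, 100, 100)   # 0
#' compute_vari(50, 150, 50)     # 2/3
#' @export
compute_vari <- function(dn_red, dn_green, dn_blue, na_on_degenerate = FALSE) {
  n <- max(length(dn_red), length(dn_green), length(dn_blue))
  r <- rep_len(as.numeric(dn_red), n)
  g <- rep_len(as.numeric(dn_green), n)
  b <- rep_len(as.numeric(dn_blue), n)
  if (any(!is.finite(c(r, g, b))) || any(c(r, g, b) < 0, na.rm = TRUE))
    stop("digital numbers must be finite and non-negative")
  den <- g + r - b
  bad <- den == 0
  if (any(bad)) {
    if (!na_on_degenerate)
      stop("degenerate pixel: DN_green + DN_red - DN_blue is zero")
    den[bad] <- NA_real_
  }
  (g - r) / den
}

#' Fractional vegetation cover from VARI
#'
#' Linear mixing between a bare-soil and a pure-vegetation VARI reference:
#' `fc = (VARI_i - VARI_soil) / (VARI_veg - VARI_soil)`, clamped to
#' `[0, 1]` because noisy references can push the raw ratio outside the
#' physical range.
#'
#' @param vari_i VARI of the target plot/pixel (vectorised).
#' @param vari_soil Bare-soil reference VARI.
#' @param vari_veg Pure-vegetation reference VARI; must differ from
#'   `vari_soil`.
#' @param clamp Clamp the result to `[0, 1]` (default `TRUE`).
#' @return Fractional cover in `[0, 1]` (or the raw ratio if `clamp = FALSE`).
#' @export
compute_fc <- function(vari_i, vari_soil, vari_veg, clamp = TRUE) {
  if (!is.finite(vari_soil) || !is.finite(vari_veg))
    stop("reference VARI values must be finite")
  if (vari_veg == vari_soil)
    stop("VARI_veg must differ from VARI_soil")
  fc <- (vari_i - vari_soil) / (vari_veg - vari_soil)
  if (clamp) fc <- pmin(1, pmax(0, fc))
  fc
}

#' Plant height from surface and terrain models
#'
#' Per-plot mean canopy height as the difference between a digital surface
#' model and a digital terrain model over the plot mask. Negative
#' differences (terrain noise) are floored at 0 before averaging, since a
#' canopy cannot have negative height.
#'
#' @param dsm,dtm Numeric matrices of identical shape (surface/terrain
#'   elevation, m).
#' @param mask Logical matrix of the same shape selecting the plot cells;
#'   must select at least one cell. `NULL` uses all cells.
#' @return Mean plant height in metres (scalar, >= 0).
#' @export
plant_height <- function(dsm, dtm, mask = NULL) {
  if (!is.matrix(dsm) || !is.matrix(dtm) || !all(dim(dsm) == dim(dtm)))
    stop("dsm and dtm must be matrices of identical shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dsm), ncol(dsm))
  if (!all(dim(mask) == dim(dsm)))
    stop("mask shape must match the grids")
  mask <- mask & !is.na(dsm) & !is.na(dtm)
  if (!any(mask)) stop("empty plot mask")
  mean(pmax(dsm[mask] - dtm[mask], 0))
}

#' Calibrate thermal imagery against ground reference targets
#'
#' Fits the linear map `truth = a + b * measured` from on-image readings of
#' reference targets (e.g. hot/cold panels, bare soil, vegetation) whose
#' ground temperature was logged during the flight, and applies it to the
#' raw image temperatures. Corrects the atmospheric and sensor-drift
#' component of the thermal signal. With exactly two references the map
#' interpolates them exactly; with more it is the least-squares line.
#'
#' @param raw Numeric vector/matrix of raw image temperatures (degC).
#' @param reference Two-column matrix or data.frame: column 1 the
#'   temperature measured on the image at the target, column 2 the ground
#'   truth. At least 2 rows with distinct measured values.
#' @return Object of the same shape as `raw` with corrected temperatures;
#'   attributes `gain` and `offset` carry the fitted map.
#' @export
calibrate_thermal <- function(raw, reference) {
  reference <- as.matrix(reference)
  if (nrow(reference) < 2)
    stop("at least two reference pairs are required")
  measured <- as.numeric(reference[, 1])
  truth <- as.numeric(reference[, 2])
  if (length(unique(measured)) < 2)
    stop("reference measured values must not be identical")
  fit <- stats::lm.fit(cbind(1, measured), truth)
  offset <- unname(fit$coefficients[1])
  gain <- unname(fit$coefficients[2])
  out <- offset + gain * raw
  attr(out, "gain") <- gain
  attr(out, "offset") <- offset
  out
}

#' Otsu threshold of a numeric sample
#'
#' Histogram threshold maximising the between-class variance, used to split
#' a VARI grid into soil and vegetation without a trained classifier.
#'
#' @param x Numeric values (e.g. a VARI grid); NA dropped.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value: cells with `x > threshold` are vegetation.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 2 || diff(range(x)) == 0)
    stop("need at least two distinct finite values to threshold")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  # between-class variance for every cut position
  mu_t <- sum(w * mids)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  valid <- omega > 0 & omega < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  breaks[which.max(bcv) + 1]
}

#' Vegetation mask from a VARI grid
#'
#' Thresholds the plot's VARI histogram (Otsu by default) to separate
#' vegetation from soil pixels.
#'
#' @param vari_grid Numeric matrix of VARI values.
#' @param threshold Optional fixed threshold; default uses
#'   [otsu_threshold()].
#' @return Logical matrix, `TRUE` for vegetation cells.
#' @export
vegetation_mask <- function(vari_grid, threshold = NULL) {
  if (!is.matrix(vari_grid)) stop("vari_grid must be a matrix")
  if (is.null(threshold)) threshold <- otsu_threshold(vari_grid)
  vari_grid > threshold
}

#' Component temperatures of canopy and soil
#'
#' Splits a (calibrated) thermal grid into canopy and soil classes with a
#' vegetation mask and returns the class-mean temperatures, as needed by
#' the two-source energy balance. A class with no cells yields `NA` with
#' its count 0 so the caller can decide on a fallback.
#'
#' @param thermal Numeric matrix of temperatures (degC).
#' @param mask Logical matrix of the same shape, `TRUE` = vegetation.
#' @return List of class `component_temperatures` with fields `t_c`, `t_s`
#'   (degC) and pixel counts `n_canopy_px`, `n_soil_px`.
#' @export
separate_component_temperatures <- function(thermal, mask) {
  if (!is.matrix(thermal) || !is.matrix(mask) ||
      !all(dim(thermal) == dim(mask)))
    stop("thermal grid and mask must be matrices of identical shape")
  veg <- mask & !is.na(thermal)
  soil <- !mask & !is.na(thermal)
  out <- list(
    t_c = if (any(veg)) mean(thermal[veg]) else NA_real_,
    t_s = if (any(soil)) mean(thermal[soil]) else NA_real_,
    n_canopy_px = sum(veg),
    n_soil_px = sum(soil)
  )
  class(out) <- "component_temperatures"
  out
}

#' @export
print.component_temperatures <- function(x, ...) {
  cat(sprintf("Component temperatures: T_C = %s degC (%d px), T_S = %s degC (%d px)\n",
              format(x$t_c, digits = 4), x$n_canopy_px,
              format(x$t_s, digits = 4), x$n_soil_px))
  invisible(x)
}
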