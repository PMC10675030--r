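# Trial-level statistics: ANOVA variance components, broad-sense
# heritability, treatment reductions, variety-mean correlations, and
# soil-water conversions.

#' Variance components by ANOVA method of moments
#'
#' Estimates the genotypic and error variance of a trait from the
#' variety/replicate ANOVA mean squares of a (balanced) trial:
#' `sigma2_g = max(0, (MS_variety - MS_error) / r)` and
#' `sigma2_e = MS_error`. With two or more environments the
#' genotype-by-environment component is estimated analogously from the
#' variety-by-environment mean square:
#' `sigma2_ge = max(0, (MS_VxE - MS_error) / r)` and
#' `sigma2_g = max(0, (MS_variety - MS_VxE) / (r * e))`. Negative moment
#' estimates are truncated to 0.
#'
#' @param data Data frame with one row per plot.
#' @param trait Name of the trait column.
#' @param variety,replicate,env Names of the variety, replicate/block and
#'   (optional) environment columns; `env = NULL` for a single
#'   environment.
#' @return Object of class `variance_components` with `sigma2_g`,
#'   `sigma2_e`, `sigma2_ge` (`NA` for one environment), replicate count
#'   `r` and environment count `e`.
#' @export
variance_components <- function(data, trait, variety = "variety",
                                replicate = "block", env = NULL) {
  v <- factor(data[[variety]])
  y <- data[[trait]]
  if (nlevels(v) < 2) stop("need at least 2 varieties")
  r <- length(y) / nlevels(v)
  e <- 1L
  if (!is.null(env)) {
    en <- factor(data[[env]])
    e <- nlevels(en)
  }
  if (e > 1) {
    r <- length(y) / (nlevels(v) * e)
    if (r < 2) stop("single replicate: genotypic variance is unidentifiable")
    tab <- suppressWarnings(stats::anova(stats::lm(y ~ en + v + en:v)))
    ms <- tab$`Mean Sq`; rn <- rownames(tab)
    ms_v <- ms[rn == "v"]; ms_ve <- ms[rn == "en:v"]
    ms_e <- ms[rn == "Residuals"]
    s2 <- ms_e
    s2ge <- max(0, (ms_ve - ms_e) / r)
    s2g <- max(0, (ms_v - ms_ve) / (r * e))
  } else {
    if (r < 2) stop("single replicate: genotypic variance is unidentifiable")
    b <- factor(data[[replicate]])
    tab <- suppressWarnings(stats::anova(stats::lm(y ~ b + v)))
    ms <- tab$`Mean Sq`; rn <- rownames(tab)
    ms_v <- ms[rn == "v"]; ms_e <- ms[rn == "Residuals"]
    s2 <- ms_e
    s2ge <- NA_real_
    s2g <- max(0, (ms_v - ms_e) / r)
  }
  structure(list(sigma2_g = s2g, sigma2_e = s2, sigma2_ge = s2ge,
                 r = r, e = e, trait = trait),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components%s: sigma2_g = %.4g, sigma2_e = %.4g",
              if (!is.null(x$trait)) paste0(" (", x$trait, ")") else "",
              x$sigma2_g, x$sigma2_e))
  if (is.finite(x$sigma2_ge)) cat(sprintf(", sigma2_ge = %.4g", x$sigma2_ge))
  cat(sprintf("  [r = %g, e = %g]\n", x$r, x$e))
  invisible(x)
}

#' Broad-sense heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / r)`: the fraction of the
#' variance of a variety mean attributable to genotype. An optional
#' multi-environment form
#' `sigma2_g / (sigma2_g + sigma2_ge / e + sigma2_e / (r e))` is available
#' when the genotype-by-environment component was estimated.
#'
#' @param vc A `variance_components` object (or a list with `sigma2_g`,
#'   `sigma2_e`, `r`, optionally `sigma2_ge`, `e`).
#' @param multi_env Use the multi-environment denominator (default
#'   `FALSE`).
#' @return H2 in `[0, 1]`.
#' @export
broad_sense_heritability <- function(vc, multi_env = FALSE) {
  s2g <- vc$sigma2_g; s2 <- vc$sigma2_e; r <- vc$r
  if (any(c(s2g, s2) < 0)) stop("variances must be >= 0")
  den <- if (multi_env) {
    if (!is.finite(vc$sigma2_ge)) stop("no genotype-by-environment component available")
    s2g + vc$sigma2_ge / vc$e + s2 / (r * vc$e)
  } else s2g + s2 / r
  if (den <= 0) stop("all variance components are zero: H2 undefined")
  s2g / den
}

#' Percent reduction relative to a reference treatment mean
#'
#' `100 * (mean_reference - mean_other) / mean_reference`, e.g. the
#' rainfed reduction relative to full irrigation.
#'
#' @param mean_reference Reference mean (> 0).
#' @param mean_other Comparison mean.
#' @param digits Rounding for reporting (`NULL` keeps full precision,
#'   the default; the field convention is integer percent).
#' @return Percent reduction.
#' @export
treatment_reduction <- function(mean_reference, mean_other, digits = NULL) {
  if (any(mean_reference <= 0)) stop("reference mean must be positive")
  out <- 100 * (mean_reference - mean_other) / mean_reference
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Pearson correlation between variety means of two traits
#'
#' Aggregates to variety means (if a variety column is given) and returns
#' the Pearson correlation coefficient between the two traits.
#'
#' @param data Data frame of variety means, or plot-level data with a
#'   `variety` column to aggregate.
#' @param trait_x,trait_y Trait column names.
#' @param variety Optional variety column name for aggregation (`NULL` if
#'   `data` already holds one row per variety).
#' @return Pearson r.
#' @export
variety_mean_correlation <- function(data, trait_x, trait_y, variety = NULL) {
  if (!is.null(variety)) {
    agg <- stats::aggregate(data[, c(trait_x, trait_y)],
                            by = list(data[[variety]]), FUN = mean)
    data <- agg
  }
  x <- data[[trait_x]]; y <- data[[trait_y]]
  if (length(x) < 3) stop("need at least 3 variety means")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the traits")
  stats::cor(x, y)
}

#' Gravimetric to volumetric soil water content
#'
#' `theta_v = theta_g * bulk_density` (bulk density in g cm-3).
#'
#' @param gravimetric Gravimetric water content (%), >= 0.
#' @param bulk_density Soil bulk density in g cm-3 (default 1.4).
#' @return Volumetric water content (%).
#' @export
volumetric_soil_water <- function(gravimetric, bulk_density = 1.4) {
  if (any(gravimetric < 0) || any(bulk_density < 0))
    stop("inputs must be >= 0")
  gravimetric * bulk_density
}

#' Soil water depletion between two dates
#'
#' Percentage difference between two readings at each depth:
#' `100 * (reading_t1 - reading_t2) / reading_t1`.
#'
#' @param reading_t1 Earlier readings (per depth), > 0.
#' @param reading_t2 Later readings, same length.
#' @return Percent depletion per depth.
#' @export
soil_water_depletion <- function(reading_t1, reading_t2) {
  if (length(reading_t1) != length(reading_t2))
    stop("readings must have the same length")
  if (any(reading_t1 <= 0)) stop("baseline readings must be positive")
  100 * (reading_t1 - reading_t2) / reading_t1
}

#' Bundled two-year winter-wheat trial summary
#'
#' Variety-mean table of a two-year Mediterranean winter-wheat trial
#' (22 commercial varieties, full irrigation vs rainfed): seasonal mean
#' LAI, season cumulative ETa (mm), grain yield (kg ha-1), cumulative ETa
#' during grain filling and the vegetative phase (mm), and water
#' productivity (kg m-3). `which = "treatment"` returns the two treatment
#' means of the same traits.
#'
#' @param which `"variety"` (default, 22 rows) or `"treatment"` (2 rows).
#' @return Data frame.
#' @export
variety_trial_means <- function(which = c("variety", "treatment")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "variety") "variety_trial_means.csv"
                   else "treatment_means.csv",
                   package = "etintegral", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
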