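# LAI estimation: BIC-selected multiple regression on RGB-derived
# predictors, and a logistic (sigmoid) seasonal growth model.

#' Construct an LAI regression model from known coefficients
#'
#' Builds a `lai_model` object directly from coefficients, e.g. to apply a
#' previously calibrated equation such as
#' `LAI = 5.063 PH + 5.451 VARI - 1.661 fc - 1.071`.
#'
#' @param intercept Intercept (LAI units).
#' @param ph,vari,fc Coefficients of plant height (per m), VARI and
#'   fractional cover; use `NULL` to omit a predictor.
#' @return Object of class `lai_model`.
#' @export
lai_model <- function(intercept, ph = NULL, vari = NULL, fc = NULL) {
  coefs <- c(intercept = intercept,
             if (!is.null(ph)) c(ph = ph),
             if (!is.null(vari)) c(vari = vari),
             if (!is.null(fc)) c(fc = fc))
  structure(list(coefficients = coefs,
                 predictors = setdiff(names(coefs), "intercept"),
                 r_squared = NA_real_, rmse = NA_real_, bic = NA_real_,
                 n = NA_integer_, search = NULL),
            class = "lai_model")
}

# BIC of an OLS fit in the standard form n*ln(RSS/n) + k*ln(n),
# k counting the intercept
.ols_bic <- function(rss, n, k) n * log(rss / n) + k * log(n)

#' Calibrate the LAI multiple regression by exhaustive BIC selection
#'
#' Fits ordinary least squares for every non-empty subset of the candidate
#' predictors (plant height, VARI, fractional cover) and keeps the subset
#' with the lowest Bayesian information criterion on the calibration set.
#'
#' @param data Data frame with a measured `lai` column and the candidate
#'   predictor columns; rows with missing values are dropped.
#' @param predictors Candidate predictor names (default
#'   `c("ph", "vari", "fc")`).
#' @param response Name of the measured-LAI column (default `"lai"`).
#' @return Object of class `lai_model` with the selected coefficients,
#'   calibration fit statistics (`r_squared`, `rmse`, `bic`, `n`) and a
#'   `search` table with the BIC of every candidate subset.
#' @export
fit_lai_regression <- function(data, predictors = c("ph", "vari", "fc"),
                               response = "lai") {
  if (length(predictors) < 1) stop("at least one candidate predictor is required")
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[, c(response, predictors)]), , drop = FALSE]
  n <- nrow(data)
  if (n < 8) stop("need at least 8 complete observations, got ", n)
  if (n <= length(predictors) + 1)
    stop("too few observations for the number of predictors")

  subsets <- unlist(lapply(seq_along(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  y <- data[[response]]
  search <- lapply(subsets, function(vars) {
    x <- cbind(intercept = 1, as.matrix(data[, vars, drop = FALSE]))
    fit <- stats::lm.fit(x, y)
    if (fit$rank < ncol(x)) return(NULL)   # rank-deficient subset
    rss <- sum(fit$residuals^2)
    list(vars = vars, coef = fit$coefficients, rss = rss,
         bic = .ols_bic(rss, n, ncol(x)))
  })
  search <- Filter(Negate(is.null), search)
  if (!length(search)) stop("rank-deficient design: no predictor subset is estimable")
  bics <- vapply(search, `[[`, numeric(1), "bic")
  best <- search[[which.min(bics)]]
  rss <- best$rss
  structure(list(coefficients = best$coef,
                 predictors = best$vars,
                 r_squared = 1 - rss / sum((y - mean(y))^2),
                 rmse = sqrt(rss / n),
                 bic = best$bic,
                 n = n,
                 search = data.frame(
                   subset = vapply(search, function(s)
                     paste(s$vars, collapse = "+"), character(1)),
                   k = vapply(search, function(s) length(s$vars) + 1L, integer(1)),
                   bic = bics)),
            class = "lai_model")
}

#' Predict LAI from plant height, VARI and fractional cover
#'
#' Evaluates the linear LAI equation. The raw linear value is returned by
#' default; negative predictions can optionally be floored at 0.
#'
#' @param object A `lai_model`.
#' @param ph,vari,fc Predictor values (vectorised); each predictor used by
#'   the model must be supplied.
#' @param floor If `TRUE`, floor predictions at 0.
#' @param ... Unused.
#' @return Predicted LAI.
#' @export
predict.lai_model <- function(object, ph = NULL, vari = NULL, fc = NULL,
                              floor = FALSE, ...) {
  supplied <- list(ph = ph, vari = vari, fc = fc)
  out <- rep(object$coefficients[["intercept"]],
             max(1, lengths(supplied)))
  for (v in object$predictors) {
    if (is.null(supplied[[v]]))
      stop("predictor '", v, "' is required by this model")
    out <- out + object$coefficients[[v]] * supplied[[v]]
  }
  if (floor) out <- pmax(out, 0)
  out
}

#' @export
coef.lai_model <- function(object, ...) object$coefficients

#' @export
print.lai_model <- function(x, ...) {
  cat("LAI regression model\n  LAI =",
      paste(sprintf("%+.4g*%s", x$coefficients[x$predictors], x$predictors),
            collapse = " "),
      sprintf("%+.4g", x$coefficients[["intercept"]]), "\n")
  if (is.finite(x$r_squared))
    cat(sprintf("  calibration: n = %d, R2 = %.3f, RMSE = %.3f, BIC = %.2f\n",
                x$n, x$r_squared, x$rmse, x$bic))
  invisible(x)
}

#' @export
summary.lai_model <- function(object, ...) {
  print(object)
  if (!is.null(object$search)) {
    cat("  subset search (lower BIC is better):\n")
    s <- object$search[order(object$search$bic), ]
    print(s, row.names = FALSE)
  }
  invisible(object)
}

# deterministic starting values for the logistic curve
.sigmoid_start <- function(das, lai) {
  c0 <- max(lai)
  half <- c0 / 2
  b0 <- tryCatch(stats::approx(lai, das, xout = half, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(b0)) b0 <- stats::median(das)
  t20 <- tryCatch(stats::approx(lai, das, xout = 0.2 * c0, ties = mean)$y,
                  error = function(e) NA_real_)
  t80 <- tryCatch(stats::approx(lai, das, xout = 0.8 * c0, ties = mean)$y,
                  error = function(e) NA_real_)
  a0 <- if (is.finite(t20) && is.finite(t80) && t80 > t20) 4 / (t80 - t20)
  else 4 / max(diff(range(das)), 1)
  c(a = a0, b = b0, c = c0)
}

#' Fit the seasonal logistic LAI growth curve
#'
#' Nonlinear least squares for `LAI(DAS) = c / (1 + exp(-a (DAS - b)))`,
#' where `a` is the slope, `b` the DAS of steepest growth (midpoint) and
#' `c` the asymptote. Initialisation is deterministic (asymptote from the
#' maximum observation, midpoint by inverse interpolation at half the
#' asymptote, slope from the 20-80% rise interval); if the optimiser fails
#' a bounded sequence of deterministically perturbed starts is tried
#' before failing with diagnostics.
#'
#' @param das Days after sowing of the observations.
#' @param lai Observed or estimated LAI at those days (>= 4 values
#'   spanning the rising part of the curve).
#' @return Object of class `sigmoid_lai` with `coefficients` `(a, b, c)`,
#'   `fitted`, `residuals` and `rmse`.
#' @export
fit_sigmoid_lai <- function(das, lai) {
  ok <- is.finite(das) & is.finite(lai)
  das <- das[ok]; lai <- lai[ok]
  if (length(das) < 4) stop("need at least 4 observations to fit the sigmoid")
  start <- .sigmoid_start(das, lai)
  perturb <- list(c(1, 1, 1), c(0.5, 1, 1), c(2, 1, 1), c(1, 0.8, 1.2),
                  c(1, 1.2, 1.1), c(0.25, 0.9, 1.5), c(3, 1.1, 0.9))
  dat <- data.frame(das = das, lai = lai)
  last_err <- NULL
  for (p in perturb) {
    st <- list(a = start[["a"]] * p[1], b = start[["b"]] * p[2],
               c = start[["c"]] * p[3])
    fit <- tryCatch(
      minpack.lm::nlsLM(lai ~ c / (1 + exp(-a * (das - b))), data = dat,
                        start = st,
                        lower = c(a = 1e-5, b = min(das) - 200, c = 1e-3),
                        upper = c(a = 5, b = max(das) + 200,
                                  c = 10 * max(lai)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      res <- lai - cf[["c"]] / (1 + exp(-cf[["a"]] * (das - cf[["b"]])))
      return(structure(list(coefficients = cf,
                            fitted = lai - res, residuals = res,
                            rmse = sqrt(mean(res^2)),
                            start = unlist(st), n = length(das)),
                       class = "sigmoid_lai"))
    }
  }
  stop("sigmoid fit did not converge after bounded restarts; last error: ",
       last_err, "; start = (a=", signif(start[["a"]], 3),
       ", b=", signif(start[["b"]], 3), ", c=", signif(start[["c"]], 3), ")")
}

#' @export
coef.sigmoid_lai <- function(object, ...) object$coefficients

#' @export
predict.sigmoid_lai <- function(object, das, ...) {
  cf <- object$coefficients
  cf[["c"]] / (1 + exp(-cf[["a"]] * (das - cf[["b"]])))
}

#' @export
print.sigmoid_lai <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "Logistic LAI growth curve: c/(1+exp(-a(DAS-b))) with a = %.4g, b = %.4g, c = %.4g\n",
    cf[["a"]], cf[["b"]], cf[["c"]]))
  cat(sprintf("  n = %d, RMSE = %.4g\n", x$n, x$rmse))
  invisible(x)
}

#' Daily LAI series from a fitted growth curve
#'
#' Evaluates the logistic curve at every integer DAS from sowing to
#' maturity.
#'
#' @param object A `sigmoid_lai` fit (or a named vector `c(a, b, c)`).
#' @param maturity_das Last day of the series (>= 1).
#' @param sowing_das First day (default 0).
#' @return Data frame with columns `das` and `lai`
#'   (`maturity_das - sowing_das + 1` rows).
#' @export
daily_lai_series <- function(object, maturity_das, sowing_das = 0) {
  if (maturity_das < 1) stop("maturity_das must be >= 1")
  cf <- if (inherits(object, "sigmoid_lai")) object$coefficients else object
  if (!all(c("a", "b", "c") %in% names(cf)) || !all(is.finite(cf)) ||
      cf[["c"]] <= 0)
    stop("invalid sigmoid parameters")
  das <- seq.int(sowing_das, maturity_das)
  data.frame(das = das,
             lai = cf[["c"]] / (1 + exp(-cf[["a"]] * (das - cf[["b"]]))))
}
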