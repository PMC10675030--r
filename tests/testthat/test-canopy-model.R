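make_lai_data <- function(n, beta = c(intercept = -1.071, ph = 5.063,
                                      vari = 5.451, fc = -1.661),
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(ph = runif(n, 0.1, 1), vari = runif(n, 0, 0.8),
                  fc = runif(n, 0, 1))
  d$lai <- beta[["intercept"]] + beta[["ph"]] * d$ph +
    beta[["vari"]] * d$vari + beta[["fc"]] * d$fc + rnorm(n, 0, noise_sd)
  d
}

test_that("noise-free calibration recovers the generating coefficients exactly", {
  d <- make_lai_data(40)
  m <- fit_lai_regression(d)
  expect_setequal(m$predictors, c("ph", "vari", "fc"))
  expect_equal(unname(coef(m)[c("intercept", "ph", "vari", "fc")]),
               c(-1.071, 5.063, 5.451, -1.661), tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("BIC subset selection finds the true sparse model among noise predictors", {
  set.seed(5)
  d <- data.frame(ph = runif(200, 0.1, 1), vari = rnorm(200),
                  fc = runif(200))
  d$lai <- 0.5 + 4 * d$ph + rnorm(200, 0, 0.2)
  m <- fit_lai_regression(d)
  expect_identical(m$predictors, "ph")
  # the search table covers all 7 non-empty subsets
  expect_equal(nrow(m$search), 7)
  expect_equal(min(m$search$bic), m$bic)
})

test_that("selected subset equals exhaustive enumeration with an lm oracle", {
  set.seed(9)
  d <- make_lai_data(60, noise_sd = 0.4, seed = 9)
  m <- fit_lai_regression(d)
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(c("ph", "vari", "fc"), k, simplify = FALSE)),
    recursive = FALSE)
  oracle <- vapply(subsets, function(v) {
    fit <- stats::lm(stats::reformulate(v, "lai"), data = d)
    n <- nrow(d)
    n * log(sum(stats::residuals(fit)^2) / n) + (length(v) + 1) * log(n)
  }, numeric(1))
  best <- subsets[[which.min(oracle)]]
  expect_setequal(m$predictors, best)
  expect_equal(m$bic, min(oracle), tolerance = 1e-10)
})

test_that("adding an irrelevant candidate does not change the selected model", {
  for (s in 1:5) {
    set.seed(100 + s)
    d <- data.frame(ph = runif(80, 0.1, 1), vari = rnorm(80), fc = runif(80))
    d$lai <- 1 + 3 * d$ph + rnorm(80, 0, 0.3)
    m1 <- fit_lai_regression(d, predictors = "ph")
    m2 <- fit_lai_regression(d, predictors = c("ph", "vari"))
    expect_identical(m2$predictors, "ph")
    expect_equal(m2$bic, m1$bic)
  }
})

test_that("degenerate calibration inputs are rejected", {
  d <- make_lai_data(3)
  expect_error(fit_lai_regression(d), "at least 8")
  d <- make_lai_data(20)
  d$vari <- 2 * d$ph   # collinear -> full subset rank-deficient, others fine
  m <- fit_lai_regression(d)
  expect_false(all(c("ph", "vari") %in% m$predictors))
  expect_error(fit_lai_regression(d[0, ]), "at least 8")
})

test_that("OLS coefficients equal the normal-equations brute force on small instances", {
  for (s in 1:5) {
    d <- make_lai_data(20 + 5 * s, noise_sd = 0.5, seed = 200 + s)
    m <- fit_lai_regression(d)
    x <- cbind(1, as.matrix(d[, m$predictors]))
    beta <- solve(t(x) %*% x, t(x) %*% d$lai)
    expect_equal(unname(coef(m)), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("the published-coefficient model evaluates the linear equation", {
  m <- lai_model(-1.071, ph = 5.063, vari = 5.451, fc = -1.661)
  expect_equal(predict(m, ph = 0, vari = 0, fc = 0), -1.071)
  expect_equal(predict(m, ph = 0.5, vari = 0.3, fc = 0.5), 2.2653)
  zero <- lai_model(0, ph = 0, vari = 0, fc = 0)
  expect_equal(predict(zero, ph = 3, vari = -2, fc = 9), 0)
  expect_error(predict(m, ph = 0.5, vari = 0.3), "required")
  expect_equal(predict(m, ph = 0, vari = 0, fc = 1, floor = TRUE), 0)
})

test_that("sigmoid fit recovers noise-free parameters to 1e-6 relative", {
  das <- seq(60, 180, by = 10)
  truth <- c(a = 0.10, b = 120, c = 6.0)
  lai <- truth[["c"]] / (1 + exp(-truth[["a"]] * (das - truth[["b"]])))
  fit <- fit_sigmoid_lai(das, lai)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  # curve value at the midpoint is half the asymptote
  expect_equal(predict(fit, das = coef(fit)[["b"]]),
               coef(fit)[["c"]] / 2)
  # asymptote at large DAS
  expect_equal(predict(fit, das = 1e6), coef(fit)[["c"]])
})

test_that("sigmoid fitting is deterministic and needs enough observations", {
  das <- seq(60, 180, by = 12)
  lai <- 5 / (1 + exp(-0.09 * (das - 115))) + sin(das / 7) * 0.1
  f1 <- fit_sigmoid_lai(das, lai)
  f2 <- fit_sigmoid_lai(das, lai)
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_sigmoid_lai(c(60, 80, 100), c(1, 2, 3)), "at least 4")
})

test_that("asymptote is recovered within 10% under observation noise", {
  truth <- c(a = 0.10, b = 120, c = 6.0)
  das <- seq(60, 180, length.out = 12)
  clean <- truth[["c"]] / (1 + exp(-truth[["a"]] * (das - truth[["b"]])))
  set.seed(314)
  rel_err <- replicate(100, {
    fit <- fit_sigmoid_lai(das, clean + rnorm(12, 0, 0.3))
    abs(coef(fit)[["c"]] - truth[["c"]]) / truth[["c"]]
  })
  expect_gte(mean(rel_err < 0.10), 0.9)
  expect_lt(mean(rel_err), 0.10)
})

test_that("daily LAI series is dense, monotone for a > 0 and anchored at c/2", {
  fit <- structure(list(coefficients = c(a = 0.12, b = 110, c = 5.5)),
                   class = "sigmoid_lai")
  ser <- daily_lai_series(fit, maturity_das = 170)
  expect_equal(nrow(ser), 171)
  expect_true(all(diff(ser$lai) > 0))
  expect_equal(ser$lai[ser$das == 110], 5.5 / 2, tolerance = 1e-12)
  expect_error(daily_lai_series(fit, maturity_das = 0), ">= 1")
  bad <- structure(list(coefficients = c(a = 0.1, b = 100, c = -2)),
                   class = "sigmoid_lai")
  expect_error(daily_lai_series(bad, 100), "invalid")
})
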