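balanced_trial <- function(n_var = 22, r = 3, sd_g = 2, sd_e = 1) {
  g <- rnorm(n_var, 0, sd_g)
  data.frame(variety = rep(paste0("V", seq_len(n_var)), each = r),
             block = rep(seq_len(r), n_var),
             y = rep(g, each = r) + rnorm(n_var * r, 0, sd_e))
}

test_that("variance components are zero for constant data and need replication", {
  d <- data.frame(variety = rep(c("A", "B"), each = 3),
                  block = rep(1:3, 2), y = 5)
  vc <- variance_components(d, "y")
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_e, 0)
  d1 <- data.frame(variety = c("A", "B"), block = 1, y = c(1, 2))
  expect_error(variance_components(d1, "y"), "single replicate")
  expect_error(variance_components(data.frame(variety = "A", block = 1:3,
                                              y = 1:3), "y"),
               "2 varieties")
})

test_that("method-of-moments genotypic variance is unbiased in simulation", {
  set.seed(55)
  est <- replicate(500, variance_components(balanced_trial(), "y")$sigma2_g)
  expect_lt(abs(mean(est) - 4) / 4, 0.10)
  # no genetic signal: truncated-at-zero estimates stay near zero on average
  est0 <- replicate(300,
                    variance_components(balanced_trial(sd_g = 0), "y")$sigma2_g)
  expect_lt(mean(est0), 0.25)
  expect_true(all(est0 >= 0))
})

test_that("multi-environment components separate genotype and interaction variance", {
  set.seed(77)
  n_var <- 15; r <- 3; e <- 2
  g <- rnorm(n_var, 0, 2)
  d <- expand.grid(variety = paste0("V", seq_len(n_var)),
                   block = seq_len(r), env = paste0("E", seq_len(e)))
  ge <- rnorm(n_var * e, 0, 1)
  d$y <- g[as.integer(factor(d$variety))] +
    ge[as.integer(interaction(d$variety, d$env))] + rnorm(nrow(d), 0, 1)
  vc <- variance_components(d, "y", env = "env")
  expect_equal(vc$e, 2)
  expect_gt(vc$sigma2_g, 0.5)
  expect_true(is.finite(vc$sigma2_ge))
  h2 <- broad_sense_heritability(vc, multi_env = TRUE)
  expect_gt(h2, 0); expect_lt(h2, 1)
})

test_that("broad-sense heritability follows the variance-ratio formula", {
  expect_equal(broad_sense_heritability(list(sigma2_g = 1, sigma2_e = 1, r = 1)),
               0.5)
  expect_equal(broad_sense_heritability(list(sigma2_g = 0, sigma2_e = 2, r = 3)),
               0)
  expect_equal(broad_sense_heritability(list(sigma2_g = 3, sigma2_e = 2, r = 4)),
               3 / 3.5)
  expect_error(broad_sense_heritability(list(sigma2_g = 0, sigma2_e = 0, r = 2)),
               "undefined")
})

test_that("heritability is bounded in [0,1] and monotone in replication", {
  set.seed(5)
  for (i in 1:20) {
    s2g <- runif(1, 0, 5); s2 <- runif(1, 0.01, 5)
    h <- vapply(1:6, function(r)
      broad_sense_heritability(list(sigma2_g = s2g, sigma2_e = s2, r = r)),
      numeric(1))
    expect_true(all(h >= 0 & h <= 1))
    if (s2g > 0) expect_true(all(diff(h) > 0))
  }
})

test_that("treatment reduction is the relative difference in percent", {
  expect_equal(treatment_reduction(10, 10), 0)
  expect_equal(treatment_reduction(97.2, 46.4, digits = 0), 52)
  expect_equal(treatment_reduction(3.8, 3.3, digits = 0), 13)
  expect_error(treatment_reduction(0, 1), "positive")
})

test_that("variety-mean correlation equals a covariance/sd brute-force oracle", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    d <- data.frame(x = rnorm(n), y = rnorm(n))
    ours <- variety_mean_correlation(d, "x", "y")
    num <- sum((d$x - mean(d$x)) * (d$y - mean(d$y)))
    den <- sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
    expect_equal(ours, num / den, tolerance = 1e-12)
  }
  lin <- data.frame(x = 1:5, y = 2 * (1:5) + 3)
  expect_equal(variety_mean_correlation(lin, "x", "y"), 1)
  expect_error(variety_mean_correlation(data.frame(x = rep(1, 5), y = 1:5),
                                        "x", "y"), "zero variance")
  expect_error(variety_mean_correlation(data.frame(x = 1:2, y = 2:3),
                                        "x", "y"), "at least 3")
})

test_that("plot-level data aggregate to variety means before correlating", {
  d <- data.frame(variety = rep(c("A", "B", "C"), each = 2),
                  x = c(1, 3, 4, 6, 9, 11), y = c(2, 2, 5, 5, 8, 8))
  means <- data.frame(x = c(2, 5, 10), y = c(2, 5, 8))
  expect_equal(variety_mean_correlation(d, "x", "y", variety = "variety"),
               variety_mean_correlation(means, "x", "y"))
})

test_that("soil water conversions follow the bulk-density and baseline arithmetic", {
  expect_equal(volumetric_soil_water(20, 1.4), 28)
  expect_equal(volumetric_soil_water(0), 0)
  expect_equal(volumetric_soil_water(17.3, 1), 17.3)
  expect_error(volumetric_soil_water(-2), ">= 0")
  expect_equal(soil_water_depletion(30, 24), 20)
  expect_equal(soil_water_depletion(c(30, 25, 40), c(30, 20, 30)),
               c(0, 20, 25))
  expect_error(soil_water_depletion(0, 5), "positive")
  expect_error(soil_water_depletion(c(1, 2), 1), "same length")
})

test_that("the bundled trial summary is intact and internally consistent", {
  v <- variety_trial_means()
  expect_equal(nrow(v), 22)
  tm <- variety_trial_means("treatment")
  expect_equal(nrow(tm), 2)
  expect_setequal(names(v)[-1], names(tm)[-1])
  expect_true(all(v$eta > 0 & v$gy > 0 & v$wp > 0))
  # the Variety 20 row satisfies the WP unit identity at printed precision
  v20 <- v[v$variety == "Variety 20", ]
  expect_equal(round(water_productivity(v20$gy, v20$eta), 1), v20$wp)
})
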