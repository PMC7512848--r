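test_that("perfect-fit counts recover theta exactly with zero divergence", {
  fit <- fit_mphi(c(25, 25, 25, 25), "example3-hw", phi = 1, h = 2)
  expect_equal(fit$theta_hat, 0.5, tolerance = 1e-8)
  expect_lt(fit$min_divergence, 1e-14)
  fit2 <- fit_mphi(c(25, 25, 25, 25), "example3-hw", phi = -2, h = 0.5)
  expect_equal(fit2$theta_hat, 0.5, tolerance = 1e-8)
})

test_that("optimizer agrees with an independent grid-search oracle", {
  set.seed(11)
  for (name in list_models()) {
    m <- mphi_model(name)
    for (rep in 1:17) {
      X <- random_counts(m$k, n = 60L)
      lam <- sample(c(-2, 0, 1), 1)
      h <- sample(c(0.5, 1, 2), 1)
      fit <- pendiv:::.fit_theta(X, m, power_divergence(lam), h)
      oracle <- oracle_grid_min(X / sum(X), m, power_divergence(lam), h)
      expect_lt(abs(fit$theta - oracle), 1e-5,
                label = sprintf("%s counts=(%s) lam=%g h=%g fit=%g oracle=%g; diff",
                                name, paste(X, collapse = ","), lam, h,
                                fit$theta, oracle))
    }
  }
})

test_that("penalty is inert when all cells are observed", {
  X <- c(17, 61, 122)
  fits <- lapply(c(0.5, 1, 2), function(h)
    fit_mphi(X, "example1", phi = -2, h = h)$theta_hat)
  expect_identical(fits[[1]], fits[[2]])
  expect_identical(fits[[1]], fits[[3]])
})

test_that("projection parameter recovers model members and matches grid search", {
  m3 <- mphi_model("example3-hw")
  th0 <- projection_parameter(model_probs(m3, 0.2), m3, phi = -2, h = 1)
  expect_equal(as.numeric(th0), 0.2, tolerance = 1e-7)
  m1 <- mphi_model("example1")
  pi <- c(0.3, 0.3, 0.4)
  th0 <- projection_parameter(pi, m1, phi = 1, h = 1)
  expect_equal(as.numeric(th0),
               oracle_grid_min(pi, m1, power_divergence(1), 1),
               tolerance = 1e-5)
  expect_lt(attr(th0, "gradient_norm"), 1e-6)
  # no empty cells: h plays no role in the projection
  expect_equal(as.numeric(projection_parameter(pi, m1, phi = 1, h = 0.5)),
               as.numeric(projection_parameter(pi, m1, phi = 1, h = 2)))
})

test_that("stationarity condition holds at interior fits", {
  for (X in list(c(165, 13, 7, 0), c(172, 5, 5, 0))) {
    for (h in c(0.5, 1, 2)) {
      fit <- fit_mphi(X, "example3-hw", phi = -2, h = h)
      expect_false(fit$boundary)
      expect_lt(fit$gradient_norm, 1e-6)
    }
  }
})

test_that("consistency: estimation error shrinks at the root-n rate", {
  set.seed(23)
  med_err <- vapply(c(250, 1000, 4000), function(n) {
    X <- simulate_counts("example3-hw", 0.8, n, 400, seed = n)
    errs <- vapply(seq_len(400), function(r)
      abs(pendiv:::.fit_theta(X[, r], mphi_model("example3-hw"),
                              power_divergence(-2), 0.5)$theta - 0.8),
      numeric(1))
    median(errs)
  }, numeric(1))
  # quadrupling n should halve the median error, up to MC wiggle
  expect_gt(med_err[1] / med_err[2], 1.5)
  expect_lt(med_err[1] / med_err[2], 2.7)
  expect_gt(med_err[2] / med_err[3], 1.5)
  expect_lt(med_err[2] / med_err[3], 2.7)
})

test_that("asymptotic covariance reduces to inverse Fisher information at the model", {
  m3 <- mphi_model("example3-hw")
  # theta-hat is a mean of 2n Bernoulli(theta) trials: var of sqrt(n) scaled
  # estimate is theta (1 - theta) / 2
  V <- asymptotic_covariance(model_probs(m3, 0.5), m3, 0.5, phi = 0, h = 1)
  expect_equal(V[1, 1], 0.125, tolerance = 1e-10)
  V <- asymptotic_covariance(model_probs(m3, 0.8), m3, 0.8, phi = 0, h = 1)
  expect_equal(V[1, 1], 0.8 * 0.2 / 2, tolerance = 1e-8)
  expect_true(isSymmetric(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values >= -1e-12))
})

test_that("asymptotic covariance matches Monte Carlo under misspecification", {
  m1 <- mphi_model("example1")
  pi <- c(0.3, 0.3, 0.4)       # outside the family
  th0 <- as.numeric(projection_parameter(pi, m1, phi = 1, h = 1))
  V <- asymptotic_covariance(pi, m1, th0, phi = 1, h = 1)[1, 1]
  n <- 10000L; reps <- 20000L
  X <- pendiv:::.with_seed(31, stats::rmultinom(reps, n, pi))
  th <- vapply(seq_len(reps), function(r)
    pendiv:::.fit_theta(X[, r], m1, power_divergence(1), 1)$theta, numeric(1))
  expect_equal(n * var(th), V, tolerance = 0.05)
})

test_that("rho-squared matches the Monte Carlo variance of the centered divergence", {
  m1 <- mphi_model("example1")
  pi <- c(0.25, 0.35, 0.4)
  ms <- misspec_summary(pi, m1, phi1 = 1, h1 = 1, phi2 = 1, h2 = 1)
  expect_gt(ms$limit_divergence, 0)
  expect_gte(ms$rho2, 0)
  n <- 10000L; reps <- 20000L
  X <- pendiv:::.with_seed(37, stats::rmultinom(reps, n, pi))
  W <- vapply(seq_len(reps), function(r) {
    f <- pendiv:::.fit_theta(X[, r], m1, power_divergence(1), 1)
    penalized_divergence(X[, r] / n, m1$probs(f$theta), 1, 1)
  }, numeric(1))
  expect_equal(n * var(W), ms$rho2, tolerance = 0.10)
})

test_that("rho-squared is free of the penalties when no cell is empty", {
  m1 <- mphi_model("example1")
  pi <- c(0.25, 0.35, 0.4)
  r <- vapply(list(c(0.5, 0.5), c(1, 2), c(2, 1)), function(hh)
    misspec_summary(pi, m1, phi1 = -2, h1 = hh[1],
                    phi2 = -2, h2 = hh[2])$rho2, numeric(1))
  expect_equal(r[1], r[2], tolerance = 1e-9)
  expect_equal(r[1], r[3], tolerance = 1e-9)
})

test_that("sqrt(n)-scaled estimates are approximately normal at large n", {
  m3 <- mphi_model("example3-hw")
  n <- 10000L; reps <- 5000L
  sigma <- sqrt(asymptotic_covariance(model_probs(m3, 0.8), m3, 0.8,
                                      phi = 0, h = 1)[1, 1])
  X <- simulate_counts(m3, 0.8, n, reps, seed = 41)
  z <- vapply(seq_len(reps), function(r)
    sqrt(n) * (pendiv:::.fit_theta(X[, r], m3, power_divergence(0), 1)$theta
               - 0.8) / sigma, numeric(1))
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_lt(abs(sample_skewness(z)), 0.15)
  expect_lt(abs(sample_kurtosis(z)), 0.3)
})

test_that("estimation rejects invalid inputs", {
  expect_error(fit_mphi(c(0, 0, 0, 0), "example3-hw", phi = -2, h = 1),
               "all zero")
  expect_error(fit_mphi(c(1.5, 2, 3, 4), "example3-hw", phi = -2, h = 1),
               "integers")
  expect_error(fit_mphi(c(10, 5, 5, 2), "example3-hw", phi = -2, h = -1),
               "positive")
  expect_error(fit_mphi(c(10, 5, 5), "example3-hw", phi = -2, h = 1),
               "cells")
})
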