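test_that("power-divergence generator matches its closed forms and limits", {
  expect_identical(pd_lambda(0, 1), 0)
  expect_equal(pd_lambda(1, 3), 2)                  # (x-1)^2/2
  expect_equal(pd_lambda(-2, 2), 0.25)              # (x-1)^2/(2x)
  # lambda = 0 and -1 are continuity limits of the generic formula
  x <- c(0.2, 0.7, 1, 1.9, 5)
  expect_equal(pd_lambda(1e-9, x), pd_lambda(0, x), tolerance = 1e-6)
  expect_equal(pd_lambda(-1 + 1e-9, x), pd_lambda(-1, x), tolerance = 1e-6)
  # nonnegativity, zero only at 1
  for (lam in c(-2, -1, 0, 1, 2, 0.7)) {
    expect_true(all(pd_lambda(lam, x) >= 0))
    expect_equal(pd_lambda(lam, 1), 0)
  }
  expect_error(pd_lambda(1, -1), "positive")
  expect_error(pd_lambda(Inf, 2), "finite")
})

test_that("phi(0) limits and derivative consistency of phi_spec objects", {
  expect_equal(power_divergence(1)$value_at_0, 0.5)
  expect_equal(power_divergence(0)$value_at_0, 1)
  expect_identical(power_divergence(-1)$value_at_0, Inf)
  expect_identical(power_divergence(-2)$value_at_0, Inf)
  # finite-difference check of d1 and d2 at probe points
  for (lam in c(-2, -0.5, 0, 1, 2)) {
    phi <- power_divergence(lam)
    expect_equal(phi$value_at_1, 0)
    expect_equal(phi$d2_at_1, 1)
    for (x0 in c(0.3, 1.4, 3)) {
      fd1 <- (phi$value(x0 + 1e-6) - phi$value(x0 - 1e-6)) / 2e-6
      fd2 <- (phi$d1(x0 + 1e-6) - phi$d1(x0 - 1e-6)) / 2e-6
      expect_equal(phi$d1(x0), fd1, tolerance = 1e-6)
      expect_equal(phi$d2(x0), fd2, tolerance = 1e-6)
      expect_gt(phi$d2(x0), 0)
    }
  }
})

test_that("generic phi_spec accepts callables and flags non-convexity", {
  phi <- phi_spec(value = function(x) (x - 1)^2 / 2,
                  d1 = function(x) x - 1,
                  d2 = function(x) rep(1, length(x)),
                  value_at_0 = 0.5)
  expect_equal(phi$value(3), pd_lambda(1, 3))
  expect_warning(
    phi_spec(value = function(x) -(x - 1)^2, d1 = function(x) -2 * (x - 1),
             d2 = function(x) rep(-2, length(x)), value_at_0 = -1),
    "convex")
})

test_that("phi-divergence handles identity, sparsity and hand-computed cases", {
  q <- rep(0.25, 4)
  expect_equal(phi_divergence(q, q, 1), 0)
  expect_equal(phi_divergence(c(.5, .5), c(.25, .75), 1), 0.125 + 1 / 24)
  expect_identical(phi_divergence(c(.5, .5, 0), c(.25, .25, .5), -2), Inf)
  # finite phi(0): empty cell contributes phi(0) * p
  expect_equal(phi_divergence(c(.5, .5, 0), c(.25, .25, .5), 1),
               0.125 + 0.125 + 0.5 * 0.5)
  expect_error(phi_divergence(c(.5, .5), c(.25, .25, .5), 1), "length")
  expect_error(phi_divergence(c(.5, .5), c(0, 1), 1), "positive")
})

test_that("penalized divergence is finite, matches hand arithmetic, and ignores h without empty cells", {
  expect_equal(penalized_divergence(c(.5, .5, 0), c(.25, .25, .5), 1, h = 0.7),
               0.125 + 0.125 + 0.7 * 0.5)
  q <- c(0.2, 0.3, 0.5); p <- c(0.3, 0.3, 0.4)
  for (lam in c(-2, -1, 0, 1, 2))
    expect_identical(penalized_divergence(q, p, lam, h = 0.5),
                     penalized_divergence(q, p, lam, h = 100))
  expect_equal(penalized_divergence(q, q, -2, h = 3), 0)
  # sparse input stays finite for every lambda, h
  qs <- c(0.6, 0.4, 0, 0)
  ps <- c(0.5, 0.3, 0.1, 0.1)
  for (lam in c(-2, -1, 0, 1, 2, 0.65))
    expect_true(is.finite(penalized_divergence(qs, ps, lam, h = 2)))
  expect_error(penalized_divergence(q, p, 1, h = Inf), "finite")
})

test_that("stable per-cell forms agree with the generic power formula", {
  set.seed(1)
  for (lam in c(-2, -1, 0, 1, 2)) {
    cellf <- pendiv:::.cell_term_fun(power_divergence(lam))
    q <- runif(20, 1e-4, 1); p <- runif(20, 1e-4, 1)
    expect_equal(cellf(q, p), p * pd_lambda(lam, q / p), tolerance = 1e-10)
  }
})

test_that("Pearson and likelihood-ratio equivalences hold on random sparse tables", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    X <- random_counts(k, n = 40L)
    if (sum(X) == 0) next
    n <- sum(X); q <- X / n
    p <- rgamma(k, 2); p <- p / sum(p)
    # Pearson X^2: 2n D_{PD1, 0.5} for any zero pattern
    X2 <- sum((X - n * p)^2 / (n * p))
    expect_equal(2 * n * penalized_divergence(q, p, 1, h = 0.5), X2,
                 tolerance = 1e-10)
    # PD0 with h = 1 coincides with the unpenalized divergence (phi(0) = 1)
    expect_equal(penalized_divergence(q, p, 0, h = 1),
                 phi_divergence(q, p, 0), tolerance = 1e-12)
    # nonnegativity of the penalized divergence
    for (lam in c(-2, 0, 2))
      expect_gte(penalized_divergence(q, p, lam, h = 0.3), 0)
  }
})

test_that("penalized divergence is midpoint-convex in its first argument", {
  set.seed(7)
  p <- c(0.2, 0.3, 0.5)
  for (rep in 1:20) {
    q1 <- rgamma(3, 1); q1 <- q1 / sum(q1)
    q2 <- rgamma(3, 1); q2 <- q2 / sum(q2)
    for (lam in c(-2, 0, 1)) {
      mid <- penalized_divergence((q1 + q2) / 2, p, lam, h = 1)
      avg <- (penalized_divergence(q1, p, lam, h = 1) +
              penalized_divergence(q2, p, lam, h = 1)) / 2
      expect_lte(mid, avg + 1e-12)
    }
  }
})
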