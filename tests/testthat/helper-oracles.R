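# Independent brute-force minimizer: two-stage grid search at 1e-6 final
# resolution over the (clamped) scalar domain.  Kept deliberately separate
# from the package's optimizer so the two routes can disagree.
oracle_grid_min <- function(pi, model, phi, h) {
  stopifnot(model$s == 1L)
  fn <- pendiv:::.make_objective(pi, model, phi, h)
  eps <- 1e-10 * (model$upper - model$lower)
  lo <- model$lower + eps
  hi <- model$upper - eps
  coarse <- seq(lo, hi, length.out = 2001L)
  best <- coarse[which.min(vapply(coarse, fn, numeric(1)))]
  half <- (hi - lo) / 2000
  fine <- seq(max(lo, best - half), min(hi, best + half), by = 1e-6)
  fine[which.min(vapply(fine, fn, numeric(1)))]
}

# Random sparse count vector with at least one positive cell.
random_counts <- function(k, n = 50L) {
  p <- rgamma(k, 0.5)
  as.integer(rmultinom(1, n, p / sum(p)))
}

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
sample_kurtosis <- function(x) mean((x - mean(x))^4) / sd(x)^4 - 3
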