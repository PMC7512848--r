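#' Penalized-divergence goodness-of-fit statistic
#'
#' Computes
#' \deqn{T = \frac{2n}{\phi_1''(1)}\left\{D_{\phi_1,h_1}(\hat\pi,
#'   P(\hat\theta_{\phi_2,h_2})) - \phi_1(1)\right\},}
#' where \eqn{\hat\theta_{\phi_2,h_2}} is the minimum penalized
#' phi-divergence estimate under \eqn{(\phi_2, h_2)}.  Under the null
#' hypothesis that \eqn{\pi} belongs to the model, T converges in law to
#' \eqn{\chi^2_{k-s-1}}, for any choice of the two generators and
#' penalties.  With \eqn{\phi_1 = PD_1, h_1 = 0.5} it is the Pearson
#' \eqn{X^2} statistic evaluated at the fitted probabilities; with
#' \eqn{\phi_1 = PD_0, h_1 = 1} it is the likelihood-ratio \eqn{G^2}.
#'
#' @param counts Vector of k nonnegative integer counts.
#' @param model A \code{multinomial_model} or built-in name.
#' @param phi1,h1 Generator and penalty of the statistic.
#' @param phi2,h2 Generator and penalty of the estimator (default: same).
#' @param n_grid Optimizer grid resolution, passed to the fitter.
#' @return List with \code{T}, \code{theta_hat}, \code{divergence} and
#'   \code{df} = k - s - 1.
#' @examples
#' gof_statistic(c(165, 13, 7, 0), "example3-hw", phi1 = -2, h1 = 0.5)
#' @export
gof_statistic <- function(counts, model, phi1, h1, phi2 = phi1, h2 = h1,
                          n_grid = 64L) {
  if (is.character(model)) model <- mphi_model(model)
  phi1 <- as_phi(phi1); phi2 <- as_phi(phi2)
  counts <- .validate_counts(counts, k = model$k)
  n <- sum(counts)
  pihat <- counts / n
  fit <- .fit_theta(counts, model, phi2, h2, n_grid = n_grid)
  d <- penalized_divergence(pihat, model$probs(fit$theta), phi1, h1)
  list(T = 2 * n / phi1$d2_at_1 * (d - phi1$value_at_1),
       theta_hat = fit$theta, divergence = d, df = model$k - model$s - 1L)
}

#' Asymptotic chi-square p-value of the goodness-of-fit statistic
#'
#' Upper-tail probability of the \eqn{\chi^2_{k-s-1}} law at T; the test
#' rejecting when \eqn{T \ge \chi^2_{k-s-1,1-\alpha}} is asymptotically of
#' level \eqn{\alpha} and consistent against fixed alternatives.
#'
#' @param T Observed statistic, nonnegative.
#' @param k Number of cells.
#' @param s Number of estimated parameters.
#' @return P-value in \code{[0, 1]}.
#' @export
asymptotic_pvalue <- function(T, k, s) {
  df <- k - s - 1
  if (df <= 0) stop("degrees of freedom k - s - 1 must be positive")
  if (!is.numeric(T) || any(T < 0)) stop("'T' must be nonnegative")
  stats::pchisq(T, df = df, lower.tail = FALSE)
}

#' Goodness-of-fit test with asymptotic and bootstrap calibration
#'
#' Tests whether the multinomial probability vector belongs to the
#' parametric family, using the penalized-divergence statistic T of
#' \code{\link{gof_statistic}}.  Besides the asymptotic \eqn{\chi^2}
#' p-value, an optional parametric-bootstrap p-value is computed by the
#' three-step algorithm: draw B multinomial samples of size n from the
#' fitted model \eqn{P(\hat\theta_{\phi_2,h_2})}, refit each with
#' \eqn{(\phi_2, h_2)}, recompute the statistic \eqn{T^*_b} with
#' \eqn{(\phi_1, h_1)}, and report
#' \deqn{\hat{p}_{boot} = \#\{b : T^*_b \ge T_{obs}\} / B}
#' (weak inequality; no +1 correction, so \eqn{\hat p} may be 0).  The
#' bootstrap distribution consistently estimates the null law of T whether
#' or not the null holds, which is what makes the p-value trustworthy for
#' sparse tables where the chi-square approximation is poor.
#'
#' All B bootstrap samples are drawn from the root seed before any
#' refitting, so the p-value does not depend on the order in which
#' replicates are processed and is bit-reproducible given \code{seed}.
#' Non-convergent refits are excluded from the denominator with a warning;
#' more than 10 percent of failures aborts.
#'
#' @inheritParams gof_statistic
#' @param B Number of bootstrap replicates; \code{B = 0} skips the
#'   bootstrap.
#' @param seed Integer seed for the bootstrap resampling (required when
#'   \code{B > 0}).
#' @return An object of class \code{mphi_gof}.
#' @examples
#' gof_test(c(165, 13, 7, 0), "example3-hw", phi1 = -2, h1 = 0.5,
#'          B = 200, seed = 1)
#' @export
gof_test <- function(counts, model, phi1, h1, phi2 = phi1, h2 = h1,
                     B = 0L, seed = NULL, n_grid = 64L) {
  if (is.character(model)) model <- mphi_model(model)
  phi1 <- as_phi(phi1); phi2 <- as_phi(phi2)
  counts <- .validate_counts(counts, k = model$k)
  n <- sum(counts)

  obs <- gof_statistic(counts, model, phi1, h1, phi2, h2, n_grid = n_grid)
  res <- list(T_obs = obs$T, df = obs$df,
              p_asymptotic = asymptotic_pvalue(obs$T, model$k, model$s),
              p_bootstrap = NA_real_, B = as.integer(B),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              n_failed = 0L, theta_hat = obs$theta_hat, n = n,
              counts = counts, model = model$name,
              settings = list(lambda1 = phi1$lambda, h1 = h1,
                              lambda2 = phi2$lambda, h2 = h2))

  if (B > 0) {
    if (is.null(seed)) stop("'seed' must be supplied when B > 0")
    p_hat <- model$probs(obs$theta_hat)
    Xstar <- .with_seed(seed, stats::rmultinom(B, n, p_hat))
    Tstar <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      Tstar[b] <- tryCatch({
        fit <- .fit_theta(Xstar[, b], model, phi2, h2, n_grid = n_grid,
                          warm = obs$theta_hat)
        ps <- model$probs(fit$theta)
        d <- penalized_divergence(Xstar[, b] / n, ps, phi1, h1)
        2 * n / phi1$d2_at_1 * (d - phi1$value_at_1)
      }, error = function(e) NA_real_)
    }
    failed <- sum(is.na(Tstar))
    if (failed > 0.1 * B)
      stop("more than 10% of bootstrap replicates failed to refit")
    if (failed > 0)
      warning(failed, " bootstrap replicate(s) failed to refit and were ",
              "excluded from the denominator")
    ok <- !is.na(Tstar)
    res$p_bootstrap <- sum(Tstar[ok] >= obs$T) / sum(ok)
    res$n_failed <- failed
  }
  structure(res, class = "mphi_gof")
}

#' @export
print.mphi_gof <- function(x, ...) {
  st <- x$settings
  cat(sprintf("Penalized phi-divergence goodness-of-fit test: model '%s'\n",
              x$model))
  cat(sprintf("  statistic PD(%g), h1 = %g; estimator PD(%g), h2 = %g\n",
              st$lambda1, st$h1, st$lambda2, st$h2))
  cat(sprintf("  n = %d, theta_hat = %s\n", x$n,
              paste(sprintf("%.4f", x$theta_hat), collapse = ", ")))
  cat(sprintf("  T = %.4f on %d df, asymptotic p = %.4f\n",
              x$T_obs, x$df, x$p_asymptotic))
  if (!is.na(x$p_bootstrap))
    cat(sprintf("  bootstrap p = %.4f (B = %d, seed = %d)\n",
                x$p_bootstrap, x$B, x$seed))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
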