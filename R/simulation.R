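#' Draw seeded multinomial samples from a fitted or true model
#'
#' @param model A \code{multinomial_model} or built-in name.
#' @param theta Parameter in the model domain.
#' @param n Sample size per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return Integer matrix, k rows by \code{reps} columns.
#' @export
simulate_counts <- function(model, theta, n, reps, seed) {
  if (is.character(model)) model <- mphi_model(model)
  p <- model_probs(model, theta)
  .with_seed(seed, stats::rmultinom(reps, n, p))
}

#' Empirical type-I error of the goodness-of-fit test
#'
#' Draws \code{reps} multinomial samples of size n from the model at
#' \code{theta_true} (so the null hypothesis holds), computes the p-value
#' of each by the asymptotic chi-square approximation or the parametric
#' bootstrap, and reports the fraction of p-values at or below each
#' nominal level.  The weak inequality \eqn{p \le \alpha} is used.
#'
#' With the bootstrap method, replicate r uses the derived seed
#' \code{seed + r} for its resampling, so results are reproducible and
#' independent of processing order; the data themselves are drawn once
#' up front from \code{seed}.
#'
#' @param model A \code{multinomial_model} or built-in name.
#' @param theta_true Parameter of the data-generating member.
#' @param n Sample size.
#' @param reps Number of Monte Carlo replicates.
#' @param phi1,h1 Generator and penalty of the statistic.
#' @param phi2,h2 Generator and penalty of the estimator.
#' @param method \code{"asymptotic"} or \code{"bootstrap"}.
#' @param B Bootstrap replicates per dataset (bootstrap method only).
#' @param alphas Nominal levels.
#' @param seed Root seed.
#' @return Object of class \code{simulation_result}: a list with a
#'   \code{rates} data frame (alpha, rate, mc_stderr), \code{reps_completed}
#'   and the settings.
#' @export
type1_error_experiment <- function(model, theta_true, n, reps,
                                   phi1, h1, phi2 = phi1, h2 = h1,
                                   method = c("asymptotic", "bootstrap"),
                                   B = 1000L, alphas = c(0.05, 0.10),
                                   seed = 1L) {
  if (is.character(model)) model <- mphi_model(model)
  method <- match.arg(method)
  phi1 <- as_phi(phi1); phi2 <- as_phi(phi2)
  stopifnot(reps >= 1, all(alphas > 0), all(alphas <= 1))
  X <- simulate_counts(model, theta_true, n, reps, seed)

  pvals <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    pvals[r] <- tryCatch({
      if (method == "asymptotic") {
        st <- gof_statistic(X[, r], model, phi1, h1, phi2, h2)
        asymptotic_pvalue(st$T, model$k, model$s)
      } else {
        gof_test(X[, r], model, phi1, h1, phi2, h2,
                 B = B, seed = seed + r)$p_bootstrap
      }
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(pvals))
  if (failed > 0.01 * reps)
    stop("more than 1% of replicates failed (", failed, " of ", reps, ")")
  ok <- !is.na(pvals)
  rate <- vapply(alphas, function(a) mean(pvals[ok] <= a), numeric(1))
  structure(list(
    rates = data.frame(alpha = alphas, rate = rate,
                       mc_stderr = sqrt(rate * (1 - rate) / sum(ok))),
    reps_completed = sum(ok), n = n, method = method, B = B, seed = seed,
    model = model$name, theta_true = theta_true,
    settings = list(lambda1 = phi1$lambda, h1 = h1,
                    lambda2 = phi2$lambda, h2 = h2)
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Monte Carlo experiment: model '%s', theta = %s, n = %d, reps = %d\n",
              x$model, paste(signif(x$theta_true, 6), collapse = ", "),
              x$n, x$reps_completed))
  if (!is.null(x$rates)) {
    cat(sprintf("  method = %s%s\n", x$method,
                if (x$method == "bootstrap") sprintf(" (B = %d)", x$B) else ""))
    print(x$rates, row.names = FALSE)
  }
  if (!is.null(x$rmsd)) cat(sprintf("  RMSD = %.6g\n", x$rmsd))
  invisible(x)
}

#' Root-mean-square deviation of the estimator
#'
#' Draws \code{reps} samples of size n from the model at \code{theta_true},
#' fits each by minimum penalized phi-divergence, and reports
#' \deqn{RMSD = \sqrt{\frac{1}{reps}\sum_r (\hat\theta_r - \theta_{true})^2}.}
#'
#' @inheritParams type1_error_experiment
#' @param phi2,h2 Generator and penalty of the estimator.
#' @return Object of class \code{simulation_result} with component
#'   \code{rmsd}.
#' @export
rmsd_experiment <- function(model, theta_true, n, phi2, h2, reps,
                            seed = 1L) {
  if (is.character(model)) model <- mphi_model(model)
  phi2 <- as_phi(phi2)
  stopifnot(model$s == 1L || length(theta_true) == model$s)
  X <- simulate_counts(model, theta_true, n, reps, seed)
  dev2 <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    dev2[r] <- tryCatch({
      th <- .fit_theta(X[, r], model, phi2, h2)$theta
      sum((th - theta_true)^2)
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(dev2))
  if (failed > 0.01 * reps)
    stop("more than 1% of replicates failed (", failed, " of ", reps, ")")
  structure(list(
    rmsd = sqrt(mean(dev2, na.rm = TRUE)),
    reps_completed = sum(!is.na(dev2)), n = n, seed = seed,
    model = model$name, theta_true = theta_true,
    settings = list(lambda2 = phi2$lambda, h2 = h2)
  ), class = "simulation_result")
}

#' Run a grid of Monte Carlo experiments
#'
#' Executes a list of experiment specifications (typically read from a
#' YAML config with \code{\link{read_experiment_config}}) and returns a
#' tidy table with one row per (cell, alpha) combination.  List-valued
#' settings (\code{n}, \code{lambda1}, \code{h1}, ...) are expanded to
#' their full grid.  A cell that errors is recorded with \code{NA} rates
#' and flagged in the \code{failed} attribute; completed cells are always
#' returned.
#'
#' @param config A list of experiment specs.  Each spec is a list with
#'   fields \code{model}, \code{theta_true}, \code{n}, \code{reps},
#'   \code{lambda1}, \code{h1}, \code{lambda2}, \code{h2},
#'   \code{method}, optional \code{B}, \code{alphas}, \code{seed}.
#' @param out Optional path: the table is also written as TSV.
#' @return Data frame with columns model, n, lambda1, h1, lambda2, h2,
#'   alpha, method, rate, stderr, reps, seed.
#' @export
run_table <- function(config, out = NULL) {
  rows <- list()
  failed <- 0L
  for (spec in config) {
    grid <- expand.grid(n = unlist(spec$n),
                        lambda1 = unlist(spec$lambda1),
                        h1 = unlist(spec$h1),
                        lambda2 = unlist(spec$lambda2),
                        h2 = unlist(spec$h2),
                        KEEP.OUT.ATTRS = FALSE)
    if (isTRUE(spec$pair_h))
      grid <- grid[grid$h1 == grid$h2, , drop = FALSE]
    if (isTRUE(spec$distinct_h))
      grid <- grid[grid$h1 != grid$h2, , drop = FALSE]
    alphas <- if (is.null(spec$alphas)) c(0.05, 0.10) else unlist(spec$alphas)
    seed <- if (is.null(spec$seed)) 1L else spec$seed
    B <- if (is.null(spec$B)) 1000L else spec$B
    method <- if (is.null(spec$method)) "asymptotic" else spec$method
    for (g in seq_len(nrow(grid))) {
      res <- tryCatch(
        type1_error_experiment(spec$model, spec$theta_true, grid$n[g],
                               spec$reps, grid$lambda1[g], grid$h1[g],
                               grid$lambda2[g], grid$h2[g],
                               method = method, B = B, alphas = alphas,
                               seed = seed),
        error = function(e) NULL)
      if (is.null(res)) {
        failed <- failed + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          model = spec$model, n = grid$n[g], lambda1 = grid$lambda1[g],
          h1 = grid$h1[g], lambda2 = grid$lambda2[g], h2 = grid$h2[g],
          alpha = alphas, method = method, rate = NA_real_,
          stderr = NA_real_, reps = spec$reps, seed = seed)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          model = spec$model, n = grid$n[g], lambda1 = grid$lambda1[g],
          h1 = grid$h1[g], lambda2 = grid$lambda2[g], h2 = grid$h2[g],
          alpha = res$rates$alpha, method = method, rate = res$rates$rate,
          stderr = res$rates$mc_stderr, reps = res$reps_completed,
          seed = seed)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), n = integer(), lambda1 = numeric(),
               h1 = numeric(), lambda2 = numeric(), h2 = numeric(),
               alpha = numeric(), method = character(), rate = numeric(),
               stderr = numeric(), reps = integer(), seed = integer())
  attr(tab, "failed") <- failed
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

#' Read a YAML experiment configuration
#'
#' The file holds either one experiment spec or a list of them under the
#' key \code{experiments}; see the configs shipped under
#' \code{system.file("configs", package = "pendiv")} for the layouts of
#' the package's simulation studies.
#'
#' @param path Path to the YAML file.
#' @return A list of experiment specs suitable for \code{\link{run_table}}.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$experiments)) cfg$experiments else list(cfg)
}
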