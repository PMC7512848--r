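# ---- internal optimizer ----------------------------------------------------

# Objective builder: theta -> D_{phi,h}(pihat, P(theta)) without argument
# validation, for use inside optimization loops.  Empty cells of pihat are
# fixed once (counts are exact, so the zero pattern never changes with theta).
.make_objective <- function(pihat, model, phi, h) {
  pos <- pihat > 0
  q <- pihat[pos]
  pfun <- model$probs
  cellf <- .cell_term_fun(phi)
  if (all(pos)) {
    function(theta) sum(cellf(q, pfun(theta)))
  } else {
    zero <- !pos
    function(theta) {
      p <- pfun(theta)
      sum(cellf(q, p[pos])) + h * sum(p[zero])
    }
  }
}

# Minimize fn over the clamped open box of `model`.  For s = 1: a uniform
# grid locates every local basin, then Brent refinement runs in each
# bracketing interval; for s > 1: L-BFGS-B multistart from a 4^s lattice.
# Returns the global minimizer plus diagnostics on basin agreement.
.minimize_model <- function(fn, model, n_grid = 64L, tol = 1e-10,
                            warm = NULL) {
  lower <- model$lower; upper <- model$upper
  eps <- 1e-10 * (upper - lower)
  lo <- lower + eps; hi <- upper - eps
  s <- length(lower)

  if (s == 1L) {
    th <- seq(lo, hi, length.out = n_grid)
    if (!is.null(warm) && warm > lo && warm < hi) th <- sort(c(th, warm))
    fv <- vapply(th, fn, numeric(1))
    n <- length(th)
    is_min <- fv <= c(Inf, fv[-n]) & fv <= c(fv[-1], Inf)
    idx <- which(is_min & is.finite(fv))
    if (!length(idx)) stop("objective not finite anywhere on the search grid")
    cand_th <- numeric(0); cand_f <- numeric(0)
    for (i in idx) {
      a <- th[max(1L, i - 1L)]; b <- th[min(n, i + 1L)]
      if (b - a < tol) { o <- list(minimum = th[i], objective = fv[i]) }
      else o <- stats::optimize(fn, c(a, b), tol = max(tol, 1e-12))
      cand_th <- c(cand_th, o$minimum); cand_f <- c(cand_f, o$objective)
    }
  } else {
    starts <- as.matrix(expand.grid(lapply(seq_len(s), function(j)
      lo[j] + (upper[j] - lower[j]) * c(.125, .375, .625, .875))))
    if (!is.null(warm)) starts <- rbind(starts, warm)
    cand_th <- NULL; cand_f <- numeric(0)
    for (r in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(starts[r, ], fn, method = "L-BFGS-B",
                                 lower = lo, upper = hi,
                                 control = list(factr = 1e3)),
                    error = function(e) NULL)
      if (is.null(o)) next
      cand_th <- rbind(cand_th, o$par); cand_f <- c(cand_f, o$value)
    }
    if (!length(cand_f)) stop("all optimizer restarts failed to converge")
    cand_th <- lapply(seq_len(nrow(cand_th)), function(r) cand_th[r, ])
  }

  best <- which.min(cand_f)
  theta <- if (s == 1L) cand_th[best] else cand_th[[best]]
  dist <- if (s == 1L) abs(cand_th - theta)
          else vapply(cand_th, function(t) max(abs(t - theta)), numeric(1))
  near_val <- cand_f <= cand_f[best] + 1e-8
  agreeing <- sum(dist < 1e-6 & near_val)
  if (any(near_val & dist > 1e-6))
    warning("multiple minima of the penalized divergence agree in value but ",
            "differ in theta: the projection parameter may not be unique",
            call. = FALSE)
  at_boundary <- any(theta - lo < 2 * eps) || any(hi - theta < 2 * eps)
  list(theta = theta, value = cand_f[best], n_restarts_agreeing = agreeing,
       boundary = at_boundary)
}

# Fast path used by simulation loops: fit theta only, no diagnostics object.
.fit_theta <- function(counts, model, phi, h, n_grid = 64L, warm = NULL) {
  pihat <- counts / sum(counts)
  fn <- .make_objective(pihat, model, phi, h)
  .minimize_model(fn, model, n_grid = n_grid, warm = warm)
}

# Norm of the stationarity condition sum_i dp_i/dtheta * v_i at theta
# (the first-order condition of the penalized divergence in the positive
# cells), used as a post-fit diagnostic.  Only meaningful off the boundary.
.gradient_condition <- function(pi, model, theta, phi, h) {
  pos <- pi > 0
  m <- sum(pos); k <- length(pi)
  p <- model$probs(theta)
  x <- pi[pos] / p[pos]
  v <- phi$value(x) - x * phi$d1(x) - h * (m < k)
  J <- model$jacobian(theta)
  g <- J[, pos, drop = FALSE] %*% v
  sqrt(sum(g^2))
}

# ---- public estimation API -------------------------------------------------

#' Minimum penalized phi-divergence estimation
#'
#' Fits a parametric multinomial model to observed counts by minimizing the
#' penalized divergence \eqn{\theta \mapsto D_{\phi,h}(\hat\pi, P(\theta))}
#' over the model domain, where \eqn{\hat\pi_i = X_i / n} are the relative
#' frequencies.  The family includes the maximum likelihood estimator
#' (\code{phi = 0}, \code{h = 1}) and the minimum modified chi-square
#' estimator (\code{phi = -2}) as members; the penalty \eqn{h} only matters
#' when the table has empty cells.
#'
#' The optimizer is deterministic: for a scalar parameter, Brent refinement
#' in every local basin found on a uniform grid (\code{n_grid} points); for
#' \eqn{s > 1}, box-constrained quasi-Newton from a \eqn{4^s} lattice of
#' starts.  Multistart agreement is reported so a failure of the uniqueness
#' assumption on the projection parameter is surfaced rather than hidden.
#'
#' The plug-in asymptotic covariance of \eqn{\hat\theta} substitutes
#' \eqn{\hat\pi} and \eqn{\hat\theta} into the misspecification-robust
#' limit covariance \eqn{G \Sigma_{\pi^+} G^t} (see
#' \code{\link{asymptotic_covariance}}) and divides by n.  It is reported
#' as \code{NA} when the fit sits on the domain boundary, where the
#' interior expansion behind the formula does not hold.
#'
#' @param counts Vector of k nonnegative integer cell counts, n = sum > 0.
#' @param model A \code{multinomial_model} or a built-in model name.
#' @param phi Divergence generator for the fit (a \code{phi_spec} or a
#'   power-divergence index \eqn{\lambda}).  Default: modified chi-square,
#'   \eqn{\lambda = -2}.
#' @param h Penalty on empty-cell model mass; must be finite and positive.
#' @param n_grid Grid resolution of the multistart (scalar parameter).
#' @return An object of class \code{mphi_fit} with components
#'   \code{theta_hat}, \code{min_divergence}, \code{converged},
#'   \code{n_restarts_agreeing}, \code{cov_theta}, \code{se},
#'   \code{gradient_norm}, \code{boundary}, and the settings used.
#' @examples
#' fit_mphi(c(165, 13, 7, 0), "example3-hw", phi = -2, h = 0.5)
#' @export
fit_mphi <- function(counts, model, phi = power_divergence(-2), h = 0.5,
                     n_grid = 64L) {
  if (is.character(model)) model <- mphi_model(model)
  phi <- as_phi(phi)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a single finite positive number")
  counts <- .validate_counts(counts, k = model$k)
  n <- sum(counts)
  pihat <- counts / n

  fit <- .fit_theta(counts, model, phi, h, n_grid = n_grid)
  grad <- if (fit$boundary) NA_real_
          else .gradient_condition(pihat, model, fit$theta, phi, h)

  cov_theta <- matrix(NA_real_, model$s, model$s)
  if (!fit$boundary)
    cov_theta <- tryCatch(
      asymptotic_covariance(pihat, model, fit$theta, phi, h) / n,
      error = function(e) matrix(NA_real_, model$s, model$s))

  structure(list(
    theta_hat = fit$theta,
    min_divergence = fit$value,
    converged = TRUE,
    n_restarts_agreeing = fit$n_restarts_agreeing,
    boundary = fit$boundary,
    gradient_norm = grad,
    cov_theta = cov_theta,
    se = sqrt(diag(as.matrix(cov_theta))),
    counts = counts, n = n,
    model = model$name, lambda = phi$lambda, h = h
  ), class = "mphi_fit")
}

#' @export
print.mphi_fit <- function(x, ...) {
  lam <- if (is.na(x$lambda)) "generic phi" else sprintf("PD(%g)", x$lambda)
  cat(sprintf("Minimum penalized phi-divergence fit: model '%s', %s, h = %g\n",
              x$model, lam, x$h))
  cat(sprintf("  n = %d, counts = (%s)\n", x$n,
              paste(x$counts, collapse = ", ")))
  cat(sprintf("  theta_hat = %s   (se = %s)\n",
              paste(sprintf("%.6f", x$theta_hat), collapse = ", "),
              paste(sprintf("%.6f", x$se), collapse = ", ")))
  cat(sprintf("  attained penalized divergence = %.6g\n", x$min_divergence))
  if (x$boundary)
    cat("  note: estimate lies on the (clamped) domain boundary\n")
  invisible(x)
}

#' Projection parameter of a probability vector on the model
#'
#' Computes \eqn{\theta_0 = \arg\min_\theta D_{\phi,h}(\pi, P(\theta))} for
#' a fixed (population) probability vector \eqn{\pi}, which may or may not
#' belong to the family.  This is the well-defined limit of the minimum
#' penalized divergence estimator under misspecification; uniqueness is an
#' assumption, and disagreeing multistart minima raise a warning.
#'
#' @param pi Probability vector in the closed simplex (zeros allowed).
#' @param model A \code{multinomial_model} or built-in name.
#' @inheritParams fit_mphi
#' @return Numeric vector \eqn{\theta_0} with attributes
#'   \code{min_divergence}, \code{gradient_norm} and \code{boundary}.
#' @export
projection_parameter <- function(pi, model, phi, h, n_grid = 64L) {
  if (is.character(model)) model <- mphi_model(model)
  phi <- as_phi(phi)
  if (!is.numeric(pi) || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("'pi' must be a probability vector")
  if (length(pi) != model$k) stop("'pi' must have length ", model$k)
  fn <- .make_objective(pi, model, phi, h)
  fit <- .minimize_model(fn, model, n_grid = n_grid)
  theta0 <- fit$theta
  attr(theta0, "min_divergence") <- fit$value
  attr(theta0, "gradient_norm") <- if (fit$boundary) NA_real_
    else .gradient_condition(pi, model, theta0, phi, h)
  attr(theta0, "boundary") <- fit$boundary
  theta0
}

# ---- asymptotic covariance machinery ---------------------------------------

# All limit-law ingredients at (pi, theta0): v, w, varpi over the m positive
# cells, D1 (s x m), D2 (s x s), G (s x m).  Cells are handled in original
# order; sums simply run over the positive cells.
.asymp_machinery <- function(pi, model, theta0, phi, h) {
  pos <- which(pi > 0)
  m <- length(pos); k <- length(pi)
  p <- model$probs(theta0)
  J <- model$jacobian(theta0)
  H <- model$cell_hessian(theta0)
  s <- model$s
  x <- pi[pos] / p[pos]

  v <- phi$value(x) - x * phi$d1(x) - h * (m < k)
  d2x <- phi$d2(x)
  w <- pi[pos]^2 / p[pos]^3 * d2x
  varpi <- pi[pos] / p[pos]^2 * d2x

  D1 <- J[, pos, drop = FALSE]
  D2 <- D1 %*% (t(D1) * w)
  for (j in seq_len(m))
    D2 <- D2 + H[, , pos[j], drop = TRUE] * v[j]
  D2 <- matrix(D2, s, s)

  ev <- eigen(D2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("the second-derivative matrix D2 of the penalized divergence is not ",
         "positive definite at theta0: the interior-minimum assumption fails")

  G <- solve(D2, D1 * rep(varpi, each = s))
  G <- matrix(G, s, m)
  list(pos = pos, m = m, k = k, p = p, x = x, v = v, w = w, varpi = varpi,
       D1 = D1, D2 = D2, G = G, pi_pos = pi[pos])
}

#' Misspecification-robust asymptotic covariance of the estimator
#'
#' Returns the s x s matrix \eqn{G \Sigma_{\pi^+} G^t}, the covariance of
#' the limiting normal law of \eqn{\sqrt{n}(\hat\theta_{\phi,h} -
#' \theta_0)}.  Here \eqn{\pi^+} collects the m positive cells of
#' \eqn{\pi}, \eqn{\Sigma_x = Diag(x) - x x^t}, and \eqn{G =
#' D_2^{-1} D_1 Diag(\varpi)} is the Jacobian of the implicit map from cell
#' frequencies to the minimizer, built from
#' \itemize{
#'   \item \eqn{v_i = \phi(\pi_i/p_i) - (\pi_i/p_i)\phi'(\pi_i/p_i) - h\,I(m<k)},
#'   \item \eqn{w_i = \pi_i^2 / p_i^3\, \phi''(\pi_i/p_i)},
#'   \item \eqn{D_2 = \sum_i \partial^2 p_i\, v_i + \sum_i \partial p_i\,
#'     \partial p_i^t\, w_i} (positive definite at an interior minimum),
#'   \item \eqn{\varpi_i = \pi_i / p_i^2\, \phi''(\pi_i/p_i)},
#' }
#' all sums running over the positive cells only.  The formula is valid
#' whether or not \eqn{\pi} belongs to the model; when it does and
#' \eqn{\phi} generates the MLE, it reduces to the inverse Fisher
#' information.
#'
#' @param pi Probability vector (population or plug-in \eqn{\hat\pi}).
#' @param model A \code{multinomial_model} or built-in name.
#' @param theta0 The projection parameter (or plug-in \eqn{\hat\theta}).
#' @inheritParams fit_mphi
#' @return Symmetric positive semidefinite s x s matrix.
#' @examples
#' m <- mphi_model("example3-hw")
#' asymptotic_covariance(model_probs(m, 0.5), m, 0.5, phi = 0, h = 1)  # 0.125
#' @export
asymptotic_covariance <- function(pi, model, theta0, phi, h) {
  if (is.character(model)) model <- mphi_model(model)
  phi <- as_phi(phi)
  mach <- .asymp_machinery(pi, model, theta0, phi, h)
  Sigma <- diag(mach$pi_pos, mach$m) - tcrossprod(mach$pi_pos)
  V <- mach$G %*% Sigma %*% t(mach$G)
  (V + t(V)) / 2
}

#' Misspecification summary: projection, limit divergence and rho-squared
#'
#' For a population vector \eqn{\pi} not necessarily in the model, computes
#' the projection parameter \eqn{\theta_0} under the estimation divergence
#' \eqn{(\phi_2, h_2)}, the limiting divergence value
#' \eqn{D_{\phi_1,h_1}(\pi, P(\theta_0))}, and the variance \eqn{\varrho^2}
#' of the limiting normal law of
#' \eqn{\sqrt{n}\{D_{\phi_1,h_1}(\hat\pi, P(\hat\theta_{\phi_2,h_2})) -
#' D_{\phi_1,h_1}(\pi, P(\theta_0))\}}.
#'
#' \eqn{\varrho^2} is computed by the delta method applied to the explicit
#' composite map \eqn{\hat\pi^+ \mapsto D_{\phi_1,h_1}(\hat\pi,
#' P(g(\hat\pi^+)))}, where g is the implicit minimizer map with Jacobian
#' G.  Its gradient at \eqn{\pi^+} has i-th coordinate
#' \deqn{a_i = \phi_1'(\pi_i/p_i(\theta_0)) + c^t G e_i, \qquad
#'   c = \sum_{j \le m} \partial p_j(\theta_0)\, v_j^{(\phi_1,h_1)},}
#' and \eqn{\varrho^2 = a^t \Sigma_{\pi^+} a}.  When \eqn{\phi_1 = \phi_2}
#' and \eqn{h_1 = h_2}, the stationarity condition makes \eqn{c = 0}
#' and the gradient reduces to the \eqn{\phi_1'} terms alone.
#'
#' @param pi Population probability vector (zeros allowed).
#' @param model A \code{multinomial_model} or built-in name.
#' @param phi1,h1 Divergence and penalty of the test statistic.
#' @param phi2,h2 Divergence and penalty of the estimator.
#' @return A list with \code{theta0}, \code{limit_divergence}, \code{rho2},
#'   the gradient \code{a}, and the machinery \code{G}, \code{D1},
#'   \code{D2}, \code{v}, \code{w}, \code{varpi} evaluated at
#'   \eqn{(\phi_2, h_2)}.
#' @export
misspec_summary <- function(pi, model, phi1, h1, phi2 = phi1, h2 = h1) {
  if (is.character(model)) model <- mphi_model(model)
  phi1 <- as_phi(phi1); phi2 <- as_phi(phi2)
  theta0 <- projection_parameter(pi, model, phi2, h2)
  th0 <- as.numeric(theta0)

  mach <- .asymp_machinery(pi, model, th0, phi2, h2)
  p0 <- mach$p
  limit_div <- penalized_divergence(pi, p0, phi1, h1)

  x <- mach$x
  v1 <- phi1$value(x) - x * phi1$d1(x) - h1 * (mach$m < mach$k)
  cvec <- mach$D1 %*% v1                       # s-vector
  a <- phi1$d1(x) + as.numeric(crossprod(mach$G, cvec))
  Sigma <- diag(mach$pi_pos, mach$m) - tcrossprod(mach$pi_pos)
  rho2 <- as.numeric(crossprod(a, Sigma %*% a))

  list(theta0 = th0, limit_divergence = limit_div, rho2 = rho2, a = a,
       G = mach$G, D1 = mach$D1, D2 = mach$D2,
       v = mach$v, w = mach$w, varpi = mach$varpi,
       m = mach$m, k = mach$k,
       boundary = isTRUE(attr(theta0, "boundary")))
}
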