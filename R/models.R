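#' Parametric multinomial model
#'
#' Represents a family \eqn{P(\theta) = (p_1(\theta), \ldots, p_k(\theta))}
#' of strictly positive cell-probability vectors over an open box domain
#' \eqn{\Theta \subset R^s}, together with its Jacobian and per-cell Hessians.
#' When derivatives are not supplied they are filled in by central finite
#' differences (see \code{\link{numeric_derivatives}}); first and second
#' derivatives are needed by the asymptotic covariance machinery.
#'
#' The identifiability condition \eqn{k - s - 1 > 0} is enforced: with
#' \eqn{s = k - 1} parameters the family saturates the simplex and the
#' goodness-of-fit problem is void.
#'
#' @param probs Function \eqn{\theta \mapsto} numeric vector of k positive
#'   probabilities summing to 1.
#' @param lower,upper Numeric vectors of length s: the open box domain.
#' @param jacobian Optional function returning the s x k matrix whose column
#'   i is \eqn{\partial p_i / \partial\theta}.
#' @param cell_hessian Optional function returning an s x s x k array of
#'   second derivatives \eqn{\partial^2 p_i / \partial\theta\partial\theta^t}.
#' @param name Model label used in reports.
#' @return An object of class \code{multinomial_model}.
#' @examples
#' m <- mphi_model("example3-hw")
#' model_probs(m, 0.8)
#' @export
multinomial_model <- function(probs, lower, upper, jacobian = NULL,
                              cell_hessian = NULL, name = "custom") {
  stopifnot(is.function(probs), is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper), all(lower < upper))
  s <- length(lower)
  mid <- (lower + upper) / 2
  p <- probs(mid)
  k <- length(p)
  if (k - s - 1 <= 0)
    stop("model must satisfy k - s - 1 > 0 (k = ", k, ", s = ", s, ")")
  if (abs(sum(p) - 1) > 1e-8 || any(p <= 0))
    stop("probs(theta) must be strictly positive and sum to 1 on the domain interior")
  m <- structure(list(probs = probs, lower = lower, upper = upper,
                      jacobian = jacobian, cell_hessian = cell_hessian,
                      s = s, k = k, name = name),
                 class = "multinomial_model")
  if (is.null(jacobian) || is.null(cell_hessian)) m <- numeric_derivatives(m)
  m
}

#' @export
print.multinomial_model <- function(x, ...) {
  cat(sprintf("Parametric multinomial model '%s': k = %d cells, s = %d parameter(s)\n",
              x$name, x$k, x$s))
  cat("  domain: (", paste(signif(x$lower, 6), collapse = ", "), ") .. (",
      paste(signif(x$upper, 6), collapse = ", "), ") open box\n", sep = "")
  invisible(x)
}

.check_theta <- function(model, theta) {
  if (length(theta) != model$s)
    stop("theta must have length ", model$s)
  if (any(theta <= model$lower) || any(theta >= model$upper))
    stop("theta = (", paste(signif(theta, 8), collapse = ", "),
         ") outside the open domain of model '", model$name, "'")
  invisible(NULL)
}

#' Evaluate model cell probabilities
#'
#' @param model A \code{multinomial_model}.
#' @param theta Parameter vector in the open domain.
#' @return Numeric vector of k positive probabilities.
#' @export
model_probs <- function(model, theta) {
  .check_theta(model, theta)
  model$probs(theta)
}

#' Evaluate the model Jacobian
#'
#' @inheritParams model_probs
#' @return s x k matrix; column i is \eqn{\partial p_i/\partial\theta}.
#'   Columns sum to zero (derivative of the sum-to-one constraint).
#' @export
model_jacobian <- function(model, theta) {
  .check_theta(model, theta)
  model$jacobian(theta)
}

#' Evaluate per-cell Hessians
#'
#' @inheritParams model_probs
#' @return s x s x k array of second derivatives of each cell probability.
#' @export
model_cell_hessian <- function(model, theta) {
  .check_theta(model, theta)
  model$cell_hessian(theta)
}

#' Fill in model derivatives by finite differences
#'
#' Replaces a missing Jacobian (or per-cell Hessian) with central
#' differences of step \eqn{\max(10^{-6}, |\theta_j| 10^{-6})} per
#' coordinate.  Within one step of the domain boundary a one-sided
#' difference is used and a warning is raised, since the model is only
#' defined on the open box.
#'
#' @param model A \code{multinomial_model} whose \code{probs} is twice
#'   continuously differentiable on the domain interior.
#' @return The model with \code{jacobian} and \code{cell_hessian} filled.
#' @export
numeric_derivatives <- function(model) {
  probs <- model$probs
  lower <- model$lower; upper <- model$upper
  s <- length(lower)

  shifted <- function(theta, j, d) { th <- theta; th[j] <- th[j] + d; th }
  # evaluation points for coordinate j: step and a boundary-aware shift
  eval_pair <- function(theta, j, step) {
    lo <- theta[j] - step > lower[j]
    hi <- theta[j] + step < upper[j]
    if (lo && hi) return(list(mode = "central"))
    warning("theta within one finite-difference step of the domain boundary; ",
            "using one-sided differences", call. = FALSE)
    list(mode = if (hi) "forward" else "backward")
  }

  jac <- function(theta) {
    out <- matrix(0, s, length(probs(theta)))
    for (j in seq_len(s)) {
      step <- max(1e-6, abs(theta[j]) * 1e-6)
      mode <- eval_pair(theta, j, step)$mode
      out[j, ] <- switch(mode,
        central  = (probs(shifted(theta, j, step)) -
                    probs(shifted(theta, j, -step))) / (2 * step),
        forward  = (probs(shifted(theta, j, step)) - probs(theta)) / step,
        backward = (probs(theta) - probs(shifted(theta, j, -step))) / step)
    }
    out
  }

  hess <- function(theta) {
    k <- length(probs(theta))
    out <- array(0, c(s, s, k))
    f0 <- probs(theta)
    step <- pmax(1e-6, abs(theta) * 1e-6)
    for (j in seq_len(s)) {
      fp <- probs(shifted(theta, j, step[j]))
      fm <- probs(shifted(theta, j, -step[j]))
      out[j, j, ] <- (fp - 2 * f0 + fm) / step[j]^2
      if (j > 1) for (l in seq_len(j - 1)) {
        fpp <- probs(shifted(shifted(theta, j, step[j]), l, step[l]))
        fpm <- probs(shifted(shifted(theta, j, step[j]), l, -step[l]))
        fmp <- probs(shifted(shifted(theta, j, -step[j]), l, step[l]))
        fmm <- probs(shifted(shifted(theta, j, -step[j]), l, -step[l]))
        cross <- (fpp - fpm - fmp + fmm) / (4 * step[j] * step[l])
        out[j, l, ] <- cross
        out[l, j, ] <- cross
      }
    }
    out
  }

  if (is.null(model$jacobian)) model$jacobian <- jac
  if (is.null(model$cell_hessian)) model$cell_hessian <- hess
  model
}

# ---- built-in models -------------------------------------------------------

.builtin_models <- local({
  zero_hessian <- function(k) function(theta) array(0, c(1, 1, k))

  example1 <- function() multinomial_model(
    probs = function(th) c(1 / 3 - th, 2 / 3 - th, 2 * th),
    lower = 0, upper = 1 / 3,
    jacobian = function(th) matrix(c(-1, -1, 2), 1, 3),
    cell_hessian = zero_hessian(3),
    name = "example1")

  example2 <- function() multinomial_model(
    probs = function(th) c(0.5 - 2 * th, 0.5 + th, th),
    lower = 0, upper = 0.25,
    jacobian = function(th) matrix(c(-2, 1, 1), 1, 3),
    cell_hessian = zero_hessian(3),
    name = "example2")

  # Hardy-Weinberg-type quadratic family on 4 cells
  example3 <- function() multinomial_model(
    probs = function(th) c(th^2, th * (1 - th), th * (1 - th), (1 - th)^2),
    lower = 0, upper = 1,
    jacobian = function(th) matrix(c(2 * th, 1 - 2 * th, 1 - 2 * th,
                                     -2 * (1 - th)), 1, 4),
    cell_hessian = function(th) array(c(2, -2, -2, 2), c(1, 1, 4)),
    name = "example3-hw")

  list("example1" = example1, "example2" = example2, "example3-hw" = example3)
})

#' Built-in model registry
#'
#' Three scalar-parameter families used throughout the package's worked
#' examples and simulations:
#' \describe{
#'   \item{\code{example1}}{\eqn{(1/3-\theta,\ 2/3-\theta,\ 2\theta)},
#'     \eqn{0<\theta<1/3}.  Near the upper boundary the first cell
#'     probability is tiny, producing empty cells even at large n.}
#'   \item{\code{example2}}{\eqn{(0.5-2\theta,\ 0.5+\theta,\ \theta)},
#'     \eqn{0<\theta<1/4}.}
#'   \item{\code{example3-hw}}{the Hardy--Weinberg-type family
#'     \eqn{(\theta^2,\ \theta(1-\theta),\ \theta(1-\theta),\ (1-\theta)^2)},
#'     \eqn{0<\theta<1}, used for the land-cover classification data.}
#' }
#'
#' @param name One of \code{"example1"}, \code{"example2"},
#'   \code{"example3-hw"}.
#' @return A \code{multinomial_model}.
#' @export
mphi_model <- function(name) {
  f <- .builtin_models[[name]]
  if (is.null(f))
    stop("unknown model '", name, "'; available: ",
         paste(names(.builtin_models), collapse = ", "))
  f()
}

#' @rdname mphi_model
#' @export
list_models <- function() names(.builtin_models)

#' Define a model from a YAML configuration file
#'
#' The file maps a model name to cell-probability expressions in the
#' parameter vector \code{theta}:
#' \preformatted{
#' name: linkage
#' lower: [0]
#' upper: [1]
#' probs:
#'   - (2 + theta[1]) / 4
#'   - (1 - theta[1]) / 4
#'   - (1 - theta[1]) / 4
#'   - theta[1] / 4
#' }
#' Derivatives are filled numerically.
#'
#' @param path Path to the YAML file.
#' @return A \code{multinomial_model}.
#' @export
model_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("name", "lower", "upper", "probs"))
    if (is.null(cfg[[f]])) stop("model config missing field '", f, "'")
  exprs <- lapply(cfg$probs, function(e) parse(text = e)[[1]])
  probs <- function(theta) {
    env <- list2env(list(theta = theta), parent = baseenv())
    vapply(exprs, eval, numeric(1), envir = env)
  }
  multinomial_model(probs, as.numeric(cfg$lower), as.numeric(cfg$upper),
                    name = cfg$name)
}
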