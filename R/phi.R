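#' Power-divergence generator
#'
#' Evaluates the Cressie--Read power-divergence generator
#' \deqn{PD_\lambda(x) = \frac{x^{\lambda+1} - x - \lambda(x-1)}{\lambda(\lambda+1)},}
#' with the continuity limits \eqn{PD_0(x) = x\log x - x + 1} (likelihood
#' ratio) and \eqn{PD_{-1}(x) = -\log x + x - 1} (reverse likelihood ratio).
#' Every member satisfies \eqn{PD_\lambda(1) = 0}, \eqn{PD_\lambda''(1) = 1}
#' and \eqn{PD_\lambda(x) \ge 0} with equality only at \eqn{x = 1}.
#'
#' @param lambda Real index of the family. \code{lambda = 1} generates the
#'   Pearson chi-square, \code{lambda = 0} the likelihood-ratio and
#'   \code{lambda = -2} the modified (Neyman) chi-square divergence.
#' @param x Positive numeric vector of evaluation points.
#' @return Numeric vector of the same length as \code{x}.
#' @examples
#' pd_lambda(1, 3)    # (x - 1)^2 / 2 = 2
#' pd_lambda(-2, 2)   # (x - 1)^2 / (2 x) = 0.25
#' @export
pd_lambda <- function(lambda, x) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda))
    stop("'lambda' must be a single finite number")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be positive and finite")
  if (lambda == 0) {
    x * log(x) - x + 1
  } else if (lambda == -1) {
    -log(x) + x - 1
  } else {
    (x^(lambda + 1) - x - lambda * (x - 1)) / (lambda * (lambda + 1))
  }
}

#' Construct a power-divergence generator object
#'
#' Packages \code{\link{pd_lambda}} together with its first two derivatives
#' and the limit \eqn{\phi(0)} into a \code{phi_spec} object understood by
#' all estimation and testing functions.
#'
#' \eqn{\phi(0)} is the continuity limit of the generator at 0: it equals
#' \eqn{1/(\lambda+1)} for \eqn{\lambda > -1} and \eqn{+\infty} for
#' \eqn{\lambda \le -1}.  A finite \eqn{\phi(0)} means the unpenalized
#' divergence is finite even when the first argument has empty cells;
#' an infinite one is the situation the penalty \eqn{h} exists for.
#'
#' @param lambda Real index of the power-divergence family.
#' @return An object of class \code{phi_spec}.
#' @seealso \code{\link{phi_spec}} for user-supplied generators.
#' @export
power_divergence <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda))
    stop("'lambda' must be a single finite number")
  force(lambda)
  structure(list(
    kind = "power-divergence",
    lambda = lambda,
    value = function(x) pd_lambda(lambda, x),
    d1 = if (lambda == 0) function(x) log(x)
         else function(x) (x^lambda - 1) / lambda,
    d2 = function(x) x^(lambda - 1),
    value_at_1 = 0,
    d2_at_1 = 1,
    value_at_0 = if (lambda > -1) 1 / (lambda + 1) else Inf
  ), class = "phi_spec")
}

#' User-supplied divergence generator
#'
#' Wraps an arbitrary strictly convex generator \eqn{\phi} given as three
#' callables (value, first and second derivative on \eqn{(0,\infty)}).
#' Strict convexity cannot be proven mechanically, so it is spot-checked on
#' a log-spaced grid; a violation raises a warning, not an error.
#'
#' @param value,d1,d2 Vectorized functions of a positive numeric argument.
#' @param value_at_0 The limit \eqn{\phi(0)}; may be \code{Inf}.
#' @param value_at_1 \eqn{\phi(1)}; defaults to \code{value(1)}.
#' @param d2_at_1 \eqn{\phi''(1)}; defaults to \code{d2(1)}, used to scale
#'   the goodness-of-fit statistic.
#' @return An object of class \code{phi_spec}.
#' @export
phi_spec <- function(value, d1, d2, value_at_0,
                     value_at_1 = value(1), d2_at_1 = d2(1)) {
  stopifnot(is.function(value), is.function(d1), is.function(d2))
  if (!is.numeric(value_at_0) || length(value_at_0) != 1L || is.na(value_at_0))
    stop("'value_at_0' must be a single number (possibly Inf)")
  grid <- 10^seq(-3, 3, length.out = 25)
  if (any(d2(grid) <= 0))
    warning("second derivative not strictly positive on probe grid; ",
            "the generator may not be strictly convex")
  step <- 1e-6
  fd <- (value(grid + step) - value(grid - step)) / (2 * step)
  if (max(abs(fd - d1(grid)) / pmax(1, abs(d1(grid)))) > 1e-4)
    warning("'d1' disagrees with a finite difference of 'value' on the probe grid")
  structure(list(kind = "generic", lambda = NA_real_,
                 value = value, d1 = d1, d2 = d2,
                 value_at_1 = value_at_1, d2_at_1 = d2_at_1,
                 value_at_0 = value_at_0),
            class = "phi_spec")
}

#' @export
print.phi_spec <- function(x, ...) {
  if (x$kind == "power-divergence")
    cat(sprintf("Power-divergence generator PD(lambda = %g)\n", x$lambda))
  else
    cat("Generic divergence generator\n")
  cat(sprintf("  phi(1) = %g, phi''(1) = %g, phi(0) = %g\n",
              x$value_at_1, x$d2_at_1, x$value_at_0))
  invisible(x)
}

# Coerce a lambda value or phi_spec to a phi_spec.
as_phi <- function(phi) {
  if (inherits(phi, "phi_spec")) return(phi)
  if (is.numeric(phi) && length(phi) == 1L) return(power_divergence(phi))
  stop("'phi' must be a phi_spec or a single power-divergence index lambda")
}
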