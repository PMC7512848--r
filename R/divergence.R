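# Per-cell contributions p * phi(q/p) for q > 0.  The five power-divergence
# indices used throughout the goodness-of-fit literature get algebraically
# rearranged forms in (q - p) or log(q/p): these avoid cancellation when
# q is close to p and overflow when p is close to 0 (lambda <= -1 forms
# carry no p in the denominator, which matters near a degenerate model cell).
.cell_term_fun <- function(phi) {
  if (phi$kind == "power-divergence") {
    lam <- phi$lambda
    if (lam == 1) return(function(q, p) (q - p)^2 / (2 * p))
    if (lam == -2) return(function(q, p) (q - p)^2 / (2 * q))
    if (lam == 0) return(function(q, p) q * log(q / p) - q + p)
    if (lam == -1) return(function(q, p) p * log(p / q) - p + q)
    if (lam == 2) return(function(q, p) (q - p)^2 * (q + 2 * p) / (6 * p^2))
    return(function(q, p) p * pd_lambda(lam, q / p))
  }
  value <- phi$value
  function(q, p) p * value(q / p)
}

.check_prob_pair <- function(q, p) {
  if (length(q) != length(p))
    stop("'q' and 'p' must have the same length")
  if (!is.numeric(q) || any(q < 0))
    stop("'q' must be a nonnegative probability vector")
  if (!is.numeric(p) || any(p <= 0))
    stop("'p' must be strictly positive in every cell")
  if (abs(sum(q) - 1) > 1e-8 || abs(sum(p) - 1) > 1e-8)
    stop("'q' and 'p' must each sum to 1")
  invisible(NULL)
}

#' Phi-divergence between two probability vectors
#'
#' Computes \eqn{D_\phi(Q, P) = \sum_i p_i \phi(q_i / p_i)} for a possibly
#' sparse \eqn{Q} (zeros allowed) and a strictly positive \eqn{P}.  Cells
#' with \eqn{q_i = 0} contribute \eqn{\phi(0)\, p_i}; when \eqn{\phi(0) =
#' +\infty} and \eqn{Q} has an empty cell the divergence is \code{Inf},
#' which is exactly the situation \code{\link{penalized_divergence}}
#' resolves.
#'
#' Zero cells are detected by exact equality: relative frequencies
#' \eqn{X_i/n} are exactly zero iff the count is zero, so no floating
#' tolerance is involved.
#'
#' @param q Nonnegative probability vector (the empirical side).
#' @param p Strictly positive probability vector of the same length.
#' @param phi A \code{phi_spec}, or a single number taken as the
#'   power-divergence index \eqn{\lambda}.
#' @return A single number, possibly \code{Inf}.
#' @examples
#' phi_divergence(c(.5, .5), c(.25, .75), 1)       # Pearson-type, 1/6
#' phi_divergence(c(.5, .5, 0), c(.25, .25, .5), -2)  # Inf: empty cell
#' @export
phi_divergence <- function(q, p, phi) {
  phi <- as_phi(phi)
  .check_prob_pair(q, p)
  pos <- q > 0
  cellf <- .cell_term_fun(phi)
  out <- sum(cellf(q[pos], p[pos]))
  if (!all(pos)) {
    if (!is.finite(phi$value_at_0)) return(Inf)
    out <- out + phi$value_at_0 * sum(p[!pos])
  }
  out
}

#' Penalized phi-divergence
#'
#' The phi-divergence with the weight \eqn{\phi(0)} on the empty cells of
#' \eqn{Q} replaced by a finite tuning constant \eqn{h}:
#' \deqn{D_{\phi,h}(Q,P) = \sum_{i: q_i>0} p_i \phi(q_i/p_i)
#'   + h \sum_{i: q_i=0} p_i.}
#' It is finite for every input and coincides with
#' \code{\link{phi_divergence}} whenever \eqn{Q} has no empty cell, so the
#' choice of \eqn{h} only matters for sparse tables.
#'
#' Two classical identities are useful as checks: with \eqn{\phi = PD_1}
#' and \eqn{h = 0.5}, \eqn{2n D_{\phi,h}(\hat\pi, P)} is the Pearson
#' \eqn{X^2} statistic for any count vector (the per-cell term
#' \eqn{(q-p)^2/(2p)} equals \eqn{p/2} at \eqn{q = 0}); with
#' \eqn{\phi = PD_0} and \eqn{h = 1} it is the likelihood-ratio \eqn{G^2}.
#'
#' @inheritParams phi_divergence
#' @param h Finite penalty placed on the total model mass of the empty
#'   cells of \code{q}.
#' @return A single finite number.
#' @examples
#' penalized_divergence(c(.5, .5, 0), c(.25, .25, .5), 1, h = 0.7)  # 0.6
#' @export
penalized_divergence <- function(q, p, phi, h) {
  phi <- as_phi(phi)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h))
    stop("'h' must be a single finite number")
  .check_prob_pair(q, p)
  pos <- q > 0
  cellf <- .cell_term_fun(phi)
  out <- sum(cellf(q[pos], p[pos]))
  if (!all(pos)) out <- out + h * sum(p[!pos])
  out
}
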