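#' Draw from an estimated multivariate normal confidence distribution
#'
#' @param theta_hat center (length `m`).
#' @param Sigma `m x m` covariance (symmetric positive semi-definite after a
#'   small jitter).
#' @param B number of draws.
#' @param jitter diagonal jitter added before factorization.
#' @return `B x m` matrix of draws.
#' @export
draw_confidence <- function(theta_hat, Sigma, B, jitter = 1e-10) {
  m <- length(theta_hat)
  stopifnot(B >= 1)
  if (all(Sigma == 0)) {
    return(matrix(theta_hat, B, m, byrow = TRUE))
  }
  S <- (Sigma + t(Sigma)) / 2 + diag(jitter, m)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-6 * max(abs(ev$values))) {
      stop("covariance is not positive semi-definite")
    }
    ch <- diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  }
  z <- matrix(stats::rnorm(B * m), B, m)
  sweep(z %*% ch, 2, theta_hat, "+")
}

#' Beliefs (probability-of-optimality) from confidence draws
#'
#' For each draw, the regime attaining the optimum (maximum or minimum,
#' per `direction`) scores one; exact ties within a draw split the score
#' equally among the tied regimes.  Beliefs are the per-regime average
#' scores and sum exactly to 1.
#'
#' @param draws `B x m` matrix of confidence-distribution draws.
#' @param direction `"min"` or `"max"`.
#' @return Length-`m` belief vector.
#' @export
beliefs_from_draws <- function(draws, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = 1)
  stopifnot(nrow(draws) >= 1)
  opt <- if (direction == "max") {
    do.call(pmax, as.data.frame(draws))
  } else {
    do.call(pmin, as.data.frame(draws))
  }
  hit <- (draws == opt) * 1
  hit <- hit / rowSums(hit)
  colMeans(hit)
}

#' Damp and clip a belief vector into randomization probabilities
#'
#' Raises beliefs to the power `c_t` and normalizes (probability matching
#' tempered toward uniform: `c_t = 0` is uniform randomization, `c_t = 1` is
#' full matching), then applies clipping bounds and renormalizes once.  The
#' single renormalization pass can leave entries slightly below `lo`;
#' strict positivity always holds.  Any `0^0` arising at `c_t = 0` is taken
#' as 1, the uniform limit.
#'
#' @param rho belief vector.
#' @param c_t damping constant in `[0, 1]`.
#' @param lo,hi clipping bounds, `0 < lo < 1/m` and `1/m < hi <= 1`.
#' @return Randomization probability vector summing to 1.
#' @export
damp_and_clip <- function(rho, c_t, lo = 0.05, hi = 0.95) {
  m <- length(rho)
  stopifnot(c_t >= 0, c_t <= 1, lo > 0, lo < 1 / m, hi > 1 / m, hi <= 1)
  if (all(rho == 0)) return(rep(1 / m, m))
  r <- ifelse(rho == 0 & c_t == 0, 1, rho^c_t)
  r <- r / sum(r)
  r <- pmin(pmax(r, lo), hi)
  r / sum(r)
}
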