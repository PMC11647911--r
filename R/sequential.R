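#' Least-squares Q-function fit for one stage
#'
#' Ordinary least squares of an outcome (or pseudo outcome) on a feature
#' matrix, with the covariance `Sigma = sigma2 * (Phi'Phi)^{-1}` and
#' residual variance `sigma2 = RSS / n` (divisor `n`, the completer count).
#' Rank-deficient normal equations fall back to a small ridge.
#'
#' @param Phi `n x p` feature matrix (completers).
#' @param y outcome vector.
#' @param ridge ridge used when the unpenalized solve fails.
#' @return List with `beta`, `Sigma`, `sigma2`, `n`, and `XtX_inv`.
#' @export
qfit_stage <- function(Phi, y, ridge = 1e-8) {
  Phi <- as.matrix(Phi)
  n <- nrow(Phi); p <- ncol(Phi)
  if (n < p) stop("precondition error: fewer completers than features")
  xtx <- crossprod(Phi)
  inv <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(inv)) inv <- solve(xtx + diag(ridge, p))
  beta <- inv %*% crossprod(Phi, y)
  res <- y - Phi %*% beta
  sigma2 <- sum(res^2) / n
  dimnames(inv) <- NULL
  list(beta = as.numeric(beta), Sigma = sigma2 * inv, sigma2 = sigma2,
       n = n, XtX_inv = inv)
}

#' Stage-1 pseudo outcomes from a stage-2 coefficient vector
#'
#' For each completer, optimizes the stage-2 model over the subject's own
#' feasible set (given observed `A1` and response status); when the feasible
#' set has a single option the observed outcome is carried back instead.
#'
#' @param X1,A1,X21,X22 completer data.
#' @param beta2 stage-2 coefficient vector (length 8).
#' @param design a `smart_design`.
#' @param direction `"min"` or `"max"`.
#' @param Y outcomes, used for the single-option carry-back.
#' @return Vector of pseudo outcomes.
#' @export
pseudo_outcomes <- function(X1, A1, X21, X22, beta2,
                            design = cancer_pain_design(),
                            direction = c("min", "max"), Y = NULL) {
  direction <- match.arg(direction)
  n <- length(X1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    opts <- feasible_lookup(design$feasible, A1[i], X22[i])
    if (length(opts) == 0) stop("design error: empty feasible set")
    if (length(opts) == 1) {
      if (is.null(Y)) stop("carry-back requires Y")
      out[i] <- Y[i]
      next
    }
    q <- as.numeric(q2_features(rep(X1[i], length(opts)),
                                rep(A1[i], length(opts)),
                                rep(X21[i], length(opts)), opts) %*% beta2)
    out[i] <- if (direction == "min") min(q) else max(q)
  }
  out
}

# Vectorized two-option pseudo-outcome machinery: feature rows for the lower
# and upper member of each completer's feasible pair, so pseudo outcomes for
# any beta2 draw are an elementwise min/max of two matrix products.
pseudo_outcome_basis <- function(X1, A1, X21, X22, design) {
  n <- length(X1)
  lo <- hi <- integer(n)
  for (i in seq_len(n)) {
    opts <- sort(feasible_lookup(design$feasible, A1[i], X22[i]))
    lo[i] <- opts[1]; hi[i] <- opts[length(opts)]
  }
  list(Flo = q2_features(X1, A1, X21, lo), Fhi = q2_features(X1, A1, X21, hi))
}

#' Nested projection-style confidence draws for Q-learning
#'
#' Stage 2: `B2` draws from the normal confidence distribution
#' `N(beta2_hat, Sigma2_hat)`.  Stage 1: `b_outer` fresh draws of the
#' stage-2 coefficients; for each, pseudo outcomes are rebuilt, the stage-1
#' model is refit by least squares, and `b_inner` draws are taken from the
#' conditional normal, pooling `b_outer * b_inner` stage-1 draws.  This
#' propagates the non-regularity of the stage-1 estimator into its
#' confidence distribution instead of relying on a single plug-in fit.
#'
#' @param fit2 stage-2 fit from [qfit_stage()].
#' @param X1,A1,X21,X22,Y completer data.
#' @param design a `smart_design`.
#' @param direction optimization direction.
#' @param B2 stage-2 pool size.
#' @param b_outer,b_inner stage-1 nesting sizes.
#' @return List with `beta2_draws` (`B2 x 8`) and `beta1_draws`
#'   (`b_outer*b_inner x 3`, features `(1, x1, a1)`).
#' @export
projection_draws <- function(fit2, X1, A1, X21, X22, Y,
                             design = cancer_pain_design(),
                             direction = c("min", "max"),
                             B2 = 1000L, b_outer = 32L, b_inner = 32L) {
  direction <- match.arg(direction)
  beta2_draws <- draw_confidence(fit2$beta, fit2$Sigma, B2)
  basis <- pseudo_outcome_basis(X1, A1, X21, X22, design)
  F1 <- cbind(1, X1, A1)
  xtx1 <- crossprod(F1)
  inv1 <- tryCatch(solve(xtx1), error = function(e) solve(xtx1 + diag(1e-8, 3)))
  proj <- inv1 %*% t(F1)
  outer_draws <- draw_confidence(fit2$beta, fit2$Sigma, b_outer)
  qlo <- basis$Flo %*% t(outer_draws)   # n x b_outer
  qhi <- basis$Fhi %*% t(outer_draws)
  V <- if (direction == "min") pmin(qlo, qhi) else pmax(qlo, qhi)
  B1 <- proj %*% V                      # 3 x b_outer point refits
  resid <- V - F1 %*% B1
  sigma2 <- colSums(resid^2) / nrow(F1)
  ch <- chol(inv1)                      # Sigma1(b) = sigma2[b] * inv1
  n_pool <- b_outer * b_inner
  z <- matrix(stats::rnorm(3 * n_pool), n_pool, 3)
  scale <- rep(sqrt(sigma2), each = b_inner)
  centers <- t(B1)[rep(seq_len(b_outer), each = b_inner), , drop = FALSE]
  beta1_draws <- centers + (z %*% ch) * scale
  list(beta2_draws = beta2_draws, beta1_draws = beta1_draws)
}

#' Per-option beliefs at one stage from Q-coefficient draws
#'
#' The belief for option `a` in feasible set `zeta` is the fraction of
#' coefficient draws under which `a` optimizes the stage model at the given
#' history; exact ties split equally.  Under the additive feature maps used
#' here, the optimizer depends on the history only through the components
#' that determine the feasible set, so beliefs are shared by all subjects in
#' the same feasibility group.
#'
#' @param draws matrix of coefficient draws (stage 2: `B x 8`; stage 1:
#'   `B x 3`).
#' @param stage 1 or 2.
#' @param zeta feasible option set (stage 2) — ignored at stage 1, where the
#'   options are the design's stage-1 set.
#' @param history list with elements `X1` and (stage 2) `A1`, `X21` — a
#'   representative history for the group.
#' @param design a `smart_design`.
#' @param direction optimization direction.
#' @return Named belief vector over the options.
#' @export
sequential_beliefs <- function(draws, stage, zeta = NULL,
                               history = list(X1 = 0, A1 = 0, X21 = 0),
                               design = cancer_pain_design(),
                               direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (stage == 1) {
    opts <- design$stage1_options
    qs <- vapply(opts, function(a) {
      as.numeric(cbind(1, history$X1, a) %*% t(draws))
    }, numeric(nrow(draws)))
  } else {
    opts <- zeta
    qs <- vapply(opts, function(a) {
      as.numeric(q2_features(history$X1, history$A1, history$X21, a) %*%
                   t(draws))
    }, numeric(nrow(draws)))
  }
  rho <- beliefs_from_draws(qs, direction)
  names(rho) <- opts
  rho
}
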