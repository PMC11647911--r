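#' Per-regime propensities from stored randomization probabilities
#'
#' The propensity for regime `j` at stage `k` is the probability, under the
#' randomization policy in force at the subject's own assignment week, of
#' receiving the treatment regime `j` recommends given the subject's history.
#'
#' Under up-front randomization the subject is randomized once among the `m`
#' embedded regimes with probabilities `r`; the stage-1 propensity is the
#' total probability of regimes sharing regime `j`'s stage-1 treatment, and
#' the stage-2 propensity is the conditional probability of regimes that
#' additionally agree with regime `j`'s stage-2 action for the subject's
#' observed response status.  Under sequential randomization the propensities
#' are the stored per-option probabilities at each stage's assignment week.
#'
#' @param design a `smart_design`.
#' @param stage1_probs for `scheme = "upfront"`, an `n x m` matrix of regime
#'   randomization vectors in force at each subject's enrollment week; for
#'   `"sequential"`, an `n x 2` matrix of stage-1 option probabilities
#'   (columns ordered as `design$stage1_options`).
#' @param X22 response indicators.
#' @param scheme `"upfront"` or `"sequential"`.
#' @param A1 (sequential only) realized stage-1 treatments.
#' @param stage2_probs (sequential only) `n x 2` matrix of the subject's own
#'   feasible-group probabilities at the stage-2 assignment week, columns
#'   aligned with the sorted feasible options.
#' @return List with `n x m` matrices `pi1` and `pi2`.  Sequential `pi2`
#'   entries for regimes whose stage-1 treatment differs from the realized
#'   `A1` are set to 1; they are only ever multiplied by zero consistency
#'   indicators.
#' @export
regime_propensities <- function(design, stage1_probs, X22,
                                scheme = c("upfront", "sequential"),
                                A1 = NULL, stage2_probs = NULL) {
  scheme <- match.arg(scheme)
  reg <- design$regimes
  m <- nrow(reg)
  if (anyNA(stage1_probs)) stop("ledger corrupt: missing stored probabilities")
  if (scheme == "upfront") {
    agr <- design_agreement(design)
    pi1 <- stage1_probs %*% agr$S1
    p2r <- (stage1_probs %*% agr$AB) / pi1
    p2n <- (stage1_probs %*% agr$AC) / pi1
    resp <- matrix(X22 == 1, nrow(pi1), m)
    pi2 <- ifelse(resp, p2r, p2n)
  } else {
    if (is.null(A1) || is.null(stage2_probs)) {
      stop("ledger corrupt: sequential scheme needs A1 and stage2_probs")
    }
    n <- length(A1)
    col1 <- match(reg$a1, design$stage1_options)
    pi1 <- stage1_probs[, col1, drop = FALSE]
    pi2 <- matrix(1, n, m)
    for (j in seq_len(m)) {
      own <- which(A1 == reg$a1[j] & !is.na(X22))
      if (!length(own)) next
      act <- regime_stage2_action(design, j, X22[own])
      opts1 <- vapply(own, function(i) {
        sort(feasible_lookup(design$feasible, A1[i], X22[i]))[1]
      }, numeric(1))
      colidx <- ifelse(act == opts1, 1L, 2L)
      pi2[cbind(own, j)] <- stage2_probs[cbind(own, colidx)]
    }
  }
  dimnames(pi1) <- dimnames(pi2) <- NULL
  list(pi1 = pi1, pi2 = pi2)
}

#' Weighted inverse probability weighted (WIPW) value estimator
#'
#' Ratio-form IPW estimator of an embedded regime's value: the weighted mean
#' of `Y` over regime-consistent completers, with weights
#' `W * C / (pi1 * pi2)`.  Setting `W = 1` gives the unweighted IPW
#' estimator.  Alongside the point estimate the per-subject estimating-
#' function terms `M_i = W C / (pi1 pi2) (Y - theta)` and the derivative
#' terms are returned for martingale-based inference.
#'
#' @param Y outcomes; `C` 0/1 regime consistency; `pi1`, `pi2` stage
#'   propensities; `W` variance-stabilizing weights (recycled); `Delta`
#'   completion indicators (recycled).
#' @return List with `theta`, `M` (per-subject estimating terms among
#'   completers), `dM` (derivative terms), `n_consistent`.  `theta` is `NA`
#'   (an undefined-estimate signal) when no consistent completers exist.
#' @export
wipw_estimate <- function(Y, C, pi1, pi2, W = 1, Delta = 1) {
  n <- length(Y)
  W <- rep_len(W, n); Delta <- rep_len(Delta, n)
  keep <- Delta == 1
  g <- W[keep] * C[keep] / (pi1[keep] * pi2[keep])
  den <- sum(g)
  ncons <- sum(C[keep] == 1)
  if (ncons == 0) {
    return(list(theta = NA_real_, M = rep(0, sum(keep)), dM = -g,
                n_consistent = 0L))
  }
  theta <- sum(g * Y[keep]) / den
  list(theta = theta, M = g * (Y[keep] - theta), dM = -g,
       n_consistent = as.integer(ncons))
}

# Stage-2 outcome-model feature map shared by the augmented estimators and
# by sequential Q-learning: (1, x1, I(a1=1), x21, I(a2=1), I(a2 in {2,5}),
# I(a2=3), I(a2=4)).
q2_features <- function(X1, A1, X21, A2) {
  cbind(1, X1, A1 == 1, X21, A2 == 1, A2 %in% c(2, 5), A2 == 3, A2 == 4) * 1
}

q1_aug_features <- function(X1, A1) {
  cbind(1, X1, A1, X1 * A1)
}

#' Fit augmentation models by backward recursion
#'
#' Fits the stage-2 outcome model `Q2` by least squares on completers, then,
#' for each embedded regime, forms pseudo outcomes by evaluating the fitted
#' model at the regime's recommended stage-2 action (given each subject's
#' own response status) and regresses them on `(1, x1, a1, x1 a1)` to obtain
#' the regime-specific stage-1 model.  Near-singular normal equations are
#' ridge-stabilized; when there are too few completers the fit is flagged
#' and downstream augmentation terms fall back to `L = 0`.
#'
#' @param X1,A1,X21,X22,A2,Y completer data vectors (all stages observed).
#' @param design a `smart_design`.
#' @param ridge ridge added to the normal-equation matrices.
#' @param min_n minimum completers required to fit.
#' @return List with `ok`, `beta2` (length 8) and `beta1` (4 x m matrix).
#' @export
fit_augmentation_models <- function(X1, A1, X21, X22, A2, Y,
                                    design = cancer_pain_design(),
                                    ridge = 1e-8, min_n = 10L) {
  m <- nrow(design$regimes)
  bad <- list(ok = FALSE, beta2 = rep(0, 8), beta1 = matrix(0, 4, m))
  n <- length(Y)
  if (n < max(min_n, 8L)) return(bad)
  P2 <- q2_features(X1, A1, X21, A2)
  beta2 <- tryCatch(
    solve(crossprod(P2) + diag(ridge, ncol(P2)), crossprod(P2, Y)),
    error = function(e) NULL)
  if (is.null(beta2) || anyNA(beta2)) return(bad)
  F1 <- q1_aug_features(X1, A1)
  M1 <- tryCatch(
    solve(crossprod(F1) + diag(ridge, 4), t(F1)),
    error = function(e) NULL)
  if (is.null(M1)) return(bad)
  beta1 <- matrix(0, 4, m)
  for (j in seq_len(m)) {
    a2j <- regime_stage2_action(design, j, X22)
    vtil <- q2_features(X1, A1, X21, a2j) %*% beta2
    beta1[, j] <- M1 %*% vtil
  }
  list(ok = TRUE, beta2 = as.numeric(beta2), beta1 = beta1)
}

# Evaluate the augmentation functions L1 (stage-1) and L2 (stage-2) for every
# subject under every regime, from a fitted model set.  L1 depends only on
# X1 and the regime's stage-1 treatment; L2 plugs the regime's stage-1 and
# stage-2 (response-specific) actions into the fitted Q2.
eval_augmentation <- function(models, design, X1, X21 = NULL, X22 = NULL,
                              stage = 2L) {
  reg <- design$regimes
  m <- nrow(reg)
  n <- length(X1)
  if (!isTRUE(models$ok)) return(matrix(0, n, m))
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    if (stage == 1L) {
      a <- reg$a1[j]
      out[, j] <- cbind(1, X1, a, X1 * a) %*% models$beta1[, j]
    } else {
      a2j <- regime_stage2_action(design, j, X22)
      out[, j] <- q2_features(X1, rep(reg$a1[j], n), X21, a2j) %*% models$beta2
    }
  }
  out
}

#' Weighted augmented IPW (WAIPW) value estimator
#'
#' Augmented estimator of an embedded regime's value for the two-stage case:
#' `psi_i = C2 Y / (pi1 pi2) + (1 - C1/pi1) L1 + (C1/pi1 - C2/(pi1 pi2)) L2`
#' and `theta = sum(WA * Delta * psi) / sum(WA * Delta)`.  With `L1 = L2 = 0`
#' the augmentation telescopes away and the estimator reduces to the
#' unnormalized Horvitz-Thompson mean; with `WA = 1` it is the unweighted
#' AIPW estimator.
#'
#' @param Y outcomes; `C1`, `C2` stagewise consistency indicators; `pi1`,
#'   `pi2` propensities; `L1`, `L2` evaluated augmentation functions (fitted
#'   on each subject's own enrollment-week data); `WA` weights; `Delta`
#'   completion indicators.
#' @return List as in [wipw_estimate()].
#' @export
waipw_estimate <- function(Y, C1, C2, pi1, pi2, L1 = 0, L2 = 0, WA = 1,
                           Delta = 1) {
  n <- length(Y)
  WA <- rep_len(WA, n); Delta <- rep_len(Delta, n)
  L1 <- rep_len(L1, n); L2 <- rep_len(L2, n)
  keep <- Delta == 1
  h1 <- C1[keep] / pi1[keep]
  h2 <- C2[keep] / (pi1[keep] * pi2[keep])
  psi <- h2 * Y[keep] + (1 - h1) * L1[keep] + (h1 - h2) * L2[keep]
  w <- WA[keep]
  ncons <- sum(C2[keep] == 1)
  if (sum(keep) == 0 || sum(w) == 0) {
    return(list(theta = NA_real_, M = numeric(0), dM = numeric(0),
                n_consistent = 0L))
  }
  theta <- sum(w * psi) / sum(w)
  list(theta = theta, M = w * (psi - theta), dM = -w,
       n_consistent = as.integer(ncons))
}

#' Normal-theory inference from estimating-function terms
#'
#' Standard error and confidence limits from the martingale central limit
#' theorem: with `delta = mean(dM)` and `sigma^2 = mean(M^2)` evaluated at
#' the estimate, `se = sigma / (|delta| sqrt(T))`, a two-sided interval
#' `theta +/- z_{1-alpha/2} se`, and one-sided bounds at `z_{1-alpha}`.
#'
#' @param theta point estimate.
#' @param M per-subject estimating-function terms at `theta`.
#' @param dM per-subject derivative terms.
#' @param alpha significance level.
#' @param n_consistent number of consistent completers (for the >= 2
#'   precondition).
#' @return A one-row data frame: `theta`, `se`, `ci_lo`, `ci_hi`, `lb`,
#'   `ub`, `n_consistent`.
#' @export
mestimation_inference <- function(theta, M, dM, alpha = 0.05,
                                  n_consistent = NA_integer_) {
  tt <- length(M)
  if (!is.na(n_consistent) && n_consistent < 2) {
    stop("precondition error: need at least 2 consistent completers")
  }
  delta <- mean(dM)
  sig2 <- max(mean(M^2), 1e-12)
  if (mean(M^2) == 0) stop("degenerate-variance error: all M terms are zero")
  se <- sqrt(sig2) / (abs(delta) * sqrt(tt))
  z2 <- stats::qnorm(1 - alpha / 2)
  z1 <- stats::qnorm(1 - alpha)
  data.frame(theta = theta, se = se,
             ci_lo = theta - z2 * se, ci_hi = theta + z2 * se,
             lb = theta - z1 * se, ub = theta + z1 * se,
             n_consistent = n_consistent)
}

#' Joint covariance of the regime-value estimators
#'
#' Stacked-estimating-equation sandwich covariance: with per-subject terms
#' `M_i^j` and derivative means `delta_j`, the `(j, l)` entry is
#' `sum_i M_i^j M_i^l / (T^2 delta_j delta_l)`.  The diagonal equals the
#' squared standard errors from [mestimation_inference()] by construction.
#'
#' @param M `T x m` matrix of per-subject estimating terms.
#' @param delta length-`m` vector of derivative means.
#' @return `m x m` covariance matrix.
#' @export
joint_confidence_covariance <- function(M, delta) {
  tt <- nrow(M)
  crossprod(M) / (tt^2 * tcrossprod(delta))
}
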