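#' Post-trial value estimates and inference for every regime
#'
#' Computes the requested estimators of every embedded regime's value on the
#' completed trial, with martingale-based standard errors, two-sided
#' confidence intervals, and one-sided bounds, and identifies the
#' estimated-optimal regime per estimator (direction-aware).
#'
#' @param state a completed `smart_trial`.
#' @param estimators subset of `c("ipw", "wipw", "aipw", "waipw")`.
#' @param alpha significance level.
#' @return Data frame with one row per estimator x regime (`estimator`,
#'   `regime`, `theta`, `se`, `ci_lo`, `ci_hi`, `lb`, `ub`, `n_consistent`,
#'   `est_opt`), where `est_opt` marks the estimated-optimal regime.
#' @export
post_trial_report <- function(state,
                              estimators = c("ipw", "wipw", "aipw", "waipw"),
                              alpha = 0.05) {
  done <- !is.na(state$Y)
  if (!all(done)) stop("precondition error: trial not complete")
  dirn <- state$scenario$direction
  out <- list()
  for (est in estimators) {
    se_ <- snapshot_estimates(state, done, est)
    rows <- lapply(seq_len(state$m), function(j) {
      if (is.na(se_$theta[j])) {
        return(data.frame(theta = NA_real_, se = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, lb = NA_real_, ub = NA_real_,
                          n_consistent = se_$n_consistent[j]))
      }
      mestimation_inference(se_$theta[j], se_$M[, j],
                            rep(se_$delta[j], nrow(se_$M)), alpha,
                            se_$n_consistent[j])
    })
    tab <- do.call(rbind, rows)
    tab$estimator <- est
    tab$regime <- seq_len(state$m)
    opt <- if (dirn == "min") which.min(se_$theta) else which.max(se_$theta)
    tab$est_opt <- tab$regime == opt
    out[[est]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("estimator", "regime", "theta", "se", "ci_lo", "ci_hi", "lb", "ub",
        "n_consistent", "est_opt")]
}

#' Flatten a completed trial into a per-subject ledger table
#'
#' One row per subject with the realized data, the stored assignment-week
#' randomization probabilities, per-regime propensities, variance-
#' stabilizing weights, and evaluated augmentation functions — everything
#' needed to recompute any of the four value estimators without the engine
#' state.
#'
#' @param state a `smart_trial`.
#' @return A data frame.
#' @export
ledger_table <- function(state) {
  m <- state$m
  df <- data.frame(subject_id = seq_len(state$N), enroll_week = state$tau,
                   X1 = state$X1, A1 = state$A1, X21 = state$X21,
                   X22 = state$X22, A2 = state$A2, Y = state$Y,
                   completion_week = state$compw)
  add <- function(df, mat, prefix) {
    cols <- as.data.frame(mat)
    names(cols) <- paste0(prefix, "_", seq_len(ncol(mat)))
    cbind(df, cols)
  }
  df <- add(df, state$R1, "p_stage1")
  if (state$method$scheme == "sequential") df <- add(df, state$P2, "p_stage2")
  df <- add(df, state$PI1, "pi1")
  df <- add(df, state$PI2, "pi2")
  df <- add(df, state$W, "w")
  df <- add(df, state$WA, "wa")
  df <- add(df, state$L1m, "l1")
  df <- add(df, state$L2m, "l2")
  df
}

#' Value estimates from a ledger table
#'
#' Recomputes the per-regime value estimates and inference from a flat
#' ledger (for example one read back from CSV), through the same estimating
#' functions used on live trial states.
#'
#' @param tbl a data frame in the [ledger_table()] layout.
#' @param design a `smart_design`.
#' @param estimators estimators to compute.
#' @param alpha significance level.
#' @param direction `"min"` or `"max"`.
#' @return As [post_trial_report()].
#' @export
value_estimates <- function(tbl, design = cancer_pain_design(),
                            estimators = c("ipw", "wipw", "aipw", "waipw"),
                            alpha = 0.05, direction = "min") {
  m <- nrow(design$regimes)
  getm <- function(prefix) {
    as.matrix(tbl[paste0(prefix, "_", seq_len(m))])
  }
  C1 <- regime_consistency(design, tbl$A1, through_stage = 1L)
  C2 <- regime_consistency(design, tbl$A1, tbl$X22, tbl$A2)
  PI1 <- getm("pi1"); PI2 <- getm("pi2")
  W <- getm("w"); WA <- getm("wa"); L1 <- getm("l1"); L2 <- getm("l2")
  out <- list()
  for (est in estimators) {
    tab <- do.call(rbind, lapply(seq_len(m), function(j) {
      e <- if (est %in% c("ipw", "wipw")) {
        wipw_estimate(tbl$Y, C2[, j], PI1[, j], PI2[, j],
                      W = if (est == "wipw") W[, j] else 1)
      } else {
        waipw_estimate(tbl$Y, C1[, j], C2[, j], PI1[, j], PI2[, j],
                       L1[, j], L2[, j],
                       WA = if (est == "waipw") WA[, j] else 1)
      }
      if (is.na(e$theta)) {
        return(data.frame(theta = NA_real_, se = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, lb = NA_real_, ub = NA_real_,
                          n_consistent = e$n_consistent))
      }
      mestimation_inference(e$theta, e$M, e$dM, alpha, e$n_consistent)
    }))
    tab$estimator <- est
    tab$regime <- seq_len(m)
    opt <- if (direction == "min") which.min(tab$theta) else
      which.max(tab$theta)
    tab$est_opt <- tab$regime == opt
    out[[est]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("estimator", "regime", "theta", "se", "ci_lo", "ci_hi", "lb", "ub",
        "n_consistent", "est_opt")]
}
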