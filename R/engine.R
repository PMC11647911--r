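#' Specify a randomization method
#'
#' @param scheme `"sr"` (simple uniform up-front randomization among the
#'   embedded regimes), `"upfront"` (Thompson sampling over regime values),
#'   or `"sequential"` (per-stage Thompson sampling via Q-learning).
#' @param estimator value estimator driving up-front adaptation.
#' @param c_t damping constant in `[0, 1]` (constant schedule).
#' @param clip length-2 clipping bounds applied to every randomization
#'   vector before the final normalization pass.
#' @param B confidence-distribution draws per up-front update.
#' @param B2,b_outer,b_inner sequential-scheme pool sizes: `B2` stage-2
#'   draws; `b_outer x b_inner` pooled stage-1 draws.
#' @param burnin_per_regime adaptation starts only after this many completed
#'   subjects are consistent with every embedded regime.
#' @param update_period weeks between policy updates (1 = weekly; larger
#'   periods hold the randomization vectors between updates).
#' @return A `rar_method` object.
#' @export
rar_method <- function(scheme = c("sr", "upfront", "sequential"),
                       estimator = c("wipw", "ipw", "aipw", "waipw"),
                       c_t = 1, clip = c(0.05, 0.95), B = 1000L,
                       B2 = 1000L, b_outer = 32L, b_inner = 32L,
                       burnin_per_regime = 25L, update_period = 1L) {
  structure(list(scheme = match.arg(scheme), estimator = match.arg(estimator),
                 c_t = c_t, clip = clip, B = as.integer(B),
                 B2 = as.integer(B2), b_outer = as.integer(b_outer),
                 b_inner = as.integer(b_inner),
                 burnin_per_regime = as.integer(burnin_per_regime),
                 update_period = as.integer(update_period)),
            class = "rar_method")
}

imax <- 2147483647

#' Initialize a trial state
#'
#' Pre-draws the potential-data stream (enrollment weeks, baseline scores,
#' transition and outcome noise) and the assignment uniforms from two
#' seed-derived streams, so that different randomization methods run against
#' identical subject populations when given the same seed.  Thompson-
#' sampling draws use a third stream, re-seeded deterministically each week,
#' which makes any week's policy update exactly reproducible from the
#' corresponding data snapshot.
#'
#' @param design a `smart_design`.
#' @param scenario a `scenario_params`.
#' @param method a `rar_method`.
#' @param seed integer seed.
#' @return A `smart_trial` state at week 0.
#' @export
init_trial <- function(design, scenario, method, seed) {
  set.seed(seed)
  ss <- sample.int(imax - 64L, 3L)
  N <- scenario$N
  m <- nrow(design$regimes)
  gap <- design$stage_gap_weeks
  set.seed(ss[1])
  tau <- sample.int(scenario$accrual_weeks, N, replace = TRUE)
  X1 <- draw_baseline(N, scenario)
  e1 <- stats::rnorm(N, 0, scenario$e1_sd)
  e2 <- stats::rnorm(N, 0, scenario$e2_sd)
  set.seed(ss[2])
  u1 <- stats::runif(N)
  u2 <- stats::runif(N)
  p1cols <- if (method$scheme == "sequential") 2L else m
  st <- list(
    design = design, scenario = scenario, method = method, seed = seed,
    N = N, m = m, gap = gap, ts_base = ss[3],
    tau = tau, X1 = X1, e1 = e1, e2 = e2, u1 = u1, u2 = u2,
    s2w = tau + gap, compw = tau + 2L * gap,
    A1 = rep(NA_integer_, N), regime = rep(NA_integer_, N),
    X21 = rep(NA_real_, N), X22 = rep(NA_integer_, N),
    A2 = rep(NA_integer_, N), Y = rep(NA_real_, N),
    R1 = matrix(NA_real_, N, p1cols), P2 = matrix(NA_real_, N, 2),
    W = matrix(NA_real_, N, m), WA = matrix(NA_real_, N, m),
    C1m = matrix(NA_real_, N, m), C2m = matrix(NA_real_, N, m),
    PI1 = matrix(NA_real_, N, m), PI2 = matrix(NA_real_, N, m),
    L1m = matrix(0, N, m), L2m = matrix(0, N, m),
    models = list(), policy = list(),
    t_star = NA_integer_,
    anchor_set = rep(FALSE, m), anchor_week = rep(NA_integer_, m),
    Xi_star = rep(NA_real_, m),
    XiA_star = rep(NA_real_, m),
    W_cur = rep(1, m), WA_cur = rep(1, m),
    r_prev = NULL, agr = design_agreement(design),
    horizon = max(tau) + gap, final_week = max(tau) + 2L * gap,
    week = 0L
  )
  class(st) <- "smart_trial"
  st
}

uniform_policy <- function(state) {
  m <- state$m
  if (state$method$scheme == "sequential") {
    g <- group_keys(state$design)
    groups <- lapply(g, function(k) c(0.5, 0.5))
    names(groups) <- g
    list(stage1 = rep(1 / 2, 2), stage2 = groups)
  } else {
    list(r = rep(1 / m, m))
  }
}

group_keys <- function(design) {
  as.vector(outer(design$stage1_options, 0:1,
                  function(a, s) paste0(a, "_", s)))
}

# Per-regime value estimates plus estimating terms on a data snapshot.
snapshot_estimates <- function(state, done, estimator) {
  m <- state$m
  idx <- which(done)
  nd <- length(idx)
  theta <- delta <- numeric(m)
  M <- matrix(0, nd, m)
  ncons <- integer(m)
  for (j in seq_len(m)) {
    if (estimator %in% c("ipw", "wipw")) {
      w <- if (estimator == "wipw") state$W[idx, j] else 1
      e <- wipw_estimate(state$Y[idx], state$C2m[idx, j],
                         state$PI1[idx, j], state$PI2[idx, j], W = w)
    } else {
      w <- if (estimator == "waipw") state$WA[idx, j] else 1
      e <- waipw_estimate(state$Y[idx], state$C1m[idx, j],
                          state$C2m[idx, j], state$PI1[idx, j],
                          state$PI2[idx, j], state$L1m[idx, j],
                          state$L2m[idx, j], WA = w)
    }
    theta[j] <- e$theta
    if (nd > 0 && length(e$M) == nd) M[, j] <- e$M
    delta[j] <- if (length(e$dM)) mean(e$dM) else NA_real_
    ncons[j] <- e$n_consistent
  }
  list(theta = theta, M = M, delta = delta, n_consistent = ncons)
}

# Current-policy propensities (pi1, pi2 by response stratum) per regime.
policy_propensities <- function(state, pol) {
  reg <- state$design$regimes
  m <- state$m
  if (state$method$scheme == "sequential") {
    col1 <- match(reg$a1, state$design$stage1_options)
    pi1 <- pol$stage1[col1]
    pi2s <- matrix(NA_real_, m, 2)   # columns: stratum s = 0, 1
    for (j in seq_len(m)) {
      for (s in 0:1) {
        key <- paste0(reg$a1[j], "_", s)
        opts <- sort(feasible_lookup(state$design$feasible, reg$a1[j], s))
        act <- regime_stage2_action(state$design, j, s)
        pi2s[j, s + 1] <- pol$stage2[[key]][match(act, opts)]
      }
    }
  } else {
    r <- pol$r
    pi1 <- as.numeric(r %*% state$agr$S1)
    pi2s <- cbind(as.numeric(r %*% state$agr$AC) / pi1,
                  as.numeric(r %*% state$agr$AB) / pi1)
  }
  list(pi1 = pi1, pi2s = pi2s)
}

# Variance-stabilizing weight state update (Eq.-(7)-style plug-in).  Called
# once per week after the week's randomization vectors are fixed.
update_weight_state <- function(state, done, t, pol) {
  m <- state$m
  if (is.na(state$t_star) || t <= state$t_star) {
    state$W_cur <- rep(1, m); state$WA_cur <- rep(1, m)
    if (!is.na(state$t_star) && t == state$t_star) {
      state <- set_weight_anchors(state, done, pol, t)
    }
    return(state)
  }
  idx <- which(done)
  nd <- length(idx)
  pp <- policy_propensities(state, pol)
  for (j in seq_len(m)) {
    # regimes anchored this very week (or not yet) keep W = 1
    if (!state$anchor_set[j] || state$anchor_week[j] >= t) {
      state$W_cur[j] <- 1; state$WA_cur[j] <- 1
      next
    }
    xi <- xi_hat(state, idx, j, pp)
    if (is.na(xi$ipw) || xi$ipw <= 0) next            # hold previous weight
    state$W_cur[j] <- sqrt(state$Xi_star[j] / xi$ipw)
    if (!is.na(xi$aipw) && xi$aipw > 0) {
      state$WA_cur[j] <- sqrt(state$XiA_star[j] / xi$aipw)
    }
  }
  # regimes whose anchor was delayed by an empty response stratum
  if (!all(state$anchor_set)) {
    state <- set_weight_anchors(state, done, pol, t)
  }
  state
}

set_weight_anchors <- function(state, done, pol, t) {
  idx <- which(done)
  pp <- policy_propensities(state, pol)
  for (j in which(!state$anchor_set)) {
    xi <- xi_hat(state, idx, j, pp)
    if (!is.na(xi$ipw) && xi$ipw > 0) {
      state$Xi_star[j] <- xi$ipw
      state$XiA_star[j] <- if (!is.na(xi$aipw) && xi$aipw > 0) xi$aipw else NA
      state$anchor_set[j] <- TRUE
      state$anchor_week[j] <- t
    }
  }
  state
}

# Plug-in estimate of the conditional second moment Xi of the estimating
# function for regime j, under the current-week probabilities `pp`.  The
# stratum components mu^{(s)} are inverse-propensity-weighted squared
# residuals around the unweighted IPW estimate, using each subject's own
# stored assignment-week propensities; Xi recombines them with the current
# probabilities.  Returns NA when either response stratum has no consistent
# completer.
xi_hat <- function(state, idx, j, pp) {
  nd <- length(idx)
  if (nd == 0) return(list(ipw = NA_real_, aipw = NA_real_))
  C2 <- state$C2m[idx, j]
  e0 <- wipw_estimate(state$Y[idx], C2, state$PI1[idx, j],
                      state$PI2[idx, j], W = 1)
  if (is.na(e0$theta)) return(list(ipw = NA_real_, aipw = NA_real_))
  ipden <- state$PI1[idx, j] * state$PI2[idx, j]
  s_ind <- state$X22[idx]
  xi_from <- function(resid2) {
    mu <- numeric(2)
    for (s in 0:1) {
      sel <- C2 == 1 & s_ind == s
      if (!any(sel)) return(NA_real_)
      mu[s + 1] <- sum(resid2[sel] / ipden[sel]) / nd
    }
    sum(mu / (pp$pi2s[j, ] * pp$pi1[j]))
  }
  r2_ipw <- (state$Y[idx] - e0$theta)^2
  h1 <- state$C1m[idx, j] / state$PI1[idx, j]
  h2 <- C2 / ipden
  psi <- h2 * state$Y[idx] + (1 - h1) * state$L1m[idx, j] +
    (h1 - h2) * state$L2m[idx, j]
  r2_aipw <- (psi - e0$theta)^2
  list(ipw = xi_from(r2_ipw), aipw = xi_from(r2_aipw))
}

compute_policy_upfront <- function(state, done, t) {
  method <- state$method
  prev <- if (!is.null(state$r_prev)) state$r_prev else uniform_policy(state)
  if (is.na(state$t_star) || t <= state$t_star) return(uniform_policy(state))
  set.seed((state$ts_base + t) %% imax)
  est <- snapshot_estimates(state, done, method$estimator)
  if (anyNA(est$theta)) return(prev)
  Sigma <- joint_confidence_covariance(est$M, est$delta)
  draws <- draw_confidence(est$theta, Sigma, method$B)
  rho <- beliefs_from_draws(draws, state$scenario$direction)
  list(r = damp_and_clip(rho, method$c_t, method$clip[1], method$clip[2]))
}

compute_policy_sequential <- function(state, done, t) {
  method <- state$method
  design <- state$design
  prev <- if (!is.null(state$r_prev)) state$r_prev else uniform_policy(state)
  if (is.na(state$t_star) || t <= state$t_star) return(uniform_policy(state))
  set.seed((state$ts_base + t) %% imax)
  idx <- which(done)
  P2f <- q2_features(state$X1[idx], state$A1[idx], state$X21[idx],
                     state$A2[idx])
  fit2 <- tryCatch(qfit_stage(P2f, state$Y[idx]), error = function(e) NULL)
  if (is.null(fit2)) return(prev)
  pd <- projection_draws(fit2, state$X1[idx], state$A1[idx], state$X21[idx],
                         state$X22[idx], state$Y[idx], design,
                         state$scenario$direction, method$B2,
                         method$b_outer, method$b_inner)
  dirn <- state$scenario$direction
  rho1 <- sequential_beliefs(pd$beta1_draws, 1, design = design,
                             direction = dirn)
  stage1 <- damp_and_clip(as.numeric(rho1), method$c_t,
                          method$clip[1], method$clip[2])
  groups <- list()
  for (a in design$stage1_options) for (s in 0:1) {
    opts <- sort(feasible_lookup(design$feasible, a, s))
    rho <- sequential_beliefs(pd$beta2_draws, 2, zeta = opts,
                              history = list(X1 = 0, A1 = a, X21 = 0),
                              design = design, direction = dirn)
    groups[[paste0(a, "_", s)]] <-
      damp_and_clip(as.numeric(rho), method$c_t,
                    method$clip[1], method$clip[2])
  }
  list(stage1 = stage1, stage2 = groups)
}

#' Advance a trial by one week
#'
#' Runs the week-`t` cycle: (i) form the strict-past snapshot (subjects who
#' completed follow-up by week `t - 1`); (ii) check the burn-in rule and fit
#' the week's augmentation models; (iii) update the randomization policy and
#' variance-stabilizing weight state; (iv) enroll this week's arrivals and
#' assign stage 1 (or an entire regime); (v) draw interim data and assign
#' stage 2 for subjects whose stage-2 decision falls due; (vi) record
#' outcomes for subjects completing follow-up.  Probabilities, weights, and
#' augmentation-model evaluations in force at each subject's own assignment
#' weeks are stored in the ledger.
#'
#' @param state a `smart_trial`.
#' @param t week number.
#' @return The updated `smart_trial`.
#' @export
advance_week <- function(state, t) {
  method <- state$method
  design <- state$design
  done <- !is.na(state$compw) & state$compw <= t - 1 & !is.na(state$A1)
  # burn-in: every regime needs the configured number of consistent completers
  if (is.na(state$t_star) && any(done)) {
    counts <- colSums(state$C2m[done, , drop = FALSE])
    if (all(counts >= method$burnin_per_regime)) state$t_star <- t
  }
  state$models[[t]] <- fit_augmentation_models(
    state$X1[done], state$A1[done], state$X21[done], state$X22[done],
    state$A2[done], state$Y[done], design)
  # policy
  hold <- method$update_period > 1L && ((t - 1L) %% method$update_period) != 0L
  pol <- if (hold && !is.null(state$r_prev)) {
    state$r_prev
  } else if (method$scheme == "sr") {
    uniform_policy(state)
  } else if (method$scheme == "upfront") {
    compute_policy_upfront(state, done, t)
  } else {
    compute_policy_sequential(state, done, t)
  }
  state$r_prev <- pol
  state <- update_weight_state(state, done, t, pol)
  state$policy[[t]] <- list(
    week = t, scheme = method$scheme, policy = pol,
    burnin = is.na(state$t_star) || t <= state$t_star,
    W = state$W_cur, WA = state$WA_cur)
  # (iv) enrollment
  idx <- which(state$tau == t)
  if (length(idx)) {
    if (method$scheme == "sequential") {
      p1 <- pol$stage1
      opts <- design$stage1_options
      state$A1[idx] <- ifelse(state$u1[idx] <= p1[1], opts[1], opts[2])
      state$R1[idx, ] <- matrix(p1, length(idx), 2, byrow = TRUE)
    } else {
      cum <- cumsum(pol$r)
      g <- 1L + findInterval(state$u1[idx], cum[-state$m])
      state$regime[idx] <- g
      state$A1[idx] <- design$regimes$a1[g]
      state$R1[idx, ] <- matrix(pol$r, length(idx), state$m, byrow = TRUE)
    }
    state$C1m[idx, ] <- regime_consistency(design, state$A1[idx],
                                           through_stage = 1L)
    state$W[idx, ] <- matrix(state$W_cur, length(idx), state$m, byrow = TRUE)
    state$WA[idx, ] <- matrix(state$WA_cur, length(idx), state$m, byrow = TRUE)
    state$L1m[idx, ] <- eval_augmentation(state$models[[t]], design,
                                          state$X1[idx], stage = 1L)
  }
  # (v) stage-2 decisions falling due
  idx2 <- which(state$s2w == t & !is.na(state$A1))
  if (length(idx2)) {
    tr <- transition_stage2(state$X1[idx2], state$A1[idx2], state$scenario,
                            e1 = state$e1[idx2])
    state$X21[idx2] <- tr$X21
    state$X22[idx2] <- tr$X22
    if (method$scheme == "sequential") {
      for (i in idx2) {
        key <- paste0(state$A1[i], "_", state$X22[i])
        opts <- sort(feasible_lookup(design$feasible, state$A1[i],
                                     state$X22[i]))
        rg <- pol$stage2[[key]]
        state$A2[i] <- opts[1L + (state$u2[i] > rg[1])]
        state$P2[i, ] <- rg
      }
    } else {
      state$A2[idx2] <- as.integer(regime_stage2_action(
        design, state$regime[idx2], state$X22[idx2]))
    }
    state$C2m[idx2, ] <- regime_consistency(design, state$A1[idx2],
                                            state$X22[idx2], state$A2[idx2])
    pr <- if (method$scheme == "sequential") {
      regime_propensities(design, state$R1[idx2, , drop = FALSE],
                          state$X22[idx2], "sequential",
                          A1 = state$A1[idx2],
                          stage2_probs = state$P2[idx2, , drop = FALSE])
    } else {
      regime_propensities(design, state$R1[idx2, , drop = FALSE],
                          state$X22[idx2], "upfront")
    }
    state$PI1[idx2, ] <- pr$pi1
    state$PI2[idx2, ] <- pr$pi2
    # stage-2 augmentation evaluations use each subject's enrollment-week fit
    for (w in unique(state$tau[idx2])) {
      sub <- idx2[state$tau[idx2] == w]
      state$L2m[sub, ] <- eval_augmentation(state$models[[w]], design,
                                            state$X1[sub],
                                            X21 = state$X21[sub],
                                            X22 = state$X22[sub], stage = 2L)
    }
    # outcome noise is pre-drawn; Y becomes observable at completion week
    state$Y[idx2] <- draw_outcome(state$X1[idx2], state$A1[idx2],
                                  state$X21[idx2], state$A2[idx2],
                                  state$scenario, e2 = state$e2[idx2])
  }
  state$week <- t
  state
}

#' Run a complete trial
#'
#' @param design a `smart_design`.
#' @param scenario a `scenario_params`.
#' @param method a `rar_method`.
#' @param seed integer seed.
#' @return The completed `smart_trial` with `in_trial` summary metrics
#'   attached (`mean_y`, `prop_a1_opt`, `prop_regime_opt`, `t_star`).
#' @export
run_trial <- function(design, scenario, method, seed) {
  state <- init_trial(design, scenario, method, seed)
  for (t in seq_len(state$horizon)) state <- advance_week(state, t)
  truth <- true_regime_values(scenario, design)
  jopt <- truth$optimal
  state$truth <- truth
  state$in_trial <- data.frame(
    mean_y = mean(state$Y),
    prop_a1_opt = mean(state$A1 == design$regimes$a1[jopt]),
    prop_regime_opt = mean(state$C2m[, jopt]),
    t_star = ifelse(is.na(state$t_star), NA_integer_, state$t_star))
  state
}

#' @export
print.smart_trial <- function(x, ...) {
  cat("SMART trial:", x$N, "subjects,", x$method$scheme, "randomization,",
      "week", x$week, "of", x$final_week, "\n")
  if (!is.null(x$in_trial)) {
    cat(sprintf("  in-trial mean Y %.3f; prop A1 optimal %.3f; ",
                x$in_trial$mean_y, x$in_trial$prop_a1_opt))
    cat(sprintf("prop optimal regime %.3f; burn-in ended week %s\n",
                x$in_trial$prop_regime_opt, x$in_trial$t_star))
  }
  invisible(x)
}

#' Data snapshot observable strictly before a given week
#'
#' Returns the analysis dataset available for a policy update at week `t`:
#' subjects enrolled by week `t - 1`, their stage data for stages reached by
#' then, completion flags, and outcomes for completers, together with the
#' stored assignment-time probabilities.
#'
#' @param state a `smart_trial`.
#' @param t week (>= 1).
#' @return A data frame (zero rows when nothing is observable).
#' @export
ledger_snapshot <- function(state, t) {
  stopifnot(t >= 1)
  enrolled <- !is.na(state$A1) & state$tau <= t - 1
  idx <- which(enrolled)
  has2 <- state$s2w[idx] <= t - 1
  done <- state$compw[idx] <= t - 1
  df <- data.frame(
    subject_id = idx, enroll_week = state$tau[idx], X1 = state$X1[idx],
    A1 = state$A1[idx],
    X21 = ifelse(has2, state$X21[idx], NA_real_),
    X22 = ifelse(has2, state$X22[idx], NA_integer_),
    A2 = ifelse(has2, state$A2[idx], NA_integer_),
    Delta = as.integer(done),
    Y = ifelse(done, state$Y[idx], NA_real_),
    completion_week = ifelse(done, state$compw[idx], NA_integer_))
  df
}

#' Up-front policy update for a given week (reproducible standalone)
#'
#' Recomputes the week-`t` regime randomization vector from the trial state
#' exactly as the engine did, including the deterministic per-week seeding
#' of the Thompson-sampling draws.
#'
#' @param state a `smart_trial` advanced at least to week `t - 1`.
#' @param t week.
#' @return List with the policy (`r` or group vectors) for week `t`.
#' @export
update_upfront_policy <- function(state, t) {
  done <- !is.na(state$compw) & state$compw <= t - 1 & !is.na(state$A1)
  compute_policy_upfront(state, done, t)
}

#' Sequential policy update for a given week (reproducible standalone)
#'
#' @inheritParams update_upfront_policy
#' @return List with `stage1` and `stage2` group randomization vectors.
#' @export
update_sequential_policy <- function(state, t) {
  done <- !is.na(state$compw) & state$compw <= t - 1 & !is.na(state$A1)
  compute_policy_sequential(state, done, t)
}

#' Variance-stabilizing weight update (exported surface)
#'
#' Applies the weight-state update for week `t` against a given policy and
#' returns the per-regime weights in force for subjects assigned at `t`.
#'
#' @param state a `smart_trial`.
#' @param t week.
#' @param pol policy list (defaults to the recorded week-`t` policy).
#' @return List with `W` and `WA` (length-`m` vectors).
#' @export
update_stabilizing_weights <- function(state, t, pol = NULL) {
  if (is.null(pol)) pol <- state$policy[[t]]$policy
  done <- !is.na(state$compw) & state$compw <= t - 1 & !is.na(state$A1)
  st <- update_weight_state(state, done, t, pol)
  list(W = st$W_cur, WA = st$WA_cur)
}
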