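test_that("up-front propensities follow the regime-pooling formulas", {
  r <- matrix(rep(1 / 8, 8), 1)
  pr <- regime_propensities(cp_design, r, X22 = 1, scheme = "upfront")
  expect_equal(pr$pi1[1, 1], 0.5)
  expect_equal(pr$pi2[1, 1], 0.5)    # (r1 + r2) / 0.5
  expect_equal(pr$pi1[1, 1] * pr$pi2[1, 1], 0.25)
  # non-uniform vector, regime 1, nonresponder: (r1 + r4) / (r1+..+r4)
  r2 <- matrix(c(0.2, 0.1, 0.1, 0.1, 0.125, 0.125, 0.125, 0.125), 1)
  pr2 <- regime_propensities(cp_design, r2, X22 = 0, scheme = "upfront")
  expect_equal(pr2$pi1[1, 1], 0.5)
  expect_equal(pr2$pi2[1, 1], 0.6)
  # degenerate policy mass on one regime gives unit propensities
  r3 <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 1)
  pr3 <- regime_propensities(cp_design, r3, X22 = 1, scheme = "upfront")
  expect_equal(pr3$pi1[1, 1], 1)
  expect_equal(pr3$pi2[1, 1], 1)
  expect_error(regime_propensities(cp_design, matrix(NA_real_, 1, 8), 1,
                                   "upfront"), "ledger corrupt")
})

test_that("sequential propensities read the stored per-option vectors", {
  s1 <- matrix(c(0.3, 0.7), 1)
  s2 <- matrix(c(0.9, 0.1), 1)   # options sorted: responder to arm 1 -> {3,4}
  pr <- regime_propensities(cp_design, s1, X22 = 1, scheme = "sequential",
                            A1 = 1, stage2_probs = s2)
  expect_equal(pr$pi1[1, 5], 0.7)  # regime 5 recommends a1 = 1
  expect_equal(pr$pi2[1, 5], 0.9)  # regime 5 responder action is 3
  expect_equal(pr$pi2[1, 8], 0.1)  # regime 8 responder action is 4
  expect_equal(pr$pi1[1, 1], 0.3)  # regime 1 recommends a1 = 0
  expect_equal(pr$pi2[1, 1], 1)    # unused: stage-1 inconsistent
})

test_that("the weighted IPW estimator matches hand evaluation", {
  # constant propensity cancels in the ratio form
  e <- wipw_estimate(Y = c(1.7, 1.9, 1.5, 0), C = c(1, 1, 1, 0),
                     pi1 = rep(0.5, 4), pi2 = rep(0.5, 4))
  expect_equal(e$theta, 1.7)
  # two consistent subjects, unequal propensities
  e2 <- wipw_estimate(Y = c(1, 2), C = c(1, 1), pi1 = c(1, 1),
                      pi2 = c(0.5, 0.25))
  expect_equal(e2$theta, 10 / 6)
  # no consistent completers: undefined-estimate signal
  e3 <- wipw_estimate(Y = 1, C = 0, pi1 = 1, pi2 = 1)
  expect_true(is.na(e3$theta))
  expect_equal(e3$n_consistent, 0L)
})

test_that("the augmented estimator matches hand evaluation of its terms", {
  # single fully-consistent subject: 2/0.25 + (1 - 2) * 1 + (2 - 4) * 1 = 5
  e <- waipw_estimate(Y = 2, C1 = 1, C2 = 1, pi1 = 0.5, pi2 = 0.5,
                      L1 = 1, L2 = 1)
  expect_equal(e$theta, 5)
  # L = 0 telescopes to the unnormalized Horvitz-Thompson mean
  y <- c(2, 1, 3); c2 <- c(1, 0, 1); p1 <- c(0.5, 0.5, 0.25)
  p2 <- c(0.5, 0.25, 0.5)
  e0 <- waipw_estimate(y, C1 = c2, C2 = c2, pi1 = p1, pi2 = p2)
  expect_equal(e0$theta, mean(c2 * y / (p1 * p2)))
})

test_that("weights equal to one reduce the weighted estimators bit-for-bit", {
  st <- small_sr_trial()
  tbl <- ledger_table(st)
  tbl[paste0("w_", 1:8)] <- 1
  tbl[paste0("wa_", 1:8)] <- 1
  est <- value_estimates(tbl, cp_design)
  ipw <- est[est$estimator == "ipw", ]
  wipw <- est[est$estimator == "wipw", ]
  expect_identical(wipw$theta, ipw$theta)
  expect_identical(wipw$se, ipw$se)
  aipw <- est[est$estimator == "aipw", ]
  waipw <- est[est$estimator == "waipw", ]
  expect_identical(waipw$theta, aipw$theta)
  expect_identical(waipw$se, aipw$se)
})

test_that("augmentation models interpolate noiseless linear data exactly", {
  set.seed(7)
  n <- 60
  x1 <- rnorm(n, 5); a1 <- rbinom(n, 1, 0.5)
  x21 <- 0.9 * x1 - 1.5 * a1 + rnorm(n)
  x22 <- as.integer(x21 < 0.9 * x1)
  a2 <- ifelse(a1 == 1, ifelse(x22 == 1, sample(3:4, n, TRUE),
                               sample(4:5, n, TRUE)),
               ifelse(x22 == 1, sample(0:1, n, TRUE), sample(1:2, n, TRUE)))
  b2 <- c(1, 0.3, -0.75, 0.6, -0.25, -0.75, -0.75, -0.85)
  y <- as.numeric(smartrar:::q2_features(x1, a1, x21, a2) %*% b2)
  mod <- fit_augmentation_models(x1, a1, x21, x22, a2, y, cp_design)
  expect_true(mod$ok)
  expect_equal(mod$beta2, b2, tolerance = 1e-7)
  # regime-specific pseudo outcomes equal the fitted stage-2 model at the
  # regime's recommended action (3-subject spot check, regime 8 -> a2 = 4)
  sub <- 1:3
  expected <- as.numeric(
    smartrar:::q2_features(x1[sub], rep(1, 3), x21[sub], rep(4, 3)) %*% b2)
  l2 <- smartrar:::eval_augmentation(mod, cp_design, x1[sub],
                                     X21 = x21[sub], X22 = x22[sub],
                                     stage = 2L)
  expect_equal(l2[, 8], expected, tolerance = 1e-7)
})

test_that("augmentation with misspecified L stays unbiased", {
  # known propensities, deliberately wrong constant augmentation functions
  set.seed(17)
  reps <- 300; n <- 400
  est <- numeric(reps)
  truth <- true_regime_values(cp_scenario, cp_design)
  for (r in seq_len(reps)) {
    x1 <- draw_baseline(n, cp_scenario)
    g <- sample.int(8, n, TRUE)
    a1 <- cp_design$regimes$a1[g]
    tr <- transition_stage2(x1, a1, cp_scenario)
    a2 <- as.integer(regime_stage2_action(cp_design, g, tr$X22))
    y <- draw_outcome(x1, a1, tr$X21, a2, cp_scenario)
    pr <- regime_propensities(cp_design, matrix(1 / 8, n, 8), tr$X22,
                              "upfront")
    c1 <- regime_consistency(cp_design, a1, through_stage = 1L)
    c2 <- regime_consistency(cp_design, a1, tr$X22, a2)
    e <- waipw_estimate(y, c1[, 8], c2[, 8], pr$pi1[, 8], pr$pi2[, 8],
                        L1 = 4.2, L2 = -1.3)
    est[r] <- e$theta
  }
  expect_lt(abs(mean(est) - truth$theta[8]),
            3 * sd(est) / sqrt(reps))
})

test_that("augmentation reduces variance when models are informative", {
  # estimator-level property with the true outcome model supplying L
  set.seed(27)
  reps <- 300; n <- 400
  truth <- true_regime_values(cp_scenario, cp_design)
  b2 <- c(cp_scenario$offset, 0.3, -0.75, 0.6, -0.25, -0.75, -0.75, -0.85)
  e_ipw <- e_aipw <- numeric(reps)
  for (r in seq_len(reps)) {
    x1 <- draw_baseline(n, cp_scenario)
    g <- sample.int(8, n, TRUE)
    a1 <- cp_design$regimes$a1[g]
    tr <- transition_stage2(x1, a1, cp_scenario)
    a2 <- as.integer(regime_stage2_action(cp_design, g, tr$X22))
    y <- draw_outcome(x1, a1, tr$X21, a2, cp_scenario)
    pr <- regime_propensities(cp_design, matrix(1 / 8, n, 8), tr$X22,
                              "upfront")
    c1 <- regime_consistency(cp_design, a1, through_stage = 1L)
    c2 <- regime_consistency(cp_design, a1, tr$X22, a2)
    l2 <- as.numeric(smartrar:::q2_features(x1, rep(1, n), tr$X21,
                                            rep(4, n)) %*% b2)
    l1 <- rep(truth$theta[8], n)
    e_ipw[r] <- wipw_estimate(y, c2[, 8], pr$pi1[, 8], pr$pi2[, 8])$theta
    e_aipw[r] <- waipw_estimate(y, c1[, 8], c2[, 8], pr$pi1[, 8],
                                pr$pi2[, 8], L1 = l1, L2 = l2)$theta
  }
  expect_lt(var(e_aipw), var(e_ipw))
  expect_lt(abs(mean(e_aipw) - truth$theta[8]), 3 * sd(e_aipw) / sqrt(reps))
})

test_that("martingale inference matches closed-form arithmetic", {
  M <- rep(c(1, -1), 50)
  out <- mestimation_inference(theta = 0, M = M, dM = rep(-1, 100),
                               alpha = 0.05)
  expect_equal(out$se, 0.1)
  expect_equal(out$ci_hi - out$theta, qnorm(0.975) * 0.1)
  expect_equal(out$ub - out$theta, qnorm(0.95) * 0.1)
  expect_error(mestimation_inference(0, M = 1, dM = -1, n_consistent = 1L),
               "at least 2")
  expect_error(mestimation_inference(0, M = rep(0, 5), dM = rep(-1, 5)),
               "degenerate-variance")
})

test_that("joint covariance diagonal equals the squared standard errors", {
  set.seed(8)
  M <- matrix(rnorm(200 * 3), 200, 3)
  delta <- c(-1, -0.5, -2)
  S <- joint_confidence_covariance(M, delta)
  for (j in 1:3) {
    se <- sqrt(mean(M[, j]^2)) / (abs(delta[j]) * sqrt(200))
    expect_equal(S[j, j], se^2)
  }
  # regimes with disjoint consistency sets have exactly zero covariance
  M2 <- cbind(c(rnorm(100), rep(0, 100)), c(rep(0, 100), rnorm(100)))
  expect_equal(joint_confidence_covariance(M2, c(-1, -1))[1, 2], 0)
})

test_that("regimes sharing a responder path are positively correlated", {
  set.seed(37)
  reps <- 200; n <- 300
  th7 <- th8 <- numeric(reps)
  for (r in seq_len(reps)) {
    x1 <- draw_baseline(n, cp_scenario)
    g <- sample.int(8, n, TRUE)
    a1 <- cp_design$regimes$a1[g]
    tr <- transition_stage2(x1, a1, cp_scenario)
    a2 <- as.integer(regime_stage2_action(cp_design, g, tr$X22))
    y <- draw_outcome(x1, a1, tr$X21, a2, cp_scenario)
    pr <- regime_propensities(cp_design, matrix(1 / 8, n, 8), tr$X22,
                              "upfront")
    c2 <- regime_consistency(cp_design, a1, tr$X22, a2)
    th7[r] <- wipw_estimate(y, c2[, 7], pr$pi1[, 7], pr$pi2[, 7])$theta
    th8[r] <- wipw_estimate(y, c2[, 8], pr$pi1[, 8], pr$pi2[, 8])$theta
  }
  expect_gt(cor(th7, th8), 0)
})
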