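test_that("stage timing follows enrollment plus the stage gaps", {
  st <- small_sr_trial()
  i <- which(st$tau == 3)[1]
  expect_equal(st$s2w[i], 9)      # stage-2 decision six weeks after entry
  expect_equal(st$compw[i], 15)   # outcome six weeks after stage 2
})

test_that("weeks without arrivals or decisions leave the ledger unchanged", {
  sc <- cancer_pain_scenario("calibrated", N = 5L)
  st <- init_trial(cp_design, sc, rar_method("sr"), 1)
  st$tau <- rep(2L, 5)                   # nobody arrives at week 1
  st$s2w <- st$tau + 6L; st$compw <- st$tau + 12L
  st1 <- advance_week(st, 1)
  for (f in c("A1", "A2", "X21", "X22", "Y", "R1", "W"))
    expect_identical(st1[[f]], st[[f]])
})

test_that("uniform randomization assigns arms at the expected rates", {
  st <- run_trial(cp_design, cp_scenario, rar_method("sr"), seed = 60)
  expect_lt(abs(mean(st$A1 == 1) - 0.5), 3 * sqrt(0.25 / st$N))
  # every regime's consistency rate is near the 0.25 forced by the design
  rates <- colMeans(st$C2m)
  expect_true(all(abs(rates - 0.25) < 3 * sqrt(0.25 * 0.75 / st$N)))
})

test_that("snapshots expose only the strict past", {
  st <- small_sr_trial()
  expect_equal(nrow(ledger_snapshot(st, 1)), 0)
  i <- which(st$tau == min(st$tau))[1]
  tcomp <- st$compw[i]
  snap_at <- ledger_snapshot(st, tcomp)      # completion week itself
  snap_after <- ledger_snapshot(st, tcomp + 1)
  expect_equal(snap_at$Delta[snap_at$subject_id == i], 0)
  expect_true(is.na(snap_at$Y[snap_at$subject_id == i]))
  expect_equal(snap_after$Delta[snap_after$subject_id == i], 1)
  expect_equal(snap_after$Y[snap_after$subject_id == i], st$Y[i])
})

test_that("snapshot counts are monotone and reconcile with a recount", {
  st <- small_sr_trial()
  prev <- c(0, 0, 0)
  for (t in seq(1, st$final_week + 1, by = 3)) {
    snap <- ledger_snapshot(st, t)
    counts <- c(nrow(snap), sum(!is.na(snap$A2)), sum(snap$Delta))
    # brute-force recount from the raw schedule
    expect_equal(counts[1], sum(st$tau <= t - 1))
    expect_equal(counts[2], sum(st$s2w <= t - 1))
    expect_equal(counts[3], sum(st$compw <= t - 1))
    expect_true(all(counts >= prev))
    expect_true(counts[1] >= counts[2] && counts[2] >= counts[3])
    prev <- counts
  }
})

test_that("stored probabilities equal the policy snapshots bitwise", {
  for (method in list(rar_method("sr", burnin_per_regime = 3L),
                      rar_method("upfront", "wipw", c_t = 1,
                                 burnin_per_regime = 3L),
                      rar_method("sequential", c_t = 1, B2 = 200L,
                                 b_outer = 8L, b_inner = 8L,
                                 burnin_per_regime = 3L))) {
    sc <- cancer_pain_scenario("calibrated", N = 150L)
    st <- run_trial(cp_design, sc, method, seed = 61)
    for (i in c(1, 50, 150)) {
      pol <- st$policy[[st$tau[i]]]
      if (method$scheme == "sequential") {
        expect_identical(st$R1[i, ], pol$policy$stage1)
        key <- paste0(st$A1[i], "_", st$X22[i])
        pol2 <- st$policy[[st$s2w[i]]]
        expect_identical(st$P2[i, ], pol2$policy$stage2[[key]])
      } else {
        expect_identical(st$R1[i, ], pol$policy$r)
      }
      expect_identical(st$W[i, ], pol$W)
    }
  }
})

test_that("identical seeds reproduce identical trials", {
  m <- rar_method("upfront", "wipw", c_t = 1, burnin_per_regime = 3L)
  sc <- cancer_pain_scenario("calibrated", N = 150L)
  a <- run_trial(cp_design, sc, m, seed = 62)
  b <- run_trial(cp_design, sc, m, seed = 62)
  expect_identical(ledger_table(a), ledger_table(b))
  expect_identical(a$policy, b$policy)
})

test_that("policy updates are reproducible from the recorded snapshots", {
  sc <- cancer_pain_scenario("calibrated", N = 200L)
  m <- rar_method("upfront", "wipw", c_t = 1, burnin_per_regime = 3L)
  st <- run_trial(cp_design, sc, m, seed = 63)
  adaptive <- which(vapply(st$policy, function(p) !p$burnin, logical(1)))
  expect_gt(length(adaptive), 0)
  for (t in adaptive[c(1, length(adaptive))]) {
    redo <- update_upfront_policy(st, t)
    expect_identical(redo$r, st$policy[[t]]$policy$r)
  }
  ms <- rar_method("sequential", c_t = 1, B2 = 200L, b_outer = 8L,
                   b_inner = 8L, burnin_per_regime = 3L)
  st2 <- run_trial(cp_design, sc, ms, seed = 63)
  adaptive2 <- which(vapply(st2$policy, function(p) !p$burnin, logical(1)))
  t <- adaptive2[length(adaptive2)]
  redo2 <- update_sequential_policy(st2, t)
  expect_identical(redo2$stage1, st2$policy[[t]]$policy$stage1)
  expect_identical(redo2$stage2, st2$policy[[t]]$policy$stage2)
})

test_that("methods share subject streams under a common seed", {
  sc <- cancer_pain_scenario("calibrated", N = 100L)
  a <- run_trial(cp_design, sc, rar_method("sr"), seed = 64)
  b <- run_trial(cp_design, sc, rar_method("sequential"), seed = 64)
  expect_identical(a$tau, b$tau)
  expect_identical(a$X1, b$X1)
  expect_identical(a$e1, b$e1)
  expect_identical(a$e2, b$e2)
})

test_that("weights are one through burn-in and recomputable afterwards", {
  sc <- cancer_pain_scenario("calibrated", N = 300L)
  m <- rar_method("upfront", "wipw", c_t = 1, burnin_per_regime = 5L)
  st <- run_trial(cp_design, sc, m, seed = 65)
  expect_false(is.na(st$t_star))
  for (t in seq_len(st$t_star)) {
    expect_identical(st$policy[[t]]$W, rep(1, 8))
  }
  post <- st$t_star + 2
  if (post <= length(st$policy)) {
    redo <- update_stabilizing_weights(st, post)
    expect_identical(redo$W, st$policy[[post]]$W)
    expect_true(all(redo$W > 0))
  }
})

test_that("dominant regimes drive the policy to the clipping bound", {
  # one regime better by a wide margin: its probability reaches the
  # post-normalization ceiling, all others stay at the floor
  sc <- scenario_params(c(0, 0.9, -1.5),
                        c(0, 0.3, -0.75, 0.6, 10, 10, 10, -10),
                        resp_threshold = 0.9, direction = "min", N = 600L)
  m <- rar_method("upfront", "ipw", c_t = 1, burnin_per_regime = 5L)
  st <- run_trial(cp_design, sc, m, seed = 66)
  last <- st$policy[[st$horizon]]
  expect_false(last$burnin)
  r <- last$policy$r
  expect_equal(which.max(r), 8)
  expect_equal(r[8], 0.95 / (0.95 + 7 * 0.05))
  expect_true(all(abs(r[1:7] - 0.05 / 1.3) < 1e-10))
})

test_that("burn-in never completes when the threshold is unreachable", {
  sc <- cancer_pain_scenario("calibrated", N = 8L)
  st <- run_trial(cp_design, sc, rar_method("upfront", "wipw"), seed = 67)
  expect_true(is.na(st$t_star))
  for (p in st$policy) {
    expect_true(p$burnin)
    expect_identical(p$policy$r, rep(1 / 8, 8))
    expect_identical(p$W, rep(1, 8))
  }
})
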