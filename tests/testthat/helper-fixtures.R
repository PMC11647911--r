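# Shared fixtures built in code.

cp_design <- cancer_pain_design()
cp_scenario <- cancer_pain_scenario("calibrated")

# A degenerate one-regime design: one option at each decision point.
one_regime_design <- function() {
  feas <- data.frame(a1 = c(0L, 0L), response = c(1L, 0L))
  feas$options <- list(0L, 0L)
  smart_design(stage1_options = 0L, feasible = feas)
}

# Two stage-1 arms, two responder x two nonresponder options each.
generic_2x2x2_design <- function() {
  feas <- data.frame(a1 = c(0L, 0L, 1L, 1L), response = c(1L, 0L, 1L, 0L))
  feas$options <- list(c(10L, 11L), c(12L, 13L), c(20L, 21L), c(22L, 23L))
  smart_design(stage1_options = c(0L, 1L), feasible = feas)
}

# Small completed SR trial reused across tests (N = 120 keeps it fast; the
# burn-in threshold is lowered so adaptive machinery is exercised).
small_sr_trial <- function(seed = 404, N = 120L) {
  sc <- cancer_pain_scenario("calibrated", N = N)
  run_trial(cp_design, sc, rar_method("sr", burnin_per_regime = 3L), seed)
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  mean((x - mean(x))^3) / stats::sd(x)^3
}
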