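---
title: "Response-adaptive randomization for SMARTs: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-adaptive randomization for SMARTs: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartrar)
```

## The problem

A sequential multiple assignment randomized trial (SMART) randomizes each
subject at two or more decision points, with later option sets depending on
interim response.  A two-stage SMART with two stage-1 arms and two feasible
stage-2 options per (arm, response) pair embeds eight treatment regimes
$(a, b, c)$: give $a$ at stage 1, then $b$ to responders and $c$ to
nonresponders.  The estimand for regime $d$ is its value
$\mathcal V(d) = E\{Y^*(d)\}$, the mean outcome if the whole population
followed $d$.

`smartrar` implements response-adaptive randomization (RAR) for such trials
by Thompson sampling, in two forms:

* **up-front**: each enrollee is randomized once among the $m$ embedded
  regimes, with probabilities $r_t^j$ refreshed weekly from the accrued
  data, and
* **sequential**: each stage is randomized separately, with the stage-2
  probabilities specific to the four (stage-1 arm, response) groups, driven
  by Q-learning.

Because data collected under RAR are not i.i.d., the package also provides
weighted inverse probability weighted (WIPW) and weighted augmented IPW
(WAIPW) value estimators whose variance-stabilizing weights restore
asymptotic normality via the martingale central limit theorem, so that the
usual normal-theory intervals remain valid after an adaptive trial.

## Accrual, progression, and information sets

Time is measured in integer weeks.  A subject enrolling at week $\tau$ is
randomized at stage 1 immediately, reaches the stage-2 decision at
$\tau + g$ and completes follow-up (outcome $Y$ observed) at $\tau + 2g$,
with $g$ the `stage_gap_weeks` (default 6).  The policy update at week $t$
may use only the *strict past*: subjects whose data were complete by week
$t - 1$.  A completion at week $t$ therefore first informs the week
$t + 1$ update.  `ledger_snapshot()` materializes exactly this information
set, and the test suite checks that no update ever uses anything newer.

Three independent seeded streams drive a trial: (1) arrivals and potential
data (enrollment weeks, baseline scores, transition and outcome noise),
(2) assignment uniforms, (3) Thompson-sampling draws.  Methods compared
under a common seed therefore face identical subject populations.  The
Thompson stream is re-seeded deterministically each week from the trial
seed, which makes any recorded policy update exactly reproducible from the
corresponding snapshot (`update_upfront_policy()`,
`update_sequential_policy()`).

## Thompson sampling over confidence distributions

At week $t$ the up-front scheme computes value estimates
$\hat\theta_t = (\hat\theta^1_t, \ldots, \hat\theta^m_t)$ with the
configured estimator, takes their estimated asymptotic normal law (the
stacked-estimating-equation sandwich, with weights treated as fixed) as a
frequentist confidence distribution, and draws $B$ samples from it
(default $B = 1000$).  The belief $\hat\rho^j_t$ is the fraction of draws
in which regime $j$ attains the optimum; ties within a draw are split
equally so that exact-null configurations give symmetric beliefs.
Randomization probabilities are

$$r^j_t = \frac{(\hat\rho^j_t)^{c_t}}{\sum_v (\hat\rho^v_t)^{c_t}},$$

where the damping constant $c_t \in [0, 1]$ tempers adaptation
($c_t = 0$ is uniform randomization, $c_t = 1$ full probability matching;
the package supports constant schedules, the only ones it validates).
Clipping bounds (defaults 0.05 and 0.95) are then applied entrywise and
the vector is renormalized **once**; after this single pass an entry can
sit slightly below the floor, which we accept because strict positivity —
the property the propensity theory needs — still holds, and the stored
per-subject probabilities are always the final vector actually used.
A belief of zero raised to the power zero is taken as 1, the correct
$c_t \to 0$ limit.

Adaptation begins only after a burn-in: the default rule waits until every
embedded regime has at least 25 completed subjects whose treatment
experience is consistent with it.  Until then randomization is uniform and
all stabilizing weights equal 1.

## Sequential randomization via Q-learning

The sequential scheme fits the stage-2 linear model
$Q_2(x_1, a_1, x_{21}, a_2; \beta_2)$ on completers by least squares, with
covariance $\hat\Sigma_2 = \hat\sigma^2_2 (\Phi'\Phi)^{-1}$ and residual
variance computed with divisor $N_t$ (the completer count).  Because the
stage-1 coefficient estimator plugs in an *optimized* stage-2 fit, it is
nonregular, and a single plug-in normal law would understate its
uncertainty.  The package therefore uses nested projection-style draws:
$b_2$ outer draws of $\beta_2$; for each, pseudo outcomes
$\tilde V = \mathrm{opt}_{a_2 \in \Psi_2} Q_2$ are rebuilt and the stage-1
model refit, and $b_1$ inner draws are taken from the conditional normal,
pooling $b_2 \times b_1$ stage-1 draws (defaults $32 \times 32 = 1024$;
stage-2 pool $B_2 = 1000$).  Single-option feasible sets carry the
observed outcome back in place of the pseudo outcome.

Beliefs are evaluated per subject, but under the shipped feature maps —
no treatment-by-covariate interactions — the optimizer depends on the
history only through the components that determine the feasible set, so
all subjects in the same (arm, response) group share one probability
vector; this matches the four-group implementation the design calls for
and makes the per-subject and configuration-maximizing constructions
coincide.  Each group's two-option vector is damped, clipped, and
normalized exactly as above (for two options the clip-and-normalize pass
is exact).

## Value estimation and post-trial inference

For regime $j$, the stage propensities of a subject randomized at week
$\tau$ are read off the stored week-$\tau$ vectors: up-front,
$\pi^j_1 = \sum_{v \sim j} r^v_\tau$ summed over regimes sharing the
stage-1 arm, and $\pi^j_2$ the conditional probability of regimes also
agreeing with $j$'s stage-2 action for the subject's observed response
status; sequentially, the stored per-option group probabilities.  The WIPW
estimator is the ratio form

$$\hat\theta^j = \frac{\sum_i W_{\tau_i} \Delta_i C^j_i Y_i / \Pi^j_i}
                      {\sum_i W_{\tau_i} \Delta_i C^j_i / \Pi^j_i},$$

and the WAIPW estimator normalizes by $\sum_i W^A_{\tau_i} \Delta_i$ and
adds the telescoping augmentation sum with stagewise consistency
indicators and functions $L^j_k$.  The $L^j_k$ are fitted by the backward
recursion — a shared stage-2 outcome model, then regime-specific stage-1
regressions of plugged-in pseudo outcomes on $(1, x_1, a_1, x_1 a_1)$ —
**on each subject's own enrollment-week snapshot**, cached once per week.
This keeps every estimating-function term conditionally unbiased given the
past, which is what the martingale argument needs.  The price is that
subjects enrolled before the first completions have no model to evaluate
and get $L \equiv 0$; their augmented terms then reduce to unnormalized
Horvitz–Thompson contributions, which raises the augmented estimators'
variance relative to a hindsight fit.  We accept this deliberately:
validity of inference, not efficiency, is the design goal, and the
estimator-level variance reduction of augmentation is verified in the test
suite with externally supplied models.

Standard errors come from the estimating-function representation: with
$\delta_T$ the mean derivative and $\sigma_T^2$ the mean squared term at
the estimate, $\mathrm{se} = \sigma_T / (|\delta_T| \sqrt T)$, giving
two-sided intervals and one-sided bounds.  The joint covariance across
regimes (used for the confidence draws) is the per-subject outer-product
sandwich; regimes sharing consistent subjects are positively correlated.

### Variance-stabilizing weights

The weights hold the conditional second moment of the estimating function
constant over time.  Writing $\mu^{j(s)}$ for the response-stratum
components of that moment, the plug-in

$$\hat\Xi^j_t = \sum_{s = 0, 1}
  \frac{\hat\mu^{j(s)}_t}{\pi^{j(s)}_{t,2}\, \pi^j_{t,1}}$$

estimates it under the **current** week's probabilities, with
$\hat\mu^{j(s)}_t$ an inverse-propensity-weighted average of squared
residuals around the unweighted IPW estimate (each subject weighted by its
own stored assignment-week propensities).  An anchor $\hat\Xi^j_{t^*}$ is
frozen at the end of burn-in and $W^j_t = (\hat\Xi^j_{t^*}/\hat\Xi^j_t)^{1/2}$
thereafter; during burn-in $W \equiv 1$.  Two package-level decisions fill
gaps the theory leaves open:

* **WAIPW weights.**  The analogous construction replaces the squared IPW
  residuals with squared *augmented* residuals (the full estimating
  integrand minus the reference estimate), same stratification, anchoring,
  and square-root-ratio form.  This is a faithful analog rather than a
  derived formula, and it is validated only through the properties it must
  deliver (conditional unbiasedness, flat conditional second moment,
  near-normality, coverage).
* **Sequential-scheme weights.**  $\hat\mu$ uses realized per-subject
  product propensities; $\hat\Xi$ recombines with the current group
  probabilities.
* **Empty strata.**  If a regime has no consistent completer in some
  response stratum, its weight holds its previous value; a regime whose
  anchor cannot yet be computed keeps $W = 1$ and is anchored at the first
  week both strata are populated.

## The synthetic scenario and its calibration

The generator is linear-Gaussian: baseline score $X_1 \sim N(5, 1)$;
interim score $X_{21} = 0.9 X_1 - 1.5 A_1 + \varepsilon_1$; outcome
$Y = \mathrm{offset} + 0.3 X_1 - 0.75 A_1 + 0.6 X_{21} + \mathrm{eff}(A_2)
+ \varepsilon_2$ with unit noise SDs and stage-2 effects
$(-0.25, -0.75, -0.75, -0.85)$ for codes $1$, $\{2,5\}$, $3$, $4$.  Lower
outcomes (greater pain reduction) are favorable, so all optimizations in
the package consume a `direction` parameter rather than assuming
larger-is-better.

The commonly quoted form of this scenario carries a response rule
$X_{22} = I(X_{21} < 0.7 X_1)$ and no outcome offset, but those choices
are inconsistent with the published regime-value vector
$(-0.126, \ldots, -2.501)$: they imply a response probability of about
0.163 on arm 0, whereas the value vector forces $p_0 = 0.5$,
$p_1 \approx 0.93$, and a common additive offset of about $-4.201$
(`calibrate_scenario()` solves these from the value contrasts of regimes
1, 4, 5, 6 and cross-checks the offset across both arms).  The solved
probabilities are exactly the normal-CDF probabilities $\Phi(0)$ and
$\Phi(1.5)$ obtained when the response threshold equals the interim-score
slope 0.9 — i.e. response is the event
$\varepsilon_1 < -\gamma_{1,2} A_1$ — so the package ships that rule, with
offset $-4.201$, as the `"calibrated"` preset, and keeps the quoted form
as `"as_printed"`.  All replication work uses the calibrated preset; its
closed-form values match the published vector within $0.002$.

What the generator does *not* emulate: dropout, missed or shifted visits,
covariate-dependent accrual, treatment-effect heterogeneity beyond the
additive stage-2 effects, and non-Gaussian outcomes.  Tests passing under
this generator certify the algorithms and their inferential properties
under the stated model, not robustness to those real-data features.

## Timing structure and what it caps

Under the default trial shape — $N = 1000$ enrolled uniformly over weeks
1–24, six-week stage gaps — the first outcomes are observed at week 13 and
can inform policy at week 14 at the earliest; the 25-per-regime burn-in
typically ends around week 15–17.  Only subjects enrolling after burn-in
can receive adaptive stage-1 randomization, i.e. roughly the final third
of enrollment.  With eight regimes and a 0.05 clip floor, the
post-normalization probability of stage-1 arm 1 can never exceed
$1.1/1.3 \approx 0.846$ (up-front) or $0.95$ (sequential), so the in-trial
proportion on the optimal arm is bounded by about $0.66$ (up-front) and
$0.71$ (sequential) *no matter how fast beliefs concentrate*.  Published
figures near $0.78$–$0.79$ for this configuration are attainable only if
the accrual window is long relative to the outcome delay; under the stated
24-week window the package's replication harness reports the values the
design actually admits, and the bound above explains the gap.  The
sequential scheme narrows it somewhat because mid-trial enrollees still
get adaptive stage-2 randomization.

## Numerical choices

* Ridge $10^{-8}$ on all normal-equation matrices; variance floor
  $10^{-12}$ on $\sigma_T^2$; jitter $10^{-10}$ before Cholesky
  factorization of confidence covariances, with an eigenvalue fallback
  that rejects genuinely indefinite matrices.
* Augmentation fits require at least 10 completers; below that the week is
  flagged and $L \equiv 0$ is used for its enrollees.
* A regime with an undefined estimate (no consistent completers) makes the
  policy update hold the previous randomization vector; post-trial it
  yields missing entries excluded from the optimal-regime argmin.
* Degenerate inputs: zero noise SDs are rejected at construction; an
  all-zero belief vector damps to uniform; exact ties in draws are split
  equally.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the simple-randomization
operating characteristics at 1000 replications of $N = 1000$, the up-front
adaptive scheme at 200–1000 replications, and the sequential scheme at 200
replications, all single-threaded; these sizes give Monte Carlo standard
errors a few times smaller than the tolerances being checked while keeping
a full run in the minutes range.  The full published tables used 5000
replications; `run_study()` accepts any `reps` for users who want them.

## Known limitations

* The engine is concrete for two-stage designs with a binary response
  tailoring variable; the types generalize, the engine does not (a
  three-stage trial needs a third transition model and a deeper projection
  recursion, which `projection_draws()` documents but does not implement).
* Interim-data (partially observed subject) estimators are out of scope;
  randomization updates use completers only.
* Damping schedules increasing in $t$ are accepted but unvalidated.
* Update cadences other than weekly are exposed via `update_period` but
  only the weekly cadence is exercised by the shipped checks.
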