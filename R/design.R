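#' Construct a two-stage SMART design
#'
#' A sequential multiple assignment randomized trial (SMART) is described by
#' its per-stage treatment sets, a feasibility map giving the subset of
#' stage-2 options available to a subject with a given stage-1 treatment and
#' response status, the spacing (in weeks) between decision points, and the
#' list of embedded regimes.  An embedded regime is a triple `(a, b, c)`:
#' give `a` at stage 1; if the subject responds give `b`, otherwise give `c`.
#'
#' The engine, estimators, and randomization algorithms in this package
#' target the two-stage case with a binary response tailoring variable; the
#' representation (decision tables keyed by the feasibility-determining
#' history) is the standard one for this class of designs.
#'
#' @param stage1_options integer vector of stage-1 treatment codes.
#' @param feasible data frame with columns `a1`, `response` (0/1) and a
#'   list-column `options` of feasible stage-2 treatment codes.
#' @param stage_gap_weeks weeks between an assignment and the next decision
#'   point (and between the final assignment and outcome ascertainment).
#' @param regimes optional data frame with columns `a1`, `responder`,
#'   `nonresponder` fixing the embedded regimes and their order.  When `NULL`
#'   the regimes are enumerated as the cross product of stage-1 options with
#'   feasible responder and nonresponder options (ascending order).
#'
#' @return An object of class `smart_design`.
#' @seealso [cancer_pain_design()] for the eight-regime behavioral pain
#'   management design used throughout the package documentation.
#' @export
smart_design <- function(stage1_options, feasible, stage_gap_weeks = 6L,
                         regimes = NULL) {
  stopifnot(is.numeric(stage1_options), length(stage1_options) >= 1)
  if (stage_gap_weeks <= 0) stop("stage_gap_weeks must be positive")
  if (!all(c("a1", "response", "options") %in% names(feasible))) {
    stop("feasible must have columns a1, response, options")
  }
  if (any(lengths(feasible$options) == 0)) {
    stop("configuration error: empty feasible set")
  }
  if (is.null(regimes)) {
    regimes <- enumerate_regime_table(stage1_options, feasible)
  }
  des <- structure(list(
    K = 2L,
    stage1_options = as.integer(stage1_options),
    feasible = feasible,
    stage_gap_weeks = as.integer(stage_gap_weeks),
    regimes = regimes
  ), class = "smart_design")
  validate_design(des)
  des
}

enumerate_regime_table <- function(stage1_options, feasible) {
  rows <- list()
  for (a in sort(stage1_options)) {
    br <- feasible_lookup(feasible, a, 1L)
    bn <- feasible_lookup(feasible, a, 0L)
    for (b in sort(br)) for (cc in sort(bn)) {
      rows[[length(rows) + 1L]] <- c(a1 = a, responder = b, nonresponder = cc)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$id <- seq_len(nrow(out))
  out[c("id", "a1", "responder", "nonresponder")]
}

feasible_lookup <- function(feasible, a1, response) {
  hit <- which(feasible$a1 == a1 & feasible$response == response)
  if (length(hit) != 1) {
    stop("configuration error: unknown history (a1=", a1,
         ", response=", response, ")")
  }
  feasible$options[[hit]]
}

validate_design <- function(design) {
  reg <- design$regimes
  for (i in seq_len(nrow(reg))) {
    if (!reg$a1[i] %in% design$stage1_options) {
      stop("regime ", i, ": stage-1 treatment not in stage-1 option set")
    }
    if (!reg$responder[i] %in% feasible_lookup(design$feasible, reg$a1[i], 1L)) {
      stop("regime ", i, ": responder treatment not feasible")
    }
    if (!reg$nonresponder[i] %in% feasible_lookup(design$feasible, reg$a1[i], 0L)) {
      stop("regime ", i, ": nonresponder treatment not feasible")
    }
  }
  invisible(design)
}

#' The behavioral cancer pain management SMART design
#'
#' Two stage-1 interventions (0 = brief pain coping skills training, 1 = the
#' full program); at the end of stage 1 subjects are classified as responders
#' or nonresponders and re-randomized between two feasible stage-2 options
#' that depend on the stage-1 arm and response status.  The eight embedded
#' regimes, in their conventional order, are
#' (0,0,1), (0,0,2), (0,1,2), (0,1,1), (1,3,4), (1,3,5), (1,4,5), (1,4,4).
#'
#' Stage-2 codes: 0 = no further intervention after the brief program,
#' 1 = maintenance of the brief program, 2 = the full program, 3 = no further
#' intervention after the full program, 4 = maintenance of the full program,
#' 5 = an augmented program.
#'
#' @param stage_gap_weeks weeks between decision points (default 6).
#' @return A `smart_design` with eight embedded regimes.
#' @export
cancer_pain_design <- function(stage_gap_weeks = 6L) {
  feas <- data.frame(a1 = c(0L, 0L, 1L, 1L), response = c(1L, 0L, 1L, 0L))
  feas$options <- list(c(0L, 1L), c(1L, 2L), c(3L, 4L), c(4L, 5L))
  reg <- data.frame(
    id = 1:8,
    a1 = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
    responder = c(0L, 0L, 1L, 1L, 3L, 3L, 4L, 4L),
    nonresponder = c(1L, 2L, 2L, 1L, 4L, 5L, 5L, 4L)
  )
  smart_design(stage1_options = c(0L, 1L), feasible = feas,
               stage_gap_weeks = stage_gap_weeks, regimes = reg)
}

#' Enumerate the embedded regimes of a SMART design
#'
#' @param design a [smart_design()].
#' @return Data frame with one row per embedded regime: `id`, `a1`
#'   (stage-1 treatment), `responder` and `nonresponder` (stage-2
#'   treatments).
#' @export
enumerate_embedded_regimes <- function(design) {
  stopifnot(inherits(design, "smart_design"))
  design$regimes
}

#' Feasible treatment options for a given history
#'
#' Returns the subset of treatments available at stage `k` to a subject
#' whose feasibility-determining history is (`a1`, `response`).  At stage 1
#' the history is empty and the full stage-1 option set is returned.
#'
#' @param design a [smart_design()].
#' @param k stage (1 or 2).
#' @param a1 stage-1 treatment (required for `k = 2`).
#' @param response response indicator 0/1 (required for `k = 2`).
#' @return Integer vector of feasible treatment codes.
#' @export
feasible_set <- function(design, k, a1 = NULL, response = NULL) {
  stopifnot(inherits(design, "smart_design"))
  if (k == 1) return(design$stage1_options)
  if (k != 2) stop("configuration error: stage must be 1 or 2")
  if (is.null(a1) || is.null(response)) {
    stop("configuration error: stage-2 feasibility needs a1 and response")
  }
  feasible_lookup(design$feasible, a1, as.integer(response))
}

#' Regime-recommended stage-2 treatment
#'
#' @param design a `smart_design`.
#' @param j regime index.
#' @param response response indicator (vectorized).
#' @return stage-2 treatment code(s) recommended by regime `j`.
#' @export
regime_stage2_action <- function(design, j, response) {
  reg <- design$regimes
  ifelse(response == 1, reg$responder[j], reg$nonresponder[j])
}

#' @export
print.smart_design <- function(x, ...) {
  cat("SMART design:", x$K, "stages,", nrow(x$regimes), "embedded regimes,",
      "stage gap", x$stage_gap_weeks, "weeks\n")
  print(x$regimes, row.names = FALSE)
  invisible(x)
}

# Internal: m x m stage-1 / stage-2 agreement matrices used for up-front
# propensities.  S1[v, j] = regimes v and j share the stage-1 treatment;
# AB (AC) additionally require the same responder (nonresponder) action.
design_agreement <- function(design) {
  reg <- design$regimes
  s1 <- outer(reg$a1, reg$a1, "==")
  list(
    S1 = s1 * 1,
    AB = (s1 & outer(reg$responder, reg$responder, "==")) * 1,
    AC = (s1 & outer(reg$nonresponder, reg$nonresponder, "==")) * 1
  )
}

#' Regime consistency indicators
#'
#' The consistency indicator for regime `j` is 1 when a subject's realized
#' treatments agree with the regime's recommendations at every stage reached,
#' given the subject's own response status.  Through stage 0 the indicator is
#' identically 1.
#'
#' @param design a `smart_design`.
#' @param A1,X22,A2 realized stage-1 treatment, response status, stage-2
#'   treatment (vectors; `X22`/`A2` may be `NA` for subjects who have not
#'   reached stage 2 when `through_stage = 1`).
#' @param j regime index (scalar) or `NULL` for all regimes.
#' @param through_stage compute consistency through this stage (0, 1 or 2).
#' @return If `j` is scalar, a 0/1 vector; otherwise an n x m matrix.
#' @export
regime_consistency <- function(design, A1, X22 = NULL, A2 = NULL, j = NULL,
                               through_stage = 2L) {
  reg <- design$regimes
  m <- nrow(reg)
  n <- length(A1)
  if (through_stage == 0L) {
    out <- matrix(1, n, m)
  } else {
    c1 <- outer(A1, reg$a1, "==") * 1
    if (through_stage == 1L) {
      out <- c1
    } else {
      if (is.null(X22) || is.null(A2)) {
        stop("precondition error: stage-2 data required for through_stage = 2")
      }
      if (anyNA(X22) || anyNA(A2)) {
        stop("precondition error: record has not reached stage 2")
      }
      target <- ifelse(outer(X22, rep(1, m)) == 1,
                       outer(rep(1, n), reg$responder),
                       outer(rep(1, n), reg$nonresponder))
      out <- c1 * (outer(A2, rep(1, m)) == target)
    }
  }
  if (!is.null(j)) out[, j] else out
}
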