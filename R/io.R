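#' Export a trial ledger to CSV
#'
#' Writes the flat per-subject [ledger_table()] (realized data, stored
#' assignment-week probabilities, propensities, weights, augmentation
#' evaluations).  The file round-trips through [read_ledger_csv()] into
#' [value_estimates()].
#'
#' @param state a `smart_trial` (or a data frame already in ledger-table
#'   layout).
#' @param path output file.
#' @export
write_ledger_csv <- function(state, path) {
  tbl <- if (is.data.frame(state)) state else ledger_table(state)
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger_csv
#' @return `read_ledger_csv` returns the ledger data frame.
#' @export
read_ledger_csv <- function(path) {
  utils::read.csv(path)
}

#' Export the weekly policy log to CSV
#'
#' One row per week x group x option with the randomization probability in
#' force, the burn-in flag, and the variance-stabilizing weight.
#'
#' @param state a `smart_trial`.
#' @param path output file.
#' @export
write_policy_log <- function(state, path) {
  rows <- list()
  for (p in state$policy) {
    if (is.null(p)) next
    if (state$method$scheme == "sequential") {
      grids <- c(list(stage1 = p$policy$stage1), p$policy$stage2)
      for (g in names(grids)) {
        v <- grids[[g]]
        rows[[length(rows) + 1L]] <- data.frame(
          week = p$week, scheme = p$scheme, group = g,
          option = seq_along(v), probability = v,
          burnin = p$burnin, weight = NA_real_)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        week = p$week, scheme = p$scheme, group = "regimes",
        option = seq_along(p$policy$r), probability = p$policy$r,
        burnin = p$burnin, weight = p$W)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Study configuration as a single JSON document
#'
#' Serializes (and restores) a design/scenario/method configuration.  The
#' shipped preset `"cancer_pain"` carries all defaults of the package's
#' replication scenario.
#'
#' @param scenario a `scenario_params`.
#' @param method a `rar_method`.
#' @param path output file.
#' @export
write_config_json <- function(scenario, method, path) {
  cfg <- list(scenario = unclass(scenario), method = unclass(method))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @return `read_config_json` returns a list with `scenario` and `method`
#'   objects reconstructed from the file.
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- cfg$scenario
  scenario <- scenario_params(
    s$gamma1, s$gamma2, s$x1_mean, s$x1_sd, s$e1_sd, s$e2_sd,
    s$resp_threshold, s$offset, s$direction, s$N, s$accrual_weeks,
    s$stage_gap_weeks)
  mt <- cfg$method
  method <- rar_method(mt$scheme, mt$estimator, mt$c_t, unlist(mt$clip),
                       mt$B, mt$B2, mt$b_outer, mt$b_inner,
                       mt$burnin_per_regime, mt$update_period)
  list(scenario = scenario, method = method)
}

#' Named configuration presets
#'
#' @param name preset name; `"cancer_pain"` returns the calibrated
#'   replication scenario with the default up-front method settings.
#' @return List with `design`, `scenario`, `method`.
#' @export
preset_config <- function(name = "cancer_pain") {
  if (name != "cancer_pain") stop("unknown preset: ", name)
  list(design = cancer_pain_design(),
       scenario = cancer_pain_scenario("calibrated"),
       method = rar_method("upfront", "wipw", c_t = 1))
}
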