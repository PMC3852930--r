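# Threshold-scenario excess morbidity: the log-linear excess-risk model
# applied cell by cell to the gridded exposure. E = E0 * exp(beta * (C -
# C0)) is the rate at concentration C given baseline rate E0 at the
# threshold C0; excess cases are N = P * E * (1 - exp(-beta * (C - C0))),
# algebraically equal to P * E0 * (exp(beta * (C - C0)) - 1).

#' Default threshold scenarios
#'
#' Zero (no safe-level assumption), the WHO annual guideline of 20 ug/m^3,
#' and the Chinese national first-class standard of 50 ug/m^3.
#'
#' @return Data frame with `label` and `c0` (ug/m^3).
#' @export
default_scenarios <- function() {
  data.frame(label = c("zero", "WHO", "National first-class standard"),
             c0 = c(0, 20, 50), stringsAsFactors = FALSE)
}

#' Health-effect rate at a concentration
#'
#' `E = E0 * exp(beta * (C - C0))`.
#'
#' @param e0 Baseline rate at the threshold concentration (> 0), in
#'   whatever per-person-per-period unit the caller uses.
#' @param beta Exposure-response coefficient, per ug/m^3.
#' @param c Concentration, ug/m^3.
#' @param c0 Threshold concentration, ug/m^3.
#' @return The rate at `c`, same units as `e0`.
#' @export
excess_effect_rate <- function(e0, beta, c, c0) {
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  e0 * exp(beta * (c - c0))
}

#' Excess cases attributable to concentrations above a threshold
#'
#' `N = P * E * (1 - 1/exp(beta * (C - C0)))` with `E` from
#' [excess_effect_rate()]. Concentrations below the threshold would give
#' negative excess; they are clamped to zero (a threshold model cannot be
#' protective) and the number of clamped elements is attached as attribute
#' `"n_clamped"`.
#'
#' @param p Exposed persons, >= 0 (vectorised).
#' @param e0 Baseline rate at the threshold, > 0.
#' @param beta Exposure-response coefficient, per ug/m^3.
#' @param c Concentration, ug/m^3 (vectorised).
#' @param c0 Threshold concentration, ug/m^3.
#' @return Excess cases in the same period as `e0`.
#' @export
excess_cases <- function(p, e0, beta, c, c0) {
  if (any(p < 0)) stop("population must be >= 0", call. = FALSE)
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  dc <- c - c0
  n <- p * excess_effect_rate(e0, beta, c, c0) * (1 - 1 / exp(beta * dc))
  clamped <- beta * dc < 0
  n[clamped] <- 0
  structure(n, n_clamped = sum(clamped))
}

#' Grid-level excess-morbidity impact for one scenario
#'
#' Applies the excess-case formula to every cell of the exposure table
#' using the cell's annual-mean concentration, then aggregates the daily
#' excess to an annual total (`days` x the daily sum). Confidence bounds,
#' if `beta_ci` is supplied, propagate only the uncertainty of `beta`.
#'
#' @param table Exposure table from [overlay()].
#' @param e0 Baseline rate per person per day, > 0.
#' @param beta Exposure-response coefficient, per ug/m^3.
#' @param scenario A one-row data frame (or list) with `label` and `c0`.
#' @param days Days in the aggregation year (365, or 366 for leap years).
#' @param beta_ci Optional `c(lower, upper)` for `beta`.
#' @return An object of class `impact_result`: `scenario`, `c0`, `cases`
#'   (annual total), `cases_ci`, `per_cell` (cell_id, population,
#'   pm10_ugm3, daily_cases, annual_cases), `n_clamped`, `days`.
#' @export
per_grid_impact <- function(table, e0, beta, scenario, days = 365,
                            beta_ci = NULL) {
  if (!nrow(table)) stop("exposure table is empty", call. = FALSE)
  stop_if_not_scalar_number(e0, "e0", lower = 1e-300)
  stop_if_not_scalar_number(days, "days", lower = 1)
  daily <- excess_cases(table$population, e0, beta, table$pm10_ugm3,
                        scenario$c0)
  total <- days * sum(daily)
  ci <- if (!is.null(beta_ci)) {
    vapply(beta_ci, function(b) {
      days * sum(excess_cases(table$population, e0, b, table$pm10_ugm3,
                              scenario$c0))
    }, numeric(1))
  } else c(NA_real_, NA_real_)
  structure(list(
    scenario = scenario$label, c0 = scenario$c0,
    cases = total, cases_ci = ci,
    per_cell = data.frame(cell_id = table$cell_id,
                          population = table$population,
                          pm10_ugm3 = table$pm10_ugm3,
                          daily_cases = as.numeric(daily),
                          annual_cases = days * as.numeric(daily)),
    n_clamped = attr(daily, "n_clamped"), days = days
  ), class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("impact_result '%s' (C0 = %g ug/m3): %.1f annual cases",
              x$scenario, x$c0, x$cases))
  if (all(is.finite(x$cases_ci))) {
    cat(sprintf(" (95%% CI %.1f-%.1f)", x$cases_ci[1], x$cases_ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' Excess-morbidity impacts for a set of threshold scenarios
#'
#' @param table Exposure table from [overlay()].
#' @param e0 Baseline rate per person per day.
#' @param fit A `gam_fit` (or any list with `beta` and `ci95`).
#' @param scenarios Data frame `label`, `c0` with distinct labels.
#' @param days Days in the aggregation year.
#' @return A list of `impact_result`, one per scenario, in input order.
#' @export
scenario_suite <- function(table, e0, fit, scenarios = default_scenarios(),
                           days = 365) {
  if (!nrow(scenarios)) stop("no scenarios supplied", call. = FALSE)
  if (anyDuplicated(scenarios$label)) {
    stop("duplicate scenario labels", call. = FALSE)
  }
  lapply(seq_len(nrow(scenarios)), function(i) {
    per_grid_impact(table, e0, fit$beta, scenarios[i, , drop = FALSE],
                    days = days, beta_ci = fit$ci95)
  })
}
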