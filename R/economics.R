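# Cost-of-illness valuation of excess morbidity and its share of regional
# GDP; also the visitor-count decomposition relating observed hospital
# visits under pollution to their counterfactual clean-air level.

#' Economic valuation inputs
#'
#' @param unit_cost Treatment cost per case (> 0), default 660.
#' @param gdp Regional gross domestic product (> 0), default 3.096e9.
#' @param currency Free-text currency label.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(unit_cost = 660, gdp = 3.096e9, currency = "USD") {
  stop_if_not_scalar_number(unit_cost, "unit_cost", lower = 1e-300)
  stop_if_not_scalar_number(gdp, "gdp", lower = 1e-300)
  structure(list(unit_cost = unit_cost, gdp = gdp, currency = currency),
            class = "cost_inputs")
}

#' Cost of illness
#'
#' Excess cases times the per-case treatment cost.
#'
#' @param cases Excess cases, >= 0 (vectorised).
#' @param unit_cost Cost per case, > 0.
#' @return Total cost in the unit-cost currency.
#' @export
cost_of_illness <- function(cases, unit_cost) {
  if (any(cases < 0)) stop("cases must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(unit_cost, "unit_cost", lower = 1e-300)
  cases * unit_cost
}

#' Cost as a percentage of GDP
#'
#' @param total_cost Total cost (same currency as `gdp`).
#' @param gdp Gross domestic product, > 0.
#' @return `100 * total_cost / gdp` (percent, unrounded).
#' @export
gdp_share <- function(total_cost, gdp) {
  stop_if_not_scalar_number(gdp, "gdp", lower = 1e-300)
  100 * total_cost / gdp
}

#' Excess hospital visitors attributable to pollution
#'
#' With `fp` observed visitors under present pollution and a concentration
#' excess `delta_c` over the threshold, the counterfactual clean-air count
#' is `ft = fp / (1 + delta_c * beta)` and the pollution-attributable
#' excess is `fp * delta_c * beta / (1 + delta_c * beta)`, so that
#' `fp = ft + excess` exactly.
#'
#' @param fp Observed visitors, >= 0.
#' @param beta Exposure-response coefficient, per ug/m^3.
#' @param delta_c Concentration excess over the threshold, ug/m^3.
#' @return Excess visitors.
#' @export
excess_visitors <- function(fp, beta, delta_c) {
  if (any(fp < 0)) stop("fp must be >= 0", call. = FALSE)
  x <- delta_c * beta
  if (any(x <= -1)) stop("delta_c * beta must exceed -1", call. = FALSE)
  fp * x / (1 + x)
}

#' Counterfactual clean-air visitor count
#'
#' @inheritParams excess_visitors
#' @return `fp / (1 + delta_c * beta)`.
#' @export
clean_air_visitors <- function(fp, beta, delta_c) {
  x <- delta_c * beta
  if (any(x <= -1)) stop("delta_c * beta must exceed -1", call. = FALSE)
  fp / (1 + x)
}

#' Assemble the scenario valuation table
#'
#' One row per scenario with excess cases (rounded to 1 decimal), total
#' cost and its confidence bounds (rounded cases times unit cost, reported
#' as integers) and the GDP percentage (3 decimals). Cost bounds propagate
#' the case bounds, which themselves carry only the exposure
#' coefficient's uncertainty.
#'
#' @param impacts A list of `impact_result` from [scenario_suite()].
#' @param cost A [cost_inputs()] object.
#' @return Data frame `scenario`, `c0_ugm3`, `cases`, `cases_lo`,
#'   `cases_hi`, `unit_cost`, `total_cost`, `cost_lo`, `cost_hi`, `gdp`,
#'   `gdp_percent`.
#' @export
build_scenario_table <- function(impacts, cost) {
  if (!length(impacts)) stop("no impacts supplied", call. = FALSE)
  if (!inherits(cost, "cost_inputs")) {
    stop("missing or invalid cost inputs", call. = FALSE)
  }
  rows <- lapply(impacts, function(im) {
    cases <- round(im$cases, 1)
    lo <- round(im$cases_ci[1], 1)
    hi <- round(im$cases_ci[2], 1)
    tc <- round(cost_of_illness(cases, cost$unit_cost))
    data.frame(
      scenario = im$scenario, c0_ugm3 = im$c0,
      cases = cases, cases_lo = lo, cases_hi = hi,
      unit_cost = cost$unit_cost,
      total_cost = tc,
      cost_lo = if (is.finite(lo)) round(cost_of_illness(lo, cost$unit_cost))
                else NA_real_,
      cost_hi = if (is.finite(hi)) round(cost_of_illness(hi, cost$unit_cost))
                else NA_real_,
      gdp = cost$gdp,
      gdp_percent = round(gdp_share(tc, cost$gdp), 3),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
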