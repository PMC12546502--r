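#' Assemble the full business case
#'
#' Runs the benefit and cost engines, discounts both sides (end-of-year
#' timing), and derives the headline figures: net present value
#' (discounted benefits minus discounted costs), the break-even year (first
#' year whose own nominal net flow is non-negative — the sense in which the
#' yearly cash flow "turns positive"), the cumulative payback year (first
#' year with non-negative cumulative nominal net flow, `NA` if never
#' reached), its discounted counterpart, and per-case economics
#' (`cost_per_case`, `revenue_per_case` = yearly totals divided by that
#' year's case volume).
#'
#' @param params A one-row `lab_parameters` tibble (normally calibrated).
#' @return An object of class `business_case`: a list with elements
#'   `cashflow` (per-year tibble), `costs`, `benefits` (the two long
#'   schedules), `npv`, `npv_benefits`, `npv_costs`, `break_even_year`,
#'   `payback_year`, `payback_year_discounted`, `params`.
#' @examples
#' bc <- build_business_case(base_case_parameters())
#' round(bc$npv)
#' bc$break_even_year
#' @export
build_business_case <- function(params) {
  stopifnot(nrow(params) == 1)
  validate_lab_parameters(params)
  cases <- project_case_volume(params)
  cons <- project_consultation_volume(params)
  benefits <- build_benefit_schedule(params, cases, cons)
  costs <- build_investment_schedule(params, cases)

  by <- yearly_totals(benefits)
  cy <- yearly_totals(costs)
  if (any(cases$cases <= 0)) {
    rlang::abort("per-case metrics undefined: zero case volume in some year",
                 class = "dpnpv_validation_error")
  }
  case_vec <- cases$cases
  cf <- tibble::tibble(
    year = by$year,
    cases = case_vec,
    consultations = cons$consultations,
    benefits = by$nominal,
    costs = cy$nominal,
    net = by$nominal - cy$nominal,
    benefits_discounted = by$discounted,
    costs_discounted = cy$discounted,
    net_discounted = by$discounted - cy$discounted,
    cumulative = cumsum(by$nominal - cy$nominal),
    cumulative_discounted = cumsum(by$discounted - cy$discounted),
    cost_per_case = cy$nominal / case_vec,
    revenue_per_case = by$nominal / case_vec
  )
  first_year <- function(x) {
    i <- which(x >= 0)
    if (length(i) == 0) NA_integer_ else cf$year[i[1]]
  }
  structure(list(
    cashflow = cf,
    costs = costs,
    benefits = benefits,
    npv = sum(cf$net_discounted),
    npv_benefits = sum(by$discounted),
    npv_costs = sum(cy$discounted),
    break_even_year = first_year(cf$net),
    payback_year = first_year(cf$cumulative),
    payback_year_discounted = first_year(cf$cumulative_discounted),
    params = params
  ), class = "business_case")
}

#' @export
print.business_case <- function(x, ...) {
  cat("<business_case over years 0..", max(x$cashflow$year), ">\n", sep = "")
  cat(sprintf("  NPV: %s (benefits %s - costs %s)\n",
              euro(x$npv), euro(x$npv_benefits), euro(x$npv_costs)))
  cat(sprintf("  yearly cash flow turns positive in Year %s; cumulative payback %s\n",
              x$break_even_year,
              if (is.na(x$payback_year)) "not reached"
              else paste("Year", x$payback_year)))
  cat(sprintf("  cost/case %.1f -> %.1f, revenue/case %.1f -> %.1f\n",
              x$cashflow$cost_per_case[1],
              utils::tail(x$cashflow$cost_per_case, 1),
              x$cashflow$revenue_per_case[1],
              utils::tail(x$cashflow$revenue_per_case, 1)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the yearly cash flow of a business case
#'
#' @param x A `business_case`.
#' @param ... Unused.
#' @return The per-year cash-flow tibble.
#' @method tidy business_case
#' @export
tidy.business_case <- function(x, ...) x$cashflow

#' One-row summary of a business case
#'
#' @param x A `business_case`.
#' @param ... Unused.
#' @return A one-row tibble: `npv`, `npv_benefits`, `npv_costs`,
#'   `break_even_year`, `payback_year`, `payback_year_discounted`, and the
#'   Year-0/horizon per-case metrics.
#' @method glance business_case
#' @export
glance.business_case <- function(x, ...) {
  n <- nrow(x$cashflow)
  tibble::tibble(
    npv = x$npv,
    npv_benefits = x$npv_benefits,
    npv_costs = x$npv_costs,
    break_even_year = x$break_even_year,
    payback_year = x$payback_year,
    payback_year_discounted = x$payback_year_discounted,
    cost_per_case_y0 = x$cashflow$cost_per_case[1],
    cost_per_case_end = x$cashflow$cost_per_case[n],
    revenue_per_case_y0 = x$cashflow$revenue_per_case[1],
    revenue_per_case_end = x$cashflow$revenue_per_case[n]
  )
}

euro <- function(x) {
  paste0("€", formatC(round(x), format = "d", big.mark = ","))
}
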