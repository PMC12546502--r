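#' Define a scenario as overrides and multipliers on model parameters
#'
#' A scenario is a named set of absolute `overrides` and positive
#' `multipliers` applied to a parameter set. Overrides are applied first,
#' then multipliers; the result is re-validated.
#'
#' @param name Scenario label (`"base"`, `"best"`, `"worst"`, or any custom
#'   label).
#' @param overrides Named list of absolute parameter values.
#' @param multipliers Named list of positive factors.
#' @return A `scenario_spec` object.
#' @examples
#' sp <- scenario_spec("tariff_up", multipliers = list(incremental_case_tariff = 1.1))
#' @export
scenario_spec <- function(name = "custom", overrides = list(),
                          multipliers = list()) {
  fields <- parameter_fields()$field
  bad <- setdiff(c(names(overrides), names(multipliers)), fields)
  if (length(bad) > 0) {
    rlang::abort(paste0("scenario names unknown parameter field(s): ",
                        paste(bad, collapse = ", ")),
                 class = "dpnpv_validation_error")
  }
  if (length(multipliers) > 0 && any(unlist(multipliers) <= 0)) {
    rlang::abort("scenario multipliers must be strictly positive",
                 class = "dpnpv_validation_error")
  }
  structure(list(name = name,
                 overrides = lapply(overrides, as.numeric),
                 multipliers = lapply(multipliers, as.numeric)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec '", x$name, "': ", length(x$overrides), " override(s), ",
      length(x$multipliers), " multiplier(s)>\n", sep = "")
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Overrides are applied first, multipliers second; the input is left
#' untouched and the result is re-validated (a scenario that pushes a
#' parameter out of range is an error naming the field).
#'
#' @param params A one-row `lab_parameters` tibble.
#' @param spec A [scenario_spec()].
#' @return A new validated `lab_parameters` tibble.
#' @export
apply_scenario <- function(params, spec) {
  stopifnot(inherits(spec, "scenario_spec"), nrow(params) == 1)
  out <- params
  for (fld in names(spec$overrides)) out[[fld]] <- spec$overrides[[fld]]
  for (fld in names(spec$multipliers)) out[[fld]] <- out[[fld]] * spec$multipliers[[fld]]
  validate_lab_parameters(out)
  out
}

#' Default base/best/worst scenario definitions
#'
#' The published model reports base, best and worst scenarios but not their
#' parameterization, so these shipped definitions are package choices meant
#' to be edited: the best case raises the demand/efficiency drivers (natural
#' growth, productivity capture, both tariffs) by `span` and lowers the unit
#' costs by `span`; the worst case mirrors it.
#'
#' @param span Relative shift, default 0.20.
#' @return A named list of three [scenario_spec()] objects.
#' @export
default_scenarios <- function(span = 0.20) {
  benefit_drivers <- c("natural_growth_rate", "productivity_capture",
                       "incremental_case_tariff", "consultation_tariff")
  cost_drivers <- c("scanner_unit_cost", "scanner_maintenance_annual",
                    "workstation_unit_cost", "storage_it_initial",
                    "storage_it_annual", "software_setup",
                    "software_annual_viewer", "software_annual_casemgr_lis")
  mk <- function(name, up, down) {
    scenario_spec(name, multipliers = c(
      stats::setNames(as.list(rep(up, length(benefit_drivers))), benefit_drivers),
      stats::setNames(as.list(rep(down, length(cost_drivers))), cost_drivers)))
  }
  list(base  = scenario_spec("base"),
       best  = mk("best", 1 + span, 1 - span),
       worst = mk("worst", 1 - span, 1 + span))
}

#' Run the business case under a list of scenarios
#'
#' @param params A one-row `lab_parameters` tibble (normally the calibrated
#'   base case).
#' @param scenarios A named list of [scenario_spec()] objects, default
#'   [default_scenarios()].
#' @return A tibble with one row per scenario: NPV, discounted benefit and
#'   cost totals, break-even and payback years.
#' @export
run_scenarios <- function(params, scenarios = default_scenarios()) {
  purrr::map_dfr(scenarios, function(sp) {
    bc <- build_business_case(apply_scenario(params, sp))
    g <- glance(bc)
    dplyr::bind_cols(tibble::tibble(scenario = sp$name), g)
  })
}
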