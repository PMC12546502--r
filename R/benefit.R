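#' Project yearly case volume
#'
#' Case volume combines natural demand growth with the share of extra
#' throughput that digital pathology lets the department capture:
#' `cases(t) = baseline * (1 + g)^t * (1 + capture * ramp(t))`, where
#' `ramp(t)` is the phase-in curve of the capture (zero at Year 0, reaching
#' one at the horizon; start and shape are parameters, normally calibrated).
#' With a zero capture the projection is pure geometric growth.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @return A tibble with columns `year`, `natural_cases` (growth-only
#'   counterfactual of the DP-era demand), `cases`, and
#'   `counterfactual_cases` (Year-0 volume held flat — the no-DP workload
#'   the department could serve).
#' @examples
#' project_case_volume(base_case_parameters())
#' @export
project_case_volume <- function(params) {
  stopifnot(nrow(params) == 1)
  validate_lab_parameters(params)
  h <- params$horizon
  t <- 0:h
  natural <- params$baseline_case_volume * (1 + params$natural_growth_rate)^t
  ramp <- capture_ramp(h, params$case_ramp_start, params$case_ramp_shape)
  tibble::tibble(
    year = t,
    natural_cases = natural,
    cases = natural * (1 + params$productivity_capture * ramp),
    counterfactual_cases = rep(params$baseline_case_volume, h + 1)
  )
}

#' Project yearly secondary-consultation volume
#'
#' Consultations grow geometrically at `consultation_growth_rate` and, like
#' case volume, carry an optional DP capture term:
#' `consultations(t) = baseline * (1 + g)^t * (1 + capture * ramp(t))`.
#' With `consultation_capture = 0` (the uncalibrated default) this is plain
#' geometric growth; the calibrated base case uses the capture ramp to
#' reproduce the published consultation benefit path.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @return A tibble with columns `year` and `consultations`.
#' @export
project_consultation_volume <- function(params) {
  stopifnot(nrow(params) == 1)
  validate_lab_parameters(params)
  h <- params$horizon
  t <- 0:h
  ramp <- capture_ramp(h, params$consult_ramp_start, params$consult_ramp_shape)
  tibble::tibble(
    year = t,
    consultations = params$baseline_consultations *
      (1 + params$consultation_growth_rate)^t *
      (1 + params$consultation_capture * ramp)
  )
}

#' Project yearly digitized slide volume
#'
#' Slides drive scanner-fleet sizing:
#' `slides(t) = cases(t) * slides_per_case * digitized_share`.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @param case_volumes Optional output of [project_case_volume()].
#' @return A tibble with columns `year` and `slides`.
#' @export
project_slide_volume <- function(params, case_volumes = project_case_volume(params)) {
  tibble::tibble(
    year = case_volumes$year,
    slides = case_volumes$cases * params$slides_per_case * params$digitized_share
  )
}

#' Build the per-year benefit schedule
#'
#' Four benefit streams, in euros per year:
#' * `increased_exam_volume`: `(cases(t) - counterfactual) * tariff`, where
#'   the counterfactual is the Year-0 volume held flat (without digital
#'   pathology the department could not absorb growth);
#' * `secondary_consultations`: `(consultations(t) - baseline) * tariff`;
#' * `workforce_efficiency`: `(0.20 pathologist FTE + 0.80 technician FTE)
#'   savings * salaries`, scaled by a per-year attribution profile
#'   (start/plateau/end), largest at go-live and tapering as freed capacity
#'   is re-absorbed by the growing exam volume stream;
#' * `equipment_reduction`: avoided microscope replacement/maintenance,
#'   constant from Year 1 (microscopes remain in use during startup).
#'
#' Negative incremental volumes are clamped to zero with a warning —
#' benefits are never negative.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @param case_volumes Optional [project_case_volume()] output.
#' @param consult_volumes Optional [project_consultation_volume()] output.
#' @return A long tibble of class `benefit_schedule`: columns `year`,
#'   `component`, `nominal`, `discounted` (end-of-year timing).
#' @export
build_benefit_schedule <- function(params,
                                   case_volumes = project_case_volume(params),
                                   consult_volumes = project_consultation_volume(params)) {
  stopifnot(nrow(params) == 1)
  h <- params$horizon
  stopifnot(nrow(case_volumes) == h + 1, nrow(consult_volumes) == h + 1)

  inc_cases <- case_volumes$cases - case_volumes$counterfactual_cases
  inc_cons <- consult_volumes$consultations - params$baseline_consultations
  if (any(inc_cases < 0) || any(inc_cons < 0)) {
    rlang::warn("negative incremental volumes clamped to zero")
    inc_cases <- pmax(inc_cases, 0)
    inc_cons <- pmax(inc_cons, 0)
  }

  wf_annual <- params$fte_saved_pathologist * params$pathologist_salary +
    params$fte_saved_technician * params$technician_salary
  wf_profile <- phase_profile(h, params$workforce_ramp_start,
                              params$workforce_ramp_base,
                              params$workforce_ramp_end)

  streams <- list(
    increased_exam_volume   = inc_cases * params$incremental_case_tariff,
    secondary_consultations = inc_cons * params$consultation_tariff,
    workforce_efficiency    = wf_annual * wf_profile,
    equipment_reduction     = c(0, rep(params$equipment_savings_annual, h))
  )
  new_schedule(streams, params, side = "benefit")
}

## shared constructor for long cost/benefit schedules
new_schedule <- function(streams, params, side, capex = NULL) {
  h <- params$horizon
  out <- purrr::imap_dfr(streams, function(v, nm) {
    tibble::tibble(year = 0:h, component = nm, nominal = v)
  })
  out$discounted <- discount_series(out$nominal, params$discount_rate,
                                    timing = "end", years = out$year)
  if (!is.null(capex)) {
    out <- dplyr::left_join(out, capex, by = c("year", "component"))
    out$capex[is.na(out$capex)] <- FALSE
  }
  cls <- if (side == "benefit") "benefit_schedule" else "cost_schedule"
  tibble::new_tibble(out, nrow = nrow(out), class = c(cls, "dpnpv_schedule", "tbl_df"),
                     side = side, discount_rate = params$discount_rate,
                     horizon = h)
}

#' Summarise a schedule into component totals
#'
#' @param schedule A `cost_schedule` or `benefit_schedule`.
#' @return A tibble with one row per component plus a `total` row: nominal
#'   and discounted (NPV) sums.
#' @export
component_totals <- function(schedule) {
  tot <- schedule |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(nominal = sum(.data$nominal),
                     discounted = sum(.data$discounted), .groups = "drop")
  dplyr::bind_rows(tot, tibble::tibble(component = "total",
                                       nominal = sum(tot$nominal),
                                       discounted = sum(tot$discounted)))
}

## wide per-year totals for one schedule
yearly_totals <- function(schedule) {
  schedule |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(nominal = sum(.data$nominal),
                     discounted = sum(.data$discounted), .groups = "drop")
}
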