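#' Size the scanner fleet from yearly slide volumes
#'
#' High-capacity scanners are added by a capacity-threshold rule: one
#' additional scanner for every full `capacity_increment` of slides per year
#' above the Year-0 volume. The fleet never shrinks within the horizon
#' (assets are kept for the full forecast):
#' `fleet(t) = initial + floor(max(0, slides(t) - slides(0)) / increment)`,
#' with `fleet(t)` additionally made non-decreasing in `t`. A `ceiling` rule
#' (a scanner is added as soon as a threshold is touched) is available as an
#' option.
#'
#' @param slide_volumes Numeric vector of slides/year for Years
#'   `0..horizon`, or the tibble from [project_slide_volume()].
#' @param initial_count Scanners in place at Year 0 (>= 1).
#' @param capacity_increment Additional slides/year that trigger one added
#'   scanner (> 0).
#' @param rule `"floor"` (default) or `"ceiling"`.
#' @return A tibble with columns `year`, `slides`, `fleet`, `purchases`.
#' @examples
#' size_scanner_fleet(c(300000, 320000, 380000), 5, 75000)
#' @export
size_scanner_fleet <- function(slide_volumes, initial_count,
                               capacity_increment, rule = c("floor", "ceiling")) {
  rule <- match.arg(rule)
  if (is.data.frame(slide_volumes)) slide_volumes <- slide_volumes$slides
  if (any(slide_volumes < 0)) {
    rlang::abort("slide volumes must be non-negative",
                 class = "dpnpv_validation_error")
  }
  if (initial_count < 1 || capacity_increment <= 0) {
    rlang::abort("initial_count must be >= 1 and capacity_increment > 0",
                 class = "dpnpv_validation_error")
  }
  excess <- pmax(0, slide_volumes - slide_volumes[1]) / capacity_increment
  added <- if (rule == "floor") floor(excess) else ceiling(excess)
  fleet <- cummax(initial_count + added)
  tibble::tibble(year = seq_along(slide_volumes) - 1,
                 slides = slide_volumes,
                 fleet = fleet,
                 purchases = diff(c(initial_count, fleet)))
}

#' Build the per-year investment and operating cost schedule
#'
#' Four cost streams, in euros per year:
#' * `hardware_equipment`: Year-0 scanner capex (`initial_scanner_count *
#'   scanner_unit_cost`) and workstation capex (`workstation_count *
#'   workstation_unit_cost`), incremental scanner purchases in the year the
#'   capacity threshold is crossed, and scanner maintenance from Year 1
#'   (first year under warranty);
#' * `software`: setup at Year 0; viewer and case-manager/LIS licence lines
#'   annually from Year 1;
#' * `it_storage`: initial storage/network investment at Year 0; all-in
#'   storage and IT operations annually from Year 1;
#' * `personnel_increase`: added scanning-technician FTEs at
#'   `technician_salary`, following a per-year phase profile — an elevated
#'   startup level at Year 0 (parallel analogue/digital running and archive
#'   conversion), a steady-state plateau, and a rise toward the horizon as
#'   volumes approach capacity.
#'
#' @param params A one-row `lab_parameters` tibble. `workstation_count` and
#'   the scanning-FTE profile must be set (they are normally calibrated); if
#'   they are still flagged "to be calibrated" the build is refused.
#' @param case_volumes Optional [project_case_volume()] output.
#' @return A long tibble of class `cost_schedule`: columns `year`,
#'   `component`, `nominal`, `discounted` (end-of-year timing), `capex`.
#' @export
build_investment_schedule <- function(params,
                                      case_volumes = project_case_volume(params)) {
  stopifnot(nrow(params) == 1)
  validate_lab_parameters(params)
  flagged <- attr(params, "needs_calibration")
  if (!is.null(flagged) && length(flagged) > 0) {
    rlang::abort(paste0("parameters need calibration before building the ",
                        "investment schedule (uncalibrated: ",
                        paste(flagged, collapse = ", "),
                        "); run calibrate_model() or supply values"),
                 class = "dpnpv_calibration_error")
  }
  h <- params$horizon
  slides <- project_slide_volume(params, case_volumes)
  fleet <- size_scanner_fleet(slides$slides, params$initial_scanner_count,
                              params$scanner_capacity_increment)

  scanner_capex <- c(params$initial_scanner_count * params$scanner_unit_cost,
                     rep(0, h)) + fleet$purchases * params$scanner_unit_cost
  workstation_capex <- c(params$workstation_count * params$workstation_unit_cost,
                         rep(0, h))
  maintenance <- c(0, rep(params$scanner_maintenance_annual, h))

  software <- c(params$software_setup, rep(0, h)) +
    c(0, rep(params$software_annual_viewer + params$software_annual_casemgr_lis, h))
  it_storage <- c(params$storage_it_initial, rep(0, h)) +
    c(0, rep(params$storage_it_annual, h))

  fte <- phase_profile(h, params$scanning_fte_startup,
                       params$scanning_fte_base, params$scanning_fte_added)
  personnel <- fte * params$technician_salary

  streams <- list(
    hardware_equipment = scanner_capex + workstation_capex + maintenance,
    software = software,
    it_storage = it_storage,
    personnel_increase = personnel
  )
  capex <- tibble::tibble(
    year = rep(0:h, 3),
    component = rep(c("hardware_equipment", "software", "it_storage"), each = h + 1),
    capex = c(scanner_capex + workstation_capex > 0,
              c(TRUE, rep(FALSE, h)) & params$software_setup > 0,
              c(TRUE, rep(FALSE, h)) & params$storage_it_initial > 0)
  )
  new_schedule(streams, params, side = "cost", capex = capex)
}
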