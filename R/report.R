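#' Investment table (discounted component totals)
#'
#' The four discounted investment components and their total, with rendered
#' euro strings (thousands separators). Component rows always re-sum to the
#' rendered total: rounding is applied after summation.
#'
#' @param bc A `business_case`.
#' @return A tibble with columns `component`, `npv`, `label`.
#' @export
investment_table <- function(bc) {
  render_component_table(bc$costs)
}

#' Benefit table (discounted component totals)
#'
#' @param bc A `business_case`.
#' @return A tibble with columns `component`, `npv`, `label`.
#' @export
benefit_table <- function(bc) {
  render_component_table(bc$benefits)
}

render_component_table <- function(schedule) {
  tot <- component_totals(schedule)
  tibble::tibble(component = tot$component,
                 npv = tot$discounted,
                 label = euro(tot$discounted))
}

#' Yearly cash-flow table in thousands of euros with component shares
#'
#' One row per year and side (investment / benefits): the yearly total in
#' thousands of euros and each component's share of that year's total as a
#' percentage to one decimal. Years whose total is zero have blank shares.
#'
#' @param bc A `business_case`.
#' @return A tibble: `side`, `year`, `total_keur`, one share column per
#'   component (character, e.g. `"61.3"`, blank when undefined).
#' @export
cashflow_table <- function(bc) {
  one_side <- function(schedule, side) {
    wide <- schedule |>
      dplyr::select("year", "component", "nominal") |>
      tidyr::pivot_wider(names_from = "component", values_from = "nominal")
    comp_cols <- setdiff(names(wide), "year")
    total <- rowSums(wide[comp_cols])
    shares <- lapply(wide[comp_cols], function(v) {
      ifelse(total > 0, sprintf("%.1f", 100 * v / total), "")
    })
    dplyr::bind_cols(
      tibble::tibble(side = side, year = wide$year,
                     total_keur = round(total / 1000, 1)),
      tibble::as_tibble(shares)
    )
  }
  dplyr::bind_rows(one_side(bc$costs, "investment"),
                   one_side(bc$benefits, "benefits"))
}

#' Write a complete business case to CSV and JSON files
#'
#' Emits `cashflow.csv` (per-year flows, cumulative series, per-case
#' metrics), `cost_schedule.csv` and `benefit_schedule.csv` (year x
#' component, nominal and discounted, capex flags), `investment_table.csv`,
#' `benefit_table.csv`, `cashflow_components.csv` (the thousands-of-euros
#' layout with shares), and `summary.json` (NPV, payback, component totals).
#' Running twice on the same input yields byte-identical files.
#'
#' @param bc A `business_case`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_business_case <- function(bc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cashflow = file.path(dir, "cashflow.csv"),
    cost_schedule = file.path(dir, "cost_schedule.csv"),
    benefit_schedule = file.path(dir, "benefit_schedule.csv"),
    investment_table = file.path(dir, "investment_table.csv"),
    benefit_table = file.path(dir, "benefit_table.csv"),
    components = file.path(dir, "cashflow_components.csv"),
    summary = file.path(dir, "summary.json")
  )
  readr::write_csv(bc$cashflow, paths["cashflow"])
  readr::write_csv(tibble::as_tibble(bc$costs), paths["cost_schedule"])
  readr::write_csv(tibble::as_tibble(bc$benefits), paths["benefit_schedule"])
  readr::write_csv(investment_table(bc), paths["investment_table"])
  readr::write_csv(benefit_table(bc), paths["benefit_table"])
  readr::write_csv(cashflow_table(bc), paths["components"])
  summary <- c(as.list(glance(bc)),
               list(cost_components = stats::setNames(
                      as.list(component_totals(bc$costs)$discounted),
                      component_totals(bc$costs)$component),
                    benefit_components = stats::setNames(
                      as.list(component_totals(bc$benefits)$discounted),
                      component_totals(bc$benefits)$component)))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Plot the yearly cash flow of a business case
#'
#' Bars for yearly nominal benefits and costs (costs negative), a line for
#' the cumulative nominal net flow, all in thousands of euros.
#'
#' @param object A `business_case`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot business_case
#' @export
autoplot.business_case <- function(object, ...) {
  cf <- object$cashflow
  long <- dplyr::bind_rows(
    tibble::tibble(year = cf$year, side = "benefits", keur = cf$benefits / 1000),
    tibble::tibble(year = cf$year, side = "investment", keur = -cf$costs / 1000)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$keur,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "identity", alpha = 0.85) +
    ggplot2::geom_line(data = tibble::tibble(year = cf$year,
                                             keur = cf$cumulative / 1000),
                       ggplot2::aes(x = .data$year, y = .data$keur),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "year", y = "thousands EUR", fill = NULL,
                  title = "Digital pathology yearly cash flow",
                  subtitle = "bars: yearly flows; line: cumulative net flow") +
    ggplot2::theme_minimal()
}

#' Tornado plot of one-way NPV sensitivity
#'
#' @param object A `dp_tornado` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dp_tornado
#' @export
autoplot.dp_tornado <- function(object, ...) {
  base_npv <- attr(object, "baseline_npv")
  dat <- tibble::as_tibble(object)
  dat$driver <- factor(dat$driver, levels = rev(dat$driver))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$driver)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$npv_low / 1000,
                                       xend = .data$npv_high / 1000,
                                       yend = .data$driver),
                          linewidth = 5, colour = "grey55") +
    ggplot2::geom_vline(xintercept = base_npv / 1000, linetype = 2) +
    ggplot2::labs(x = "NPV (thousands EUR)", y = NULL,
                  title = "One-way sensitivity of NPV") +
    ggplot2::theme_minimal()
}

#' Histogram of the PSA NPV sample
#'
#' @param object A `dp_psa` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dp_psa
#' @export
autoplot.dp_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$npv / 1000)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "NPV (thousands EUR)", y = "draws",
                  title = "Probabilistic sensitivity analysis of NPV") +
    ggplot2::theme_minimal()
}
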