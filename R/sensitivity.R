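#' Default tornado drivers
#'
#' Each driver is a named character vector of one or more parameter fields
#' varied together (e.g. demand growth and case-processing efficiency form
#' one "growth and productivity" driver).
#'
#' @return A named list of character vectors of parameter fields.
#' @export
default_tornado_drivers <- function() {
  list(
    growth_and_productivity = c("natural_growth_rate", "productivity_capture"),
    case_tariff             = "incremental_case_tariff",
    consultation_tariff     = "consultation_tariff",
    scanner_costs           = c("scanner_unit_cost", "scanner_maintenance_annual"),
    it_storage_costs        = c("storage_it_initial", "storage_it_annual"),
    software_costs          = c("software_setup", "software_annual_viewer",
                                "software_annual_casemgr_lis"),
    scanning_staff          = "technician_salary",
    workforce_savings       = "pathologist_salary",
    equipment_savings       = "equipment_savings_annual",
    discount_rate           = "discount_rate"
  )
}

#' One-way (tornado) sensitivity analysis of NPV
#'
#' Each driver is moved to `(1 - span)` and `(1 + span)` times its base
#' value with everything else fixed, the business case is rebuilt, and
#' drivers are ranked by the absolute NPV swing. Fully deterministic.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @param drivers Named list of character vectors of parameter fields (see
#'   [default_tornado_drivers()]); a plain character vector is also accepted.
#' @param span Relative half-width (> 0 scalar, or one value per driver).
#' @return A tibble of class `dp_tornado`, sorted by `|delta|` descending:
#'   columns `driver`, `npv_low`, `npv_high`, `delta`
#'   (`npv_high - npv_low`), `swing` (max |NPV - base|), `rank`; the base
#'   NPV is in attribute `baseline_npv`.
#' @examples
#' tornado_sensitivity(base_case_parameters(),
#'                     drivers = list(growth = "natural_growth_rate"))
#' @export
tornado_sensitivity <- function(params, drivers = default_tornado_drivers(),
                                span = 0.20) {
  if (is.character(drivers)) drivers <- as.list(stats::setNames(drivers, drivers))
  fields <- parameter_fields()$field
  bad <- setdiff(unlist(drivers), fields)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown driver field(s): ",
                        paste(bad, collapse = ", "),
                        "; valid fields are listed by parameter_fields()"),
                 class = "dpnpv_validation_error")
  }
  if (any(span < 0)) {
    rlang::abort("span must be non-negative", class = "dpnpv_validation_error")
  }
  span <- rep_len(span, length(drivers))
  base_npv <- build_business_case(params)$npv

  npv_at <- function(flds, mult) {
    sp <- scenario_spec("tornado",
                        multipliers = stats::setNames(as.list(rep(mult, length(flds))),
                                                      flds))
    build_business_case(apply_scenario(params, sp))$npv
  }
  out <- purrr::imap_dfr(drivers, function(flds, nm) {
    i <- match(nm, names(drivers))
    tibble::tibble(driver = nm,
                   npv_low = npv_at(flds, 1 - span[i]),
                   npv_high = npv_at(flds, 1 + span[i]))
  })
  out$delta <- out$npv_high - out$npv_low
  out$swing <- pmax(abs(out$npv_high - base_npv), abs(out$npv_low - base_npv))
  out <- dplyr::arrange(out, dplyr::desc(.data$swing))
  out$rank <- seq_len(nrow(out))
  tibble::new_tibble(out, nrow = nrow(out),
                     class = c("dp_tornado", "tbl_df"),
                     baseline_npv = base_npv, span = span)
}

#' Specify a parameter distribution for probabilistic sensitivity analysis
#'
#' @param param Parameter field name.
#' @param dist `"uniform"`, `"normal"` (truncated at the field's validity
#'   bounds) or `"fixed"`.
#' @param rel_halfwidth Half-width of a uniform as a fraction of the base
#'   value (uniform only).
#' @param cv Coefficient of variation (normal only).
#' @return A `psa_dist` specification.
#' @export
psa_dist <- function(param, dist = c("uniform", "normal", "fixed"),
                     rel_halfwidth = 0.1, cv = 0.1) {
  dist <- match.arg(dist)
  spec <- parameter_fields()
  if (!param %in% spec$field) {
    rlang::abort(paste0("unknown parameter field '", param, "'"),
                 class = "dpnpv_validation_error")
  }
  structure(list(param = param, dist = dist,
                 rel_halfwidth = rel_halfwidth, cv = cv),
            class = "psa_dist")
}

#' Default PSA distribution set
#'
#' Uniform +/-10% on the main demand and tariff drivers.
#'
#' @return List of [psa_dist()] specifications.
#' @export
default_psa_distributions <- function() {
  lapply(c("natural_growth_rate", "productivity_capture",
           "incremental_case_tariff", "consultation_tariff",
           "storage_it_annual", "scanner_maintenance_annual"),
         psa_dist, dist = "uniform", rel_halfwidth = 0.1)
}

#' Monte Carlo probabilistic sensitivity analysis of NPV
#'
#' Draws `n` independent parameter vectors from the supplied distributions
#' (all other fields fixed at base), rebuilds the business case for each,
#' and summarises the NPV sample. Identical `seed`, `n` and distributions
#' reproduce the result bit-identically. Distribution supports are checked
#' against the parameter validity bounds when the specification is read —
#' a uniform that can leave the valid range is rejected before any draw.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @param distributions List of [psa_dist()] specifications.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Object of class `dp_psa`: list with `draws` (tibble of sampled
#'   parameters and resulting `npv`), `summary` (one-row tibble: `mean_npv`,
#'   `sd_npv`, `q025`, `q975`, `p_npv_positive`), `n`, `seed`.
#' @export
monte_carlo_psa <- function(params, distributions = default_psa_distributions(),
                            n = 1000, seed = 1L) {
  stopifnot(nrow(params) == 1, n >= 1)
  validate_lab_parameters(params)
  spec <- parameter_fields()
  ## reject bound-violating specs before drawing
  for (ds in distributions) {
    stopifnot(inherits(ds, "psa_dist"))
    i <- match(ds$param, spec$field)
    base <- params[[ds$param]]
    if (ds$dist == "uniform") {
      lo <- base * (1 - ds$rel_halfwidth); hi <- base * (1 + ds$rel_halfwidth)
      if (min(lo, hi) < spec$lower[i] || max(lo, hi) > spec$upper[i]) {
        rlang::abort(paste0("PSA uniform for '", ds$param,
                            "' leaves the valid range [", spec$lower[i], ", ",
                            spec$upper[i], "]"),
                     class = "dpnpv_validation_error")
      }
    }
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  draws <- purrr::map_dfr(seq_len(n), function(k) {
    q <- params
    for (ds in distributions) {
      i <- match(ds$param, spec$field)
      base <- params[[ds$param]]
      q[[ds$param]] <- switch(
        ds$dist,
        fixed = base,
        uniform = stats::runif(1, base * (1 - ds$rel_halfwidth),
                               base * (1 + ds$rel_halfwidth)),
        normal = rtrunc_norm(1, base, abs(base) * ds$cv,
                             spec$lower[i], spec$upper[i], ds$param)
      )
    }
    q <- validate_lab_parameters(q)
    out <- tibble::as_tibble(q)[, vapply(distributions, function(z) z$param, "")]
    out$npv <- build_business_case(q)$npv
    out
  })
  summary <- tibble::tibble(
    mean_npv = mean(draws$npv),
    sd_npv = stats::sd(draws$npv),
    q025 = stats::quantile(draws$npv, 0.025, names = FALSE, type = 7),
    q975 = stats::quantile(draws$npv, 0.975, names = FALSE, type = 7),
    p_npv_positive = mean(draws$npv > 0)
  )
  structure(list(draws = draws, summary = summary, n = n,
                 seed = as.integer(seed)),
            class = "dp_psa")
}

#' @export
print.dp_psa <- function(x, ...) {
  cat("<dp_psa: ", x$n, " draws, seed ", x$seed, ">\n", sep = "")
  print(x$summary)
  invisible(x)
}

## save/restore global RNG state so model code has no side effects
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
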