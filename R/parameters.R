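#' Field metadata for laboratory model parameters
#'
#' Every model input lives in a flat, one-row table (a `lab_parameters`
#' object). This function returns the field registry: defaults, validity
#' bounds, and the roles each field plays in validation, synthetic-panel
#' sampling and calibration.
#'
#' @details Field kinds:
#' * `structural` — shared across a multi-lab panel, never sampled (forecast
#'   horizon, discount rate, scanner capacity rule).
#' * `rate` — annual fractions, constrained to (-1, 1).
#' * `share`/`ramp` — fractions in \[0, 1\].
#' * `money`, `volume`, `fte`, `count` — non-negative.
#' * `shape` — strictly positive exponents of the capture-ramp family.
#'
#' Fields with `calibrated = TRUE` carry documented provisional defaults and
#' are solved by [calibrate_model()] from printed anchors; a configuration
#' file may omit them, in which case [read_lab_parameters()] fills the default
#' and flags the field as "to be calibrated".
#'
#' @return A tibble with columns `field`, `default`, `lower`, `upper`,
#'   `kind`, `sampled`, `calibrated`.
#' @export
parameter_fields <- function() {
  f <- function(field, default, lower, upper, kind, sampled, calibrated) {
    tibble::tibble(field = field, default = default, lower = lower,
                   upper = upper, kind = kind, sampled = sampled,
                   calibrated = calibrated)
  }
  dplyr::bind_rows(
    f("horizon",                    7,       1,     50,   "structural", FALSE, FALSE),
    f("discount_rate",              0.05,   -0.99,  0.99, "rate",       FALSE, FALSE),
    f("baseline_case_volume",       56000,   0,     Inf,  "volume",     TRUE,  FALSE),
    f("natural_growth_rate",        0.0206, -0.99,  0.99, "rate",       TRUE,  FALSE),
    f("digitized_share",            0.814,   0,     1,    "share",      TRUE,  FALSE),
    f("slides_per_case",            4.5,     1e-9,  Inf,  "count",      TRUE,  FALSE),
    f("productivity_gain",          0.074,   0,     1,    "share",      FALSE, FALSE),
    f("productivity_capture",       0.074,   0,     2,    "share2",     TRUE,  TRUE),
    f("case_ramp_start",            0,       0,     1,    "ramp",       FALSE, TRUE),
    f("case_ramp_shape",            1,       0.01,  10,   "shape",      FALSE, TRUE),
    f("incremental_case_tariff",    80,      0,     Inf,  "money",      TRUE,  TRUE),
    f("baseline_consultations",     2785,    0,     Inf,  "volume",     TRUE,  FALSE),
    f("consultation_growth_rate",   0.0206, -0.99,  0.99, "rate",       TRUE,  FALSE),
    f("consultation_capture",       0,       0,     2,    "share2",     TRUE,  TRUE),
    f("consult_ramp_start",         0,       0,     1,    "ramp",       FALSE, TRUE),
    f("consult_ramp_shape",         1,       0.01,  10,   "shape",      FALSE, TRUE),
    f("consultation_tariff",        65,      0,     Inf,  "money",      TRUE,  TRUE),
    f("scanner_unit_cost",          277000,  0,     Inf,  "money",      TRUE,  FALSE),
    f("initial_scanner_count",      5,       1,     Inf,  "structural", FALSE, FALSE),
    f("scanner_capacity_increment", 75000,   1e-9,  Inf,  "structural", FALSE, FALSE),
    f("scanner_maintenance_annual", 65000,   0,     Inf,  "money",      TRUE,  FALSE),
    f("workstation_unit_cost",      4211,    0,     Inf,  "money",      TRUE,  FALSE),
    f("workstation_count",          50,      0,     Inf,  "count",      TRUE,  TRUE),
    f("storage_it_initial",         278000,  0,     Inf,  "money",      TRUE,  FALSE),
    f("storage_it_annual",          155000,  0,     Inf,  "money",      TRUE,  FALSE),
    f("software_setup",             276000,  0,     Inf,  "money",      TRUE,  FALSE),
    f("software_annual_viewer",     73000,   0,     Inf,  "money",      TRUE,  FALSE),
    f("software_annual_casemgr_lis", 137000, 0,     Inf,  "money",      TRUE,  FALSE),
    f("technician_salary",          50000,   0,     Inf,  "money",      TRUE,  FALSE),
    f("scanning_fte_startup",       1,       0,     Inf,  "fte",        TRUE,  TRUE),
    f("scanning_fte_base",          1,       0,     Inf,  "fte",        TRUE,  TRUE),
    f("scanning_fte_added",         1,       0,     Inf,  "fte",        TRUE,  TRUE),
    f("pathologist_salary",         120000,  0,     Inf,  "money",      TRUE,  TRUE),
    f("fte_saved_pathologist",      0.20,    0,     Inf,  "fte",        TRUE,  FALSE),
    f("fte_saved_technician",       0.80,    0,     Inf,  "fte",        TRUE,  FALSE),
    f("workforce_ramp_start",       1,       0,     1,    "ramp",       FALSE, TRUE),
    f("workforce_ramp_base",        1,       0,     1,    "ramp",       FALSE, TRUE),
    f("workforce_ramp_end",         1,       0,     1,    "ramp",       FALSE, TRUE),
    f("equipment_savings_annual",   32000,   0,     Inf,  "money",      TRUE,  TRUE),
    f("tat_reduction",              0.153,   0,     1,    "share",      FALSE, FALSE)
  )
}

#' Construct a validated laboratory parameter set
#'
#' Builds the full input vector of one laboratory (or of the averaged model
#' laboratory) as a one-row tibble of class `lab_parameters`. Unspecified
#' fields take the documented defaults of [parameter_fields()].
#'
#' @param ... Named numeric values overriding field defaults.
#' @param .validate Validate the result (default `TRUE`).
#' @return A one-row `lab_parameters` tibble.
#' @examples
#' p <- lab_parameters(baseline_case_volume = 62000, digitized_share = 0.9)
#' p$digitized_share
#' @export
lab_parameters <- function(..., .validate = TRUE) {
  spec <- parameter_fields()
  vals <- stats::setNames(as.list(spec$default), spec$field)
  dots <- list(...)
  if (length(dots) > 0 && (is.null(names(dots)) || any(names(dots) == ""))) {
    rlang::abort("all arguments to lab_parameters() must be named",
                 class = "dpnpv_validation_error")
  }
  unknown <- setdiff(names(dots), spec$field)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown parameter field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "dpnpv_validation_error")
  }
  vals[names(dots)] <- lapply(dots, as.numeric)
  out <- tibble::new_tibble(vals, nrow = 1L,
                            class = c("lab_parameters", "tbl_df"))
  if (.validate) validate_lab_parameters(out)
  out
}

#' Coerce a data frame to lab_parameters
#'
#' Accepts a data frame with one row per laboratory (a panel) or a single
#' row; missing fields are filled with defaults, every row is validated.
#'
#' @param x A data frame with parameter columns.
#' @return A `lab_parameters` tibble with the same number of rows.
#' @export
as_lab_parameters <- function(x) {
  spec <- parameter_fields()
  x <- tibble::as_tibble(x)
  unknown <- setdiff(names(x), spec$field)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown parameter field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "dpnpv_validation_error")
  }
  for (i in seq_len(nrow(spec))) {
    if (is.null(x[[spec$field[i]]])) x[[spec$field[i]]] <- spec$default[i]
  }
  x <- x[, spec$field]
  x <- tibble::new_tibble(x, nrow = nrow(x),
                          class = c("lab_parameters", "tbl_df"))
  validate_lab_parameters(x)
  x
}

#' Validate laboratory parameters against field bounds
#'
#' Checks every row of a parameter table against the bounds in
#' [parameter_fields()]: monetary fields non-negative, rates in (-1, 1),
#' shares and ramp weights in \[0, 1\], capacity increments strictly
#' positive, horizon a positive integer.
#'
#' @param params A `lab_parameters` tibble (one or more rows).
#' @return `params`, invisibly, if valid; otherwise an error of class
#'   `dpnpv_validation_error` naming the offending field and bound.
#' @export
validate_lab_parameters <- function(params) {
  spec <- parameter_fields()
  missing <- setdiff(spec$field, names(params))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing parameter field(s): ",
                        paste(missing, collapse = ", ")),
                 class = "dpnpv_validation_error")
  }
  for (i in seq_len(nrow(spec))) {
    fld <- spec$field[i]
    v <- params[[fld]]
    if (!is.numeric(v) || anyNA(v)) {
      rlang::abort(paste0("field '", fld, "' must be numeric and non-missing"),
                   class = "dpnpv_validation_error")
    }
    strict_lower <- spec$kind[i] %in% c("shape") || fld == "scanner_capacity_increment"
    lo_ok <- if (strict_lower) all(v >= spec$lower[i]) else all(v >= spec$lower[i])
    if (spec$kind[i] == "rate") {
      lo_ok <- all(v > -1)
    }
    if (!lo_ok || !all(v <= spec$upper[i])) {
      rlang::abort(
        paste0("field '", fld, "' out of range: must lie in [",
               spec$lower[i], ", ", spec$upper[i], "], got ",
               paste(signif(v[v < spec$lower[i] | v > spec$upper[i]], 6),
                     collapse = ", ")),
        class = "dpnpv_validation_error")
    }
  }
  if (any(params$horizon != round(params$horizon)) || any(params$horizon < 1)) {
    rlang::abort("field 'horizon' must be a positive integer",
                 class = "dpnpv_validation_error")
  }
  invisible(params)
}

#' @export
print.lab_parameters <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<lab_parameters: %d %s, horizon %s years, discount %s>\n",
              n, if (n == 1) "laboratory" else "laboratories",
              paste(unique(x$horizon), collapse = "/"),
              paste(unique(x$discount_rate), collapse = "/")))
  flagged <- attr(x, "needs_calibration")
  if (!is.null(flagged) && length(flagged) > 0) {
    cat("  fields defaulted, to be calibrated: ",
        paste(flagged, collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Packaged base-case parameters
#'
#' Reads the packaged base-case configuration (the averaged model laboratory:
#' 56,000 cases and 2,785 consultations at Year 0, 81.4% of cases digitized,
#' 2.06% natural growth, 5% discount rate, five scanners at 277 k euro each,
#' and the published software/IT/personnel unit costs). With
#' `calibrated = TRUE` (the default) the under-specified fields (tariffs,
#' capture ramps, workstation count, scanning-FTE profile, pathologist
#' salary, equipment saving) are solved at call time by [calibrate_model()]
#' against [printed_anchors()]; the solve is deterministic and closed-form,
#' so repeated calls are bit-identical.
#'
#' @param calibrated Solve the calibrated fields (default `TRUE`); if
#'   `FALSE`, returns the raw configuration with provisional defaults.
#' @return A one-row `lab_parameters` tibble.
#' @examples
#' base <- base_case_parameters()
#' round(base$incremental_case_tariff, 2)
#' @export
base_case_parameters <- function(calibrated = TRUE) {
  path <- system.file("extdata", "base_case.yaml", package = "dpnpv",
                      mustWork = TRUE)
  raw <- read_lab_parameters(path)
  if (!calibrated) return(raw)
  calibrate_model(raw)$params
}

#' Read laboratory parameters from a YAML configuration file
#'
#' The canonical configuration dialect is flat YAML: one `field: value` pair
#' per line, fields named as in [parameter_fields()]. Unknown keys are an
#' error; omitted calibrated fields are defaulted and flagged
#' "to be calibrated" (see the `needs_calibration` attribute); omitted
#' non-calibrated fields are defaulted with a message.
#'
#' @param path Path to a YAML file.
#' @return A one-row `lab_parameters` tibble.
#' @export
read_lab_parameters <- function(path) {
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      rlang::abort(paste0("failed to parse configuration '", path, "': ",
                          conditionMessage(e)),
                   class = "dpnpv_parse_error", parent = e)
    })
  if (!is.list(vals) || length(vals) == 0) {
    rlang::abort(paste0("configuration '", path,
                        "' is empty or not a key/value mapping"),
                 class = "dpnpv_parse_error")
  }
  spec <- parameter_fields()
  unknown <- setdiff(names(vals), spec$field)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "dpnpv_validation_error")
  }
  absent <- setdiff(spec$field, names(vals))
  to_calibrate <- intersect(absent, spec$field[spec$calibrated])
  defaulted <- setdiff(absent, to_calibrate)
  if (length(defaulted) > 0) {
    rlang::inform(paste0("using defaults for: ",
                         paste(defaulted, collapse = ", ")))
  }
  out <- do.call(lab_parameters, lapply(vals, as.numeric))
  attr(out, "needs_calibration") <- to_calibrate
  out
}

#' Write laboratory parameters to a YAML configuration file
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip reproduces integers bit-identically and rates to full
#' precision.
#'
#' @param params A one-row `lab_parameters` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lab_parameters <- function(params, path) {
  stopifnot(nrow(params) == 1)
  validate_lab_parameters(params)
  vals <- as.list(params)[parameter_fields()$field]
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' Export a laboratory panel (or single parameter set) to CSV
#'
#' One row per laboratory, one column per parameter field.
#'
#' @param panel A `lab_parameters` tibble (any number of rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lab_panel <- function(panel, path) {
  validate_lab_parameters(panel)
  readr::write_csv(tibble::as_tibble(panel), path)
  invisible(path)
}

#' Import a laboratory panel from CSV
#'
#' @param path CSV path written by [write_lab_panel()].
#' @return A validated `lab_parameters` tibble.
#' @export
read_lab_panel <- function(path) {
  as_lab_parameters(readr::read_csv(path, show_col_types = FALSE))
}

#' Average a multi-laboratory panel into the model laboratory
#'
#' Field-wise unweighted arithmetic mean of the numeric fields, as used to
#' synthesize the study's per-laboratory inputs into a single model input
#' vector. Structural fields (horizon, scanner capacity rule, discount rate)
#' must be identical across laboratories.
#'
#' @param panel A `lab_parameters` tibble with one row per laboratory.
#' @return A one-row `lab_parameters` tibble.
#' @examples
#' panel <- dplyr::bind_rows(lab_parameters(baseline_case_volume = 50000),
#'                           lab_parameters(baseline_case_volume = 62000))
#' average_labs(as_lab_parameters(panel))$baseline_case_volume  # 56000
#' @export
average_labs <- function(panel) {
  if (nrow(panel) < 1) {
    rlang::abort("panel must contain at least one laboratory",
                 class = "dpnpv_validation_error")
  }
  validate_lab_parameters(panel)
  spec <- parameter_fields()
  structural <- spec$field[spec$kind == "structural"]
  for (fld in structural) {
    if (length(unique(panel[[fld]])) != 1) {
      rlang::abort(paste0("structural field '", fld,
                          "' differs across laboratories"),
                   class = "dpnpv_validation_error")
    }
  }
  means <- lapply(tibble::as_tibble(panel), mean)
  out <- tibble::new_tibble(means, nrow = 1L,
                            class = c("lab_parameters", "tbl_df"))
  validate_lab_parameters(out)
  out
}
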