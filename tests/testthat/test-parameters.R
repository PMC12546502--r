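test_that("constructor applies defaults, overrides, and rejects unknown fields", {
  p <- lab_parameters()
  expect_s3_class(p, "lab_parameters")
  expect_equal(p$horizon, 7)
  expect_equal(p$discount_rate, 0.05)
  p2 <- lab_parameters(baseline_case_volume = 62000, digitized_share = 0.9)
  expect_equal(p2$baseline_case_volume, 62000)
  expect_equal(p2$digitized_share, 0.9)
  expect_error(lab_parameters(not_a_field = 1), class = "dpnpv_validation_error")
  expect_error(lab_parameters(1), class = "dpnpv_validation_error")
})

test_that("validation names the offending field and bound", {
  expect_error(lab_parameters(digitized_share = 1.2),
               regexp = "digitized_share", class = "dpnpv_validation_error")
  expect_error(lab_parameters(scanner_unit_cost = -1),
               regexp = "scanner_unit_cost", class = "dpnpv_validation_error")
  expect_error(lab_parameters(natural_growth_rate = -1),
               regexp = "natural_growth_rate", class = "dpnpv_validation_error")
  expect_error(lab_parameters(scanner_capacity_increment = 0),
               class = "dpnpv_validation_error")
  expect_error(lab_parameters(horizon = 2.5), regexp = "horizon",
               class = "dpnpv_validation_error")
})

test_that("packaged base-case config carries the published inputs", {
  raw <- base_case_parameters(calibrated = FALSE)
  expect_equal(raw$discount_rate, 0.05)
  expect_equal(raw$natural_growth_rate, 0.0206)
  expect_equal(raw$initial_scanner_count, 5)
  expect_equal(raw$scanner_unit_cost, 277000)
  expect_equal(raw$digitized_share, 0.814)
  expect_equal(raw$baseline_case_volume, 56000)
  expect_equal(raw$baseline_consultations, 2785)
  # omitted calibrated fields are defaulted and flagged
  flagged <- attr(raw, "needs_calibration")
  expect_true(all(c("workstation_count", "incremental_case_tariff",
                    "pathologist_salary") %in% flagged))
})

test_that("config round-trip preserves integers bit-identically and rates fully", {
  p <- lab_parameters(baseline_case_volume = 56000,
                      natural_growth_rate = 0.0206,
                      incremental_case_tariff = 85.78947368421052,
                      workstation_count = 135.68894977939538)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_lab_parameters(p, path)
  q <- read_lab_parameters(path)
  expect_identical(q$baseline_case_volume, 56000)
  expect_identical(q$horizon, 7)
  expect_equal(q$natural_growth_rate, 0.0206, tolerance = 0)
  for (fld in parameter_fields()$field) {
    expect_equal(q[[fld]], p[[fld]], tolerance = 1e-14, label = fld)
  }
})

test_that("malformed and unknown-key configs raise parse/validation errors", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("horizon: 7", "discount_rate: [unclosed"), bad)
  expect_error(read_lab_parameters(bad), class = "dpnpv_parse_error")
  unk <- tempfile(fileext = ".yaml")
  writeLines(c("horizon: 7", "no_such_parameter: 3"), unk)
  expect_error(read_lab_parameters(unk), regexp = "no_such_parameter",
               class = "dpnpv_validation_error")
  unlink(c(bad, unk))
})

test_that("averaging is the unweighted field-wise mean", {
  one <- lab_parameters(baseline_case_volume = 50000)
  two <- lab_parameters(baseline_case_volume = 62000)
  panel <- as_lab_parameters(dplyr::bind_rows(one, two))
  expect_equal(average_labs(panel)$baseline_case_volume, 56000)
  # identity on a uniform panel, for every field
  uni <- as_lab_parameters(dplyr::bind_rows(one, one, one))
  avg <- average_labs(uni)
  for (fld in parameter_fields()$field) {
    expect_identical(avg[[fld]], one[[fld]], label = fld)
  }
  # permutation invariance
  sh <- as_lab_parameters(dplyr::bind_rows(two, one))
  expect_equal(average_labs(sh), average_labs(panel), ignore_attr = TRUE)
})

test_that("averaging refuses mixed structural fields", {
  a <- lab_parameters(horizon = 7)
  b <- lab_parameters(horizon = 6)
  panel <- as_lab_parameters(dplyr::bind_rows(a, b))
  expect_error(average_labs(panel), regexp = "horizon",
               class = "dpnpv_validation_error")
})

test_that("panel CSV round-trips", {
  panel <- generate_lab_panel(3, seed = 7, dispersion = 0.1,
                              base = calibrated_base())
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_lab_panel(panel, path)
  back <- read_lab_panel(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(panel),
               tolerance = 1e-12)
})

test_that("scenarios: identity, multipliers, overrides, and range errors", {
  p <- calibrated_base()
  # empty spec is the identity on every field
  same <- apply_scenario(p, scenario_spec("base"))
  for (fld in parameter_fields()$field) {
    expect_identical(same[[fld]], p[[fld]], label = fld)
  }
  up <- apply_scenario(p, scenario_spec(
    multipliers = list(incremental_case_tariff = 1.10)))
  expect_equal(up$incremental_case_tariff, p$incremental_case_tariff * 1.10)
  z <- apply_scenario(p, scenario_spec(overrides = list(discount_rate = 0)))
  expect_equal(z$discount_rate, 0)
  expect_error(scenario_spec(multipliers = list(discount_rate = -1)),
               class = "dpnpv_validation_error")
  expect_error(scenario_spec(overrides = list(nope = 1)),
               class = "dpnpv_validation_error")
  expect_error(apply_scenario(p, scenario_spec(
    multipliers = list(digitized_share = 1.5))),
    regexp = "digitized_share", class = "dpnpv_validation_error")
  # original untouched
  expect_equal(p$incremental_case_tariff, calibrated_base()$incremental_case_tariff)
})
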