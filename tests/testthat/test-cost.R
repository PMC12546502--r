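test_that("scanner fleet follows the 75k-slide threshold rule", {
  # constant volume: fleet stays at the initial five, no purchases
  flat <- size_scanner_fleet(rep(300000, 8), 5, 75000)
  expect_equal(flat$fleet, rep(5, 8))
  expect_equal(flat$purchases, rep(0, 8))
  # one full increment crossed by Year 3
  v <- c(300000, 320000, 350000, 380000)
  f <- size_scanner_fleet(v, 5, 75000)
  expect_equal(f$fleet, c(5, 5, 5, 6))
  expect_equal(f$purchases, c(0, 0, 0, 1))
  # boundary: 74,999 extra slides do not trigger a purchase
  expect_equal(size_scanner_fleet(c(300000, 374999), 5, 75000)$fleet, c(5, 5))
  expect_equal(size_scanner_fleet(c(300000, 375000), 5, 75000)$fleet, c(5, 6))
  # ceiling option adds as soon as the threshold is touched
  expect_equal(size_scanner_fleet(c(300000, 300001), 5, 75000,
                                  rule = "ceiling")$fleet, c(5, 6))
})

test_that("fleet size is monotone in slide volumes and never shrinks", {
  set.seed(31)
  for (k in 1:20) {
    v <- stats::runif(8, 2e5, 6e5)
    f <- size_scanner_fleet(v, 5, 75000)
    expect_true(all(diff(f$fleet) >= 0))
    expect_true(all(f$purchases >= 0))
    # raising a later year's volume never lowers any year's fleet (Year 0
    # sets the threshold origin, so only operating years are perturbed)
    v2 <- v
    i <- sample(2:8, 1)
    v2[i] <- v2[i] + stats::runif(1, 0, 2e5)
    f2 <- size_scanner_fleet(v2, 5, 75000)
    expect_true(all(f2$fleet >= f$fleet))
  }
  expect_error(size_scanner_fleet(c(10, -5), 5, 75000),
               class = "dpnpv_validation_error")
})

test_that("zero unit costs give an all-zero investment schedule", {
  p <- lab_parameters(scanner_unit_cost = 0, scanner_maintenance_annual = 0,
                      workstation_unit_cost = 0, storage_it_initial = 0,
                      storage_it_annual = 0, software_setup = 0,
                      software_annual_viewer = 0, software_annual_casemgr_lis = 0,
                      technician_salary = 0)
  sched <- build_investment_schedule(p)
  expect_true(all(sched$nominal == 0))
})

test_that("doubling one unit cost doubles only its component stream", {
  p <- calibrated_base()
  s1 <- build_investment_schedule(p)
  p2 <- apply_scenario(p, scenario_spec(multipliers = list(
    storage_it_initial = 2, storage_it_annual = 2)))
  s2 <- build_investment_schedule(p2)
  expect_equal(s2$nominal[s2$component == "it_storage"],
               2 * s1$nominal[s1$component == "it_storage"])
  for (comp in c("hardware_equipment", "software", "personnel_increase")) {
    expect_identical(s2$nominal[s2$component == comp],
                     s1$nominal[s1$component == comp], label = comp)
  }
})

test_that("discounted component totals equal the explicit-loop oracle", {
  sched <- build_investment_schedule(calibrated_base())
  r <- calibrated_base()$discount_rate
  for (comp in unique(sched$component)) {
    rows <- sched[sched$component == comp, ]
    rows <- rows[order(rows$year), ]
    expect_equal(sum(rows$discounted),
                 sum(loop_discount(rows$nominal, r, shift = 1)),
                 tolerance = 1e-12, label = comp)
  }
})

test_that("Year 0 carries the capex; recurring lines start in Year 1", {
  p <- calibrated_base()
  sched <- build_investment_schedule(p)
  hw0 <- sched$nominal[sched$component == "hardware_equipment" & sched$year == 0]
  expect_equal(hw0, 5 * 277000 + p$workstation_count * 4211)
  sw <- sched$nominal[sched$component == "software"]
  expect_equal(sw, c(276000, rep(73000 + 137000, 7)))
  it <- sched$nominal[sched$component == "it_storage"]
  expect_equal(it, c(278000, rep(155000, 7)))
  expect_true(all(sched$capex[sched$year == 0 & sched$component != "personnel_increase"]))
})

test_that("parameters still flagged for calibration are refused by the cost engine", {
  raw <- base_case_parameters(calibrated = FALSE)
  expect_error(build_investment_schedule(raw), regexp = "calibration",
               class = "dpnpv_calibration_error")
})
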