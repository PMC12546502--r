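test_that("case projection: no growth and no capture give a flat series", {
  p <- lab_parameters(natural_growth_rate = 0, productivity_capture = 0)
  cv <- project_case_volume(p)
  expect_equal(cv$cases, rep(p$baseline_case_volume, 8))
})

test_that("natural growth alone reaches ~64.6k by Year 7 from 56k", {
  # closed form: 56000 * 1.0206^7; the capture ramp must supply the rest of
  # the published 75k
  p <- lab_parameters(productivity_capture = 0)
  cv <- project_case_volume(p)
  expect_equal(cv$cases[8], 56000 * 1.0206^7, tolerance = 1e-12)
  expect_lt(cv$cases[8], 65000)
  cal <- project_case_volume(calibrated_base())
  expect_equal(cal$cases[8], 75000, tolerance = 1e-9)
  expect_true(all(diff(cal$cases) > 0))
})

test_that("consultation projection is geometric when capture is zero", {
  p <- lab_parameters(consultation_growth_rate = 0, consultation_capture = 0)
  expect_equal(project_consultation_volume(p)$consultations, rep(2785, 8))
  q <- lab_parameters(consultation_growth_rate = 0.0977, consultation_capture = 0)
  cc <- project_consultation_volume(q)
  expect_equal(cc$consultations, 2785 * 1.0977^(0:7), tolerance = 1e-12)
  # calibrated base reproduces the published Year-7 consultation volume
  cal <- project_consultation_volume(calibrated_base())
  expect_equal(cal$consultations[8], 5348, tolerance = 1e-9)
})

test_that("zero tariffs and savings give an all-zero benefit schedule", {
  p <- lab_parameters(incremental_case_tariff = 0, consultation_tariff = 0,
                      pathologist_salary = 0, technician_salary = 0,
                      fte_saved_pathologist = 0, fte_saved_technician = 0,
                      equipment_savings_annual = 0)
  sched <- build_benefit_schedule(p)
  expect_true(all(sched$nominal == 0))
  expect_true(all(sched$discounted == 0))
})

test_that("exam benefit is linear in the incremental case tariff", {
  p <- calibrated_base()
  s1 <- build_benefit_schedule(p)
  p2 <- apply_scenario(p, scenario_spec(
    multipliers = list(incremental_case_tariff = 3)))
  s2 <- build_benefit_schedule(p2)
  exam1 <- s1$nominal[s1$component == "increased_exam_volume"]
  exam2 <- s2$nominal[s2$component == "increased_exam_volume"]
  expect_equal(exam2, 3 * exam1, tolerance = 1e-12)
  # other components untouched
  for (comp in c("secondary_consultations", "workforce_efficiency",
                 "equipment_reduction")) {
    expect_identical(s2$nominal[s2$component == comp],
                     s1$nominal[s1$component == comp], label = comp)
  }
})

test_that("benefit components are never negative; shrinkage is clamped with a warning", {
  p <- lab_parameters(natural_growth_rate = -0.05, productivity_capture = 0)
  expect_warning(sched <- build_benefit_schedule(p), regexp = "clamped")
  expect_true(all(sched$nominal >= 0))
  # and under arbitrary validated parameters, streams stay non-negative
  set.seed(21)
  for (k in 1:10) {
    q <- lab_parameters(
      natural_growth_rate = stats::runif(1, 0, 0.1),
      productivity_capture = stats::runif(1, 0, 0.5),
      incremental_case_tariff = stats::runif(1, 0, 200),
      consultation_growth_rate = stats::runif(1, 0, 0.15),
      equipment_savings_annual = stats::runif(1, 0, 5e4))
    expect_true(all(build_benefit_schedule(q)$nominal >= 0))
  }
})

test_that("at a zero discount rate the workforce total is the plain sum of yearly savings", {
  p <- apply_scenario(calibrated_base(),
                      scenario_spec(overrides = list(discount_rate = 0)))
  sched <- build_benefit_schedule(p)
  wf <- sched[sched$component == "workforce_efficiency", ]
  expect_identical(sum(wf$discounted), sum(wf$nominal))
})

test_that("equipment savings start in Year 1, not in the startup year", {
  sched <- build_benefit_schedule(calibrated_base())
  eq <- sched[sched$component == "equipment_reduction", ]
  expect_equal(eq$nominal[eq$year == 0], 0)
  expect_true(all(eq$nominal[eq$year > 0] > 0))
})

test_that("schedule totals equal the component-wise sum year by year", {
  sched <- build_benefit_schedule(calibrated_base())
  per_year <- dplyr::summarise(dplyr::group_by(sched, year),
                               total = sum(nominal), .groups = "drop")
  bc <- base_bc()
  expect_equal(bc$cashflow$benefits, per_year$total)
})
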