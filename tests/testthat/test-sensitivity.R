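test_that("tornado: zero span gives zero deltas; ranks are a permutation", {
  p <- calibrated_base()
  t0 <- tornado_sensitivity(p, span = 0)
  expect_true(all(t0$delta == 0))
  t1 <- tornado_sensitivity(p, span = 0.2)
  expect_setequal(t1$rank, seq_len(nrow(t1)))
  expect_true(all(diff(t1$swing) <= 0))  # sorted by swing, descending
  expect_equal(attr(t1, "baseline_npv"), base_bc()$npv)
})

test_that("growth and case-processing efficiency dominate equipment savings", {
  t1 <- tornado_sensitivity(calibrated_base(),
                            drivers = list(
                              growth_and_productivity = c("natural_growth_rate",
                                                          "productivity_capture"),
                              equipment_savings = "equipment_savings_annual"),
                            span = 0.2)
  swing <- stats::setNames(t1$swing, t1$driver)
  expect_gt(swing[["growth_and_productivity"]], swing[["equipment_savings"]])
  expect_equal(t1$driver[1], "growth_and_productivity")
})

test_that("NPV responds linearly to the incremental case tariff", {
  p <- calibrated_base()
  t1 <- tornado_sensitivity(p, drivers = list(tariff = "incremental_case_tariff"),
                            span = 0.2)
  exam_npv <- component_totals(base_bc()$benefits)
  exam_npv <- exam_npv$discounted[exam_npv$component == "increased_exam_volume"]
  expect_equal(t1$npv_high - attr(t1, "baseline_npv"), 0.2 * exam_npv,
               tolerance = 1e-9)
  expect_equal(t1$delta, 0.4 * exam_npv, tolerance = 1e-9)
})

test_that("unknown tornado drivers are rejected with guidance", {
  expect_error(tornado_sensitivity(calibrated_base(),
                                   drivers = list(x = "no_such_field")),
               regexp = "parameter_fields", class = "dpnpv_validation_error")
})

test_that("scenario runs: best beats base beats worst", {
  sc <- run_scenarios(calibrated_base())
  expect_equal(sc$scenario, c("base", "best", "worst"))
  expect_gt(sc$npv[sc$scenario == "best"], sc$npv[sc$scenario == "base"])
  expect_gt(sc$npv[sc$scenario == "base"], sc$npv[sc$scenario == "worst"])
  expect_equal(sc$npv[sc$scenario == "base"], base_bc()$npv)
})

test_that("PSA: degenerate distributions collapse to the base NPV with zero variance", {
  p <- calibrated_base()
  dists <- list(psa_dist("incremental_case_tariff", "fixed"),
                psa_dist("natural_growth_rate", "uniform", rel_halfwidth = 0))
  out <- monte_carlo_psa(p, dists, n = 25, seed = 9)
  expect_equal(out$summary$sd_npv, 0)
  expect_true(all(out$draws$npv == base_bc()$npv))
})

test_that("PSA is bit-reproducible under a fixed seed", {
  p <- calibrated_base()
  dists <- default_psa_distributions()
  a <- monte_carlo_psa(p, dists, n = 40, seed = 123)
  b <- monte_carlo_psa(p, dists, n = 40, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c <- monte_carlo_psa(p, dists, n = 40, seed = 124)
  expect_false(identical(a$draws$npv, c$draws$npv))
})

test_that("a symmetric uniform on a linear driver keeps the PSA mean near base", {
  p <- calibrated_base()
  out <- monte_carlo_psa(p, list(psa_dist("incremental_case_tariff", "uniform",
                                          rel_halfwidth = 0.1)),
                         n = 200, seed = 5)
  se <- out$summary$sd_npv / sqrt(out$n)
  expect_lt(abs(out$summary$mean_npv - base_bc()$npv), 4 * se)
  expect_true(out$summary$q025 <= out$summary$q975)
})

test_that("bound-violating PSA distributions are rejected before any draw", {
  expect_error(
    monte_carlo_psa(calibrated_base(),
                    list(psa_dist("digitized_share", "uniform",
                                  rel_halfwidth = 0.3)),
                    n = 10, seed = 1),
    regexp = "digitized_share", class = "dpnpv_validation_error")
})

test_that("PSA leaves the caller's RNG stream untouched", {
  set.seed(77)
  before <- stats::runif(1)
  set.seed(77)
  invisible(monte_carlo_psa(calibrated_base(),
                            list(psa_dist("incremental_case_tariff", "uniform")),
                            n = 5, seed = 3))
  after <- stats::runif(1)
  expect_identical(before, after)
})
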