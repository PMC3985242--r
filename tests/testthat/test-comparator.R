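fx <- iran_rtt_2011()

test_that("the hemodialysis arm reproduces the published annual costs", {
  d <- dialysis_annual_cost(fx$dialysis, fx$rate)
  expect_identical(d$components_irr[["dialysis"]], 255066240000)
  expect_identical(d$components_irr[["adjunct_treatment"]], 46706880000)
  expect_identical(d$total_irr, 301773120000)
  expect_identical(d$per_patient_irr, 137169600)
  expect_identical(d$per_patient_usd, 11188)
  expect_identical(d$components_usd[["dialysis"]], 20804750)
  expect_identical(d$components_usd[["adjunct_treatment"]], 3809697)
  expect_identical(d$total_usd, 24614447)

  none <- dialysis_arm(743200, sessions_per_year = 0,
                       adjunct_annual_per_patient = 0,
                       cohort = fx$strategy$cohort)
  expect_identical(dialysis_annual_cost(none)$total_irr, 0)
})

test_that("dialysis costs about twice as much per patient as transplantation", {
  rtt <- strategy_report(fx$strategy, fx$rate)
  hd <- dialysis_annual_cost(fx$dialysis, fx$rate)
  cmp <- compare_strategies(rtt, hd)
  expect_identical(cmp$per_patient_irr[["a"]], 77599240)
  expect_identical(cmp$per_patient_irr[["b"]], 137169600)
  expect_equal(cmp$per_patient_ratio$value, 137169600 / 77599240)
  expect_gt(cmp$per_patient_ratio$value, 1.7)
  expect_lt(cmp$per_patient_ratio$value, 2)
  # the reduced fraction reproduces the ratio exactly
  expect_identical(cmp$per_patient_ratio$num / cmp$per_patient_ratio$den,
                   cmp$per_patient_ratio$value)
})

test_that("comparison is antisymmetric and zero on identical arms", {
  a <- strategy_report(fx$strategy, fx$rate)
  b <- dialysis_annual_cost(fx$dialysis, fx$rate)
  ab <- compare_strategies(a, b)
  ba <- compare_strategies(b, a)
  expect_identical(ab$incremental_total_irr, -ba$incremental_total_irr)
  expect_identical(ab$incremental_per_patient_irr,
                   -ba$incremental_per_patient_irr)
  aa <- compare_strategies(a, a)
  expect_identical(aa$incremental_total_irr, 0)
  expect_identical(aa$incremental_per_patient_irr, 0)
  expect_true(all(aa$delta_components_irr == 0))
  expect_identical(aa$per_patient_ratio$value, 1)
})

test_that("adding one line moves the increment by exactly its cost", {
  s <- fx$strategy
  extra <- regimen_line("new-drug", units_per_day = 2, unit_price = 5000,
                        n_eligible = 2200, duration_days = 365)
  s2 <- strategy_definition(s$name, s$cohort, s$hospitalization,
                            s$maintenance, s$adverse_events,
                            c(s$misc, list(extra)))
  cmp <- compare_strategies(strategy_report(s, fx$rate),
                            strategy_report(s2, fx$rate))
  expect_identical(cmp$incremental_total_irr,
                   regimen_line_cohort_cost(extra))
  expect_identical(cmp$delta_components_irr[["miscellaneous"]],
                   regimen_line_cohort_cost(extra))
})

test_that("mismatched cohorts warn but still compare per patient", {
  a <- strategy_report(fx$strategy, fx$rate)
  small <- strategy_definition("small", cohort_spec(1100),
                               hospitalization = global_tariff(60000, 650))
  b <- strategy_report(small, fx$rate)
  expect_warning(cmp <- compare_strategies(a, b), "cohort sizes differ")
  expect_identical(cmp$per_patient_irr[["b"]], 39000000)
  expect_length(cmp$warnings, 1)
})
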