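# Deterministic engine vs the published 2011-2012 tariff tables.

fx <- iran_rtt_2011()

test_that("the global tariff and hospitalization component reproduce exactly", {
  t <- global_tariff(60000, 650)
  expect_identical(global_tariff_total(t), 39000000)
  expect_identical(global_tariff_total(global_tariff(0, 650)), 0)
  expect_identical(global_tariff_total(global_tariff(60000, 1)), 60000)
  expect_identical(hospitalization_cohort_cost(t, cohort_spec(2200)),
                   85800000000)
  expect_identical(hospitalization_cohort_cost(t, cohort_spec(1)), 39000000)
  expect_identical(hospitalization_cohort_cost(t, cohort_spec(0)), 0)
})

test_that("maintenance regimen lines reproduce the published line costs", {
  cases <- list( # drug, expected cohort cost (IRR)
    list(drug = "Cyclosporine (generic)", cost = 1886247000),
    list(drug = "Mycophenolate mofetil", cost = 35332000000),
    list(drug = "Prednisolone", cost = 104390000),
    list(drug = "Tacrolimus", cost = 2248400000)
  )
  lines <- fx$strategy$maintenance
  names(lines) <- vapply(lines, `[[`, character(1), "drug")
  for (cs in cases) {
    expect_identical(regimen_line_cohort_cost(lines[[cs$drug]]), cs$cost)
  }
  expect_identical(maintenance_total(lines), 39571037000)
  expect_identical(maintenance_total(list()), 0)
  # a line nobody is eligible for costs nothing
  expect_identical(regimen_line_cohort_cost(
    regimen_line("x", units_per_day = 2, unit_price = 100, n_eligible = 0,
                 duration_days = 365)), 0)
})

test_that("treatment items cost per their kind-specific formula", {
  expect_identical(treatment_item_cost(
    treatment_item("drug_course", "Ganciclovir", 250000, duration = 7,
                   units_per_day = 2)), 3500000)
  expect_identical(treatment_item_cost(
    treatment_item("procedure", "Dialysis", 743200, duration = 10)),
    7432000)
  expect_identical(treatment_item_cost(
    treatment_item("hospitalization", "Hospitalization", 1600000,
                   duration = 7)), 11200000)
  expect_identical(treatment_item_cost(
    treatment_item("fixed_tariff", "Re-transplantation", 39000000)),
    39000000)
})

test_that("adverse-event bundles sum to the published per-patient unit costs", {
  expected <- c("CMV" = 14700000, "Other infections" = 651600,
                "Delayed graft function" = 26729600,
                "Acute rejection" = 29750000, "Hyperlipidemia" = 401500,
                "Hypertension" = 54750, "Graft failure" = 46432000,
                "Thrombocytopenia" = 13000000)
  aes <- fx$strategy$adverse_events
  names(aes) <- vapply(aes, `[[`, character(1), "name")
  for (nm in names(expected)) {
    expect_identical(ae_unit_cost_per_patient(aes[[nm]]), expected[[nm]],
                     info = nm)
  }
  expect_identical(sum(vapply(aes, ae_unit_cost_per_patient, numeric(1))),
                   131719450)
  expect_identical(
    ae_unit_cost_per_patient(adverse_event_profile("none", 0.5)), 0)
})

test_that("expected AE costs follow the rounding policy of the published table", {
  aes <- fx$strategy$adverse_events
  names(aes) <- vapply(aes, `[[`, character(1), "name")
  cohort <- fx$strategy$cohort

  cmv <- ae_expected_costs(aes[["CMV"]], cohort)
  expect_identical(cmv$expected_exact, 3087000)
  expect_identical(cmv$expected_display, 3087000)
  expect_identical(cmv$cohort_total, 6791400000)

  # half-Rial expectation: display rounds up, cohort total stays exact
  ht <- ae_expected_costs(aes[["Hypertension"]], cohort)
  expect_identical(ht$expected_exact, 36682.5)
  expect_identical(ht$expected_display, 36683)
  expect_identical(ht$cohort_total, 80701500)
  expect_identical(ht$cohort_total_exact, 80701500)

  # a certain event contributes its full bundle cost
  oi <- ae_expected_costs(aes[["Other infections"]], cohort)
  expect_identical(oi$expected_display, 651600)
  expect_identical(oi$cohort_total, 1433520000)

  zero <- ae_expected_costs(adverse_event_profile("never", 0, aes[["CMV"]]$items),
                            cohort)
  expect_identical(zero$expected_display, 0)
  expect_identical(zero$cohort_total, 0)
})

test_that("AE component totals split the rounded and unrounded paths", {
  cohort <- fx$strategy$cohort
  tot <- ae_component_totals(fx$strategy$adverse_events, cohort)
  expect_identical(tot$per_patient_total_display, 19645885)
  expect_identical(tot$per_patient_total_exact, 19645884.5)
  expect_identical(tot$cohort_total, 43220945900)
  expect_identical(ae_component_totals(list(), cohort)$cohort_total, 0)
  one <- ae_component_totals(fx$strategy$adverse_events[1], cohort)
  expect_identical(one$per_patient_total_display, 3087000)
  expect_identical(one$cohort_total, 6791400000)
})

test_that("the strategy report reproduces the published summary table", {
  rep <- strategy_report(fx$strategy, fx$rate)
  expect_identical(unname(rep$components_irr),
                   c(85800000000, 39571037000, 43220945900, 2126344000))
  expect_identical(rep$total_irr, 170718326900)
  expect_identical(rep$per_patient_irr_exact, 77599239.5)
  expect_identical(rep$per_patient_irr, 77599240)
  expect_identical(unname(rep$components_usd),
                   c(6998369, 3227654, 3525363, 173438))
  expect_identical(rep$total_usd, 13924823)
  expect_identical(rep$per_patient_usd, 6329)
  # component shares: hospitalization ~50%, immuno ~23%, AEs ~25%, misc ~1%
  expect_equal(unname(round(rep$shares * 100)), c(50, 23, 25, 1))
  expect_gt(rep$shares[["hospitalization"]], 0.5)
})

test_that("degenerate strategies behave", {
  empty <- strategy_definition("empty", cohort_spec(10))
  rep <- strategy_report(empty)
  expect_identical(rep$total_irr, 0)
  expect_identical(rep$per_patient_irr, 0)
  expect_identical(rep$total_usd, 0)

  # zero patients with real costs has no per-patient interpretation
  # (the misc line's eligibility does not scale with the cohort)
  s <- strategy_definition(
    "bad", cohort_spec(0),
    misc = list(regimen_line("x", units_per_day = 1, unit_price = 100,
                             n_eligible = 5, duration_days = 10)))
  expect_error(strategy_report(s), "undefined")
})
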