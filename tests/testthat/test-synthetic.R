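test_that("generation is reproducible from the seed", {
  a <- generate_strategy(generator_spec(seed = 77))
  b <- generate_strategy(generator_spec(seed = 77))
  expect_identical(a, b)
  c <- generate_strategy(generator_spec(seed = 78))
  expect_false(identical(a, c))
})

test_that("every generated strategy is valid and costs are finite and non-negative", {
  for (seed in 1:50) {
    s <- generate_strategy(generator_spec(seed = seed))
    expect_s3_class(s, "strategy_definition")
    expect_true(all(vapply(s$adverse_events, function(a) {
      a$probability >= 0 && a$probability <= 1 && length(a$items) >= 1
    }, logical(1))))
    rep <- strategy_report(s)
    expect_true(is.finite(rep$total_irr))
    expect_gte(rep$total_irr, 0)
    expect_true(all(rep$components_irr >= 0))
    expect_identical(rep$total_irr, sum(rep$components_irr))
  }
})

test_that("generator ranges are honoured", {
  spec <- generator_spec(seed = 5, n_events = c(8, 8),
                         probability_range = c(0.2, 0.4))
  s <- generate_strategy(spec)
  expect_length(s$adverse_events, 8)
  p <- vapply(s$adverse_events, `[[`, numeric(1), "probability")
  expect_true(all(p >= 0.2 & p <= 0.4))
})

test_that("certain events make simulation exactly analytic", {
  s <- generate_strategy(generator_spec(seed = 3,
                                        probability_range = c(1, 1)))
  sim <- simulate_cohort(simulation_config(100, 10, seed = 4),
                         s$adverse_events)
  expect_identical(sim$sd, 0)
  expect_identical(unique(sim$replicate_means), sim$analytic_expectation)
})

test_that("engine totals agree with the brute-force rational oracle", {
  for (seed in 1:100) {
    s <- generate_strategy(generator_spec(seed = seed))
    o <- oracle_strategy_totals(s)
    rep <- strategy_report(s)
    expect_identical(rep$total_irr, o$total, info = paste("seed", seed))
    expect_identical(rep$components_irr[["adverse_events"]],
                     o$adverse_events)
    expect_identical(rep$ae_per_patient_total_display,
                     o$ae_per_patient_display)
  }
})

test_that("price jitter keeps prices whole and strategies valid", {
  s <- generate_strategy(generator_spec(seed = 12, price_jitter_cv = 0.3))
  rep <- strategy_report(s)
  expect_true(is.finite(rep$total_irr))
  expect_identical(rep$total_irr, floor(rep$total_irr))
})

test_that("the bundled reference inputs match the study design", {
  fx <- iran_rtt_2011()
  expect_length(fx$strategy$adverse_events, 8)
  expect_setequal(
    vapply(fx$strategy$adverse_events, `[[`, numeric(1), "probability"),
    c(0.21, 1, 0.17, 0.18, 0.14, 0.67, 0.105, 0.08))
  expect_identical(fx$strategy$cohort$n_patients, 2200)
  expect_length(fx$strategy$maintenance, 4)
  expect_length(fx$strategy$misc, 5)
  expect_identical(maintenance_total(fx$strategy$misc), 2126344000)
  expect_identical(fx$rate, 12260)
  expect_identical(fx$dialysis$sessions_per_year, 156)
})
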