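# Randomized, structurally valid strategy generation for property testing,
# plus the bundled 2011-2012 Iranian transplant-cohort input set.
#
# The generator's job is structural coverage of the input space (the
# Bernoulli event layer over fixed per-event cost bundles), not clinical
# realism: prices and durations are drawn uniformly on integer ranges and
# probabilities on a thousandths grid, so every generated strategy stays
# in exact decimal arithmetic unless price jitter is switched on.

#' Generator specification for synthetic strategies
#'
#' All ranges are inclusive `c(lo, hi)` integer ranges except
#' `probability_range`, a sub-interval of \[0, 1\] sampled on a 1/1000
#' grid.  `price_jitter_cv` (default 0) applies multiplicative log-normal
#' noise to unit prices, rounded back to whole Rials; it exists to
#' stress-test the rounding policy and is off by default so synthetic
#' tests remain exact.
#'
#' @param seed RNG seed.
#' @param n_events Range for the number of adverse-event profiles.
#' @param n_items_per_event Range for items per event bundle.
#' @param probability_range Sub-interval of \[0, 1\].
#' @param unit_price_range Range of unit prices in IRR.
#' @param duration_range Range of durations (days or sessions).
#' @param n_maintenance_lines Range for the number of maintenance lines.
#' @param cohort_size_range Range for the cohort size.
#' @param price_jitter_cv Coefficient of variation of optional price noise.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed, n_events = c(1, 5),
                           n_items_per_event = c(1, 4),
                           probability_range = c(0, 1),
                           unit_price_range = c(100, 1000000),
                           duration_range = c(1, 30),
                           n_maintenance_lines = c(0, 4),
                           cohort_size_range = c(10, 5000),
                           price_jitter_cv = 0) {
  assert_count(seed, "seed", min = -.Machine$integer.max)
  chk_range <- function(r, what, lo_min = 0) {
    if (!is.numeric(r) || length(r) != 2L || any(r != floor(r)) ||
        r[1] > r[2] || r[1] < lo_min) {
      stop("`", what, "` must be an integer range c(lo, hi) with lo >= ",
           lo_min, call. = FALSE)
    }
  }
  chk_range(n_events, "n_events")
  chk_range(n_items_per_event, "n_items_per_event", lo_min = 1)
  chk_range(unit_price_range, "unit_price_range", lo_min = 1)
  chk_range(duration_range, "duration_range", lo_min = 1)
  chk_range(n_maintenance_lines, "n_maintenance_lines")
  chk_range(cohort_size_range, "cohort_size_range", lo_min = 1)
  if (!is.numeric(probability_range) || length(probability_range) != 2L ||
      probability_range[1] < 0 || probability_range[2] > 1 ||
      probability_range[1] > probability_range[2]) {
    stop("`probability_range` must be a sub-interval of [0, 1]",
         call. = FALSE)
  }
  assert_nonneg(price_jitter_cv, "price_jitter_cv")
  structure(
    list(seed = seed, n_events = n_events,
         n_items_per_event = n_items_per_event,
         probability_range = probability_range,
         unit_price_range = unit_price_range,
         duration_range = duration_range,
         n_maintenance_lines = n_maintenance_lines,
         cohort_size_range = cohort_size_range,
         price_jitter_cv = price_jitter_cv),
    class = "generator_spec"
  )
}

sample_int_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
}

#' Generate a random, valid therapy strategy
#'
#' Deterministic given the spec's seed.  Every generated adverse event has
#' a probability inside the spec's range (on a thousandths grid) and at
#' least one treatment item; all objects pass their type invariants and
#' the result serializes and reads back identically.
#'
#' @param spec A [generator_spec()].
#' @return A [strategy_definition()].
#' @export
generate_strategy <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  n <- sample_int_range(spec$cohort_size_range)
  cohort <- cohort_spec(n)

  price <- function() {
    p <- sample_int_range(spec$unit_price_range)
    if (spec$price_jitter_cv > 0) {
      p <- max(1, round_half_away(p * exp(stats::rnorm(1, 0,
                                                       spec$price_jitter_cv))))
    }
    p
  }

  hosp <- global_tariff(k_value = price(),
                        multiplier = sample_int_range(c(1, 1000)))

  make_line <- function(i, prefix) {
    if (stats::runif(1) < 0.2) {
      regimen_line(drug = paste0(prefix, "-", i),
                   duration_days = sample_int_range(spec$duration_range),
                   cohort_daily_cost = price() * sample_int_range(c(1, 50)))
    } else {
      regimen_line(drug = paste0(prefix, "-", i),
                   units_per_day = sample_int_range(c(1, 6)),
                   unit_price = price(),
                   n_eligible = sample_int_range(c(0, n)),
                   duration_days = sample_int_range(spec$duration_range))
    }
  }
  maint <- lapply(seq_len(sample_int_range(spec$n_maintenance_lines)),
                  make_line, prefix = "maint")
  misc <- lapply(seq_len(sample_int_range(c(0, 3))), make_line,
                 prefix = "misc")

  grid_lo <- ceiling(spec$probability_range[1] * 1000)
  grid_hi <- floor(spec$probability_range[2] * 1000)
  if (grid_lo > grid_hi) grid_lo <- grid_hi <- round(
    spec$probability_range[1] * 1000)

  make_item <- function(j) {
    kind <- sample(c("drug_course", "procedure", "hospitalization",
                     "fixed_tariff"), 1L)
    treatment_item(
      kind = kind, label = paste0("item-", j), unit_price = price(),
      duration = if (kind == "fixed_tariff") 0 else
        sample_int_range(spec$duration_range),
      units_per_day = if (kind == "drug_course")
        sample_int_range(c(1, 6)) else 0
    )
  }
  aes <- lapply(seq_len(sample_int_range(spec$n_events)), function(i) {
    adverse_event_profile(
      name = paste0("event-", i),
      probability = sample_int_range(c(grid_lo, grid_hi)) / 1000,
      items = lapply(seq_len(sample_int_range(spec$n_items_per_event)),
                     make_item)
    )
  })

  strategy_definition(
    name = paste0("synthetic-", spec$seed),
    cohort = cohort, hospitalization = hosp,
    maintenance = maint, adverse_events = aes, misc = misc
  )
}

#' Bundled 2011-2012 Iranian renal-transplantation inputs
#'
#' Reads the configuration shipped with the package describing the
#' 2011-2012 Iranian incident transplant cohort (2,200 patients): the
#' 650 x 60,000 IRR global hospitalization tariff, the four maintenance
#' immunosuppressive lines, the eight adverse-event profiles with their
#' treatment bundles and first-year probabilities, the five miscellaneous
#' medication lines, and the hemodialysis comparator tariffs, at the
#' study-year exchange rate of 12,260 IRR per USD.
#'
#' @return A list with `strategy` (a [strategy_definition()]), `dialysis`
#'   (a [dialysis_arm()]) and `rate` (IRR per USD).
#' @export
#' @examples
#' fx <- iran_rtt_2011()
#' strategy_report(fx$strategy, fx$rate)$total_irr
iran_rtt_2011 <- function() {
  path <- system.file("extdata", "iran_rtt_2011.yaml", package = "txcost",
                      mustWork = TRUE)
  read_config(path)
}
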