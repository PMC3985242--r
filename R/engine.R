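# Deterministic cost engine.
#
# Rounding policy (applied consistently everywhere):
#   * per-event expected cost per patient: exact rational p x unit_cost;
#     the display value rounds half away from zero, but cohort totals are
#     computed from the UNROUNDED expectation and rounded only at the end;
#   * per-patient strategy totals: cohort total / n, half away from zero;
#   * USD: IRR / rate, half away from zero.

#' Total value of a global tariff
#'
#' @param t A [global_tariff()].
#' @return `multiplier * k_value`, in IRR.
#' @export
#' @examples
#' global_tariff_total(global_tariff(60000, 650))  # 39,000,000
global_tariff_total <- function(t) {
  stopifnot(inherits(t, "global_tariff"))
  t$multiplier * t$k_value
}

#' Cohort cost of initial hospitalization
#'
#' The global tariff is paid once per transplanted patient (one
#' recipient-donor operation pair each).
#'
#' @param t A [global_tariff()].
#' @param cohort A [cohort_spec()].
#' @return Cohort hospitalization cost in IRR.
#' @export
hospitalization_cohort_cost <- function(t, cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  global_tariff_total(t) * cohort$n_patients
}

#' Cohort cost of one regimen line
#'
#' `units_per_day * unit_price * n_eligible * duration_days`, or
#' `cohort_daily_cost * duration_days` when the override is set.
#'
#' @param line A [regimen_line()].
#' @return Cohort cost in IRR.
#' @export
regimen_line_cohort_cost <- function(line) {
  stopifnot(inherits(line, "regimen_line"))
  if (!is.null(line$cohort_daily_cost)) {
    return(line$cohort_daily_cost * line$duration_days)
  }
  cost <- line$units_per_day * line$unit_price * line$n_eligible *
    line$duration_days
  if (cost != floor(cost)) {
    stop("regimen line `", line$drug, "` yields a fractional Rial total; ",
         "use a cohort_daily_cost override for mixed dosing", call. = FALSE)
  }
  cost
}

#' Total cohort cost of a list of regimen lines
#'
#' @param lines List of [regimen_line()] objects; may be empty.
#' @return Sum of [regimen_line_cohort_cost()] over the lines, in IRR.
#' @export
maintenance_total <- function(lines) {
  if (length(lines) == 0) return(0)
  sum(vapply(lines, regimen_line_cohort_cost, numeric(1)))
}

#' Cost of one adverse-event treatment item
#'
#' Drug courses cost units/day x price x days; procedures price x
#' sessions; hospitalization price/day x days; fixed tariffs their amount.
#'
#' @param item A [treatment_item()].
#' @return Item cost in IRR.
#' @export
treatment_item_cost <- function(item) {
  stopifnot(inherits(item, "treatment_item"))
  cost <- switch(item$kind,
    drug_course = item$units_per_day * item$unit_price * item$duration,
    procedure = item$unit_price * item$duration,
    hospitalization = item$unit_price * item$duration,
    fixed_tariff = item$unit_price
  )
  if (cost != floor(cost)) {
    stop("treatment item `", item$label, "` yields a fractional Rial cost",
         call. = FALSE)
  }
  cost
}

#' Treatment cost per affected patient for an adverse event
#'
#' @param ae An [adverse_event_profile()].
#' @return Sum of the bundle's item costs, in IRR.
#' @export
ae_unit_cost_per_patient <- function(ae) {
  stopifnot(inherits(ae, "ae_profile"))
  if (length(ae$items) == 0) return(0)
  sum(vapply(ae$items, treatment_item_cost, numeric(1)))
}

#' Expected adverse-event costs, per patient and for the cohort
#'
#' The expected cost per patient is `probability x unit cost`, computed as
#' an exact decimal rational.  The displayed per-patient value rounds that
#' expectation half away from zero; the cohort total multiplies the
#' unrounded expectation by `n_patients` and rounds only at the end (so a
#' half-Rial expectation still yields an exact cohort total whenever the
#' product is whole).
#'
#' @param ae An [adverse_event_profile()].
#' @param cohort A [cohort_spec()].
#' @return A list with `unit_cost`, `expected_exact` (possibly
#'   fractional), `expected_display`, `cohort_total_exact` and
#'   `cohort_total` (rounded at the end), all in IRR.
#' @export
ae_expected_costs <- function(ae, cohort) {
  stopifnot(inherits(ae, "ae_profile"), inherits(cohort, "cohort_spec"))
  unit <- ae_unit_cost_per_patient(ae)
  num <- ae$prob_num * unit
  den <- ae$prob_den
  list(
    unit_cost = unit,
    expected_exact = num / den,
    expected_display = ratio_round_half_away(num, den),
    cohort_total_exact = num * cohort$n_patients / den,
    cohort_total = ratio_round_half_away(num * cohort$n_patients, den)
  )
}

#' Adverse-event component totals
#'
#' The per-patient column total sums the per-event *displayed* (rounded)
#' expectations, matching how the per-patient column of a published cost
#' table is totalled; the cohort total sums the per-event cohort totals,
#' each of which is based on the unrounded expectation.
#'
#' @param aes List of [adverse_event_profile()] objects.
#' @param cohort A [cohort_spec()].
#' @return A list with `per_patient_total_display`, `per_patient_total_exact`
#'   and `cohort_total`, in IRR.
#' @export
ae_component_totals <- function(aes, cohort) {
  if (length(aes) == 0) {
    return(list(per_patient_total_display = 0, per_patient_total_exact = 0,
                cohort_total = 0))
  }
  per <- lapply(aes, ae_expected_costs, cohort = cohort)
  list(
    per_patient_total_display =
      sum(vapply(per, `[[`, numeric(1), "expected_display")),
    per_patient_total_exact =
      sum(vapply(per, `[[`, numeric(1), "expected_exact")),
    cohort_total = sum(vapply(per, `[[`, numeric(1), "cohort_total"))
  )
}

#' Full cost report for a therapy strategy
#'
#' Computes the four component totals (initial hospitalization,
#' immunosuppressive maintenance, adverse-event treatment, miscellaneous
#' medicines), the cohort grand total, the per-patient cost, component
#' shares of the total, and USD conversions of every figure, plus a
#' per-event adverse-event breakdown.
#'
#' @param s A [strategy_definition()].
#' @param rate Exchange rate in IRR per USD (default 12,260, the study
#'   year's official rate).
#' @return An object of class `cost_report`; see Details.
#' @details The report is a list with `components_irr` and
#'   `components_usd` (named vectors over `hospitalization`,
#'   `immunosuppressive`, `adverse_events`, `miscellaneous`), `total_irr`,
#'   `total_usd`, `per_patient_irr_exact`, `per_patient_irr`,
#'   `per_patient_usd`, `shares` (fractions of the total), an
#'   `ae_breakdown` data frame, `ae_per_patient_total_display`,
#'   `n_patients` and `rate`.
#' @export
strategy_report <- function(s, rate = 12260) {
  stopifnot(inherits(s, "strategy_definition"))
  n <- s$cohort$n_patients
  hosp <- if (is.null(s$hospitalization)) 0 else
    hospitalization_cohort_cost(s$hospitalization, s$cohort)
  maint <- maintenance_total(s$maintenance)
  aet <- ae_component_totals(s$adverse_events, s$cohort)
  misc <- maintenance_total(s$misc)

  components <- c(hospitalization = hosp, immunosuppressive = maint,
                  adverse_events = aet$cohort_total, miscellaneous = misc)
  total <- sum(components)

  if (n == 0 && total > 0) {
    stop("per-patient cost is undefined: zero patients with non-zero costs",
         call. = FALSE)
  }
  pp_exact <- if (n == 0) 0 else total / n
  pp_disp <- if (n == 0) 0 else ratio_round_half_away(total, n)

  breakdown <- if (length(s$adverse_events) > 0) {
    per <- lapply(s$adverse_events, ae_expected_costs, cohort = s$cohort)
    data.frame(
      event = vapply(s$adverse_events, `[[`, character(1), "name"),
      probability = vapply(s$adverse_events, `[[`, numeric(1), "probability"),
      unit_cost_irr = vapply(per, `[[`, numeric(1), "unit_cost"),
      expected_per_patient_irr =
        vapply(per, `[[`, numeric(1), "expected_display"),
      cohort_total_irr = vapply(per, `[[`, numeric(1), "cohort_total"),
      cohort_total_usd =
        vapply(per, function(p) to_usd(p$cohort_total, rate), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(event = character(), probability = numeric(),
               unit_cost_irr = numeric(), expected_per_patient_irr = numeric(),
               cohort_total_irr = numeric(), cohort_total_usd = numeric(),
               stringsAsFactors = FALSE)
  }

  structure(
    list(
      strategy = s$name,
      n_patients = n,
      rate = rate,
      components_irr = components,
      total_irr = total,
      per_patient_irr_exact = pp_exact,
      per_patient_irr = pp_disp,
      components_usd = vapply(components, to_usd, numeric(1), rate = rate),
      total_usd = to_usd(total, rate),
      per_patient_usd = to_usd(pp_disp, rate),
      shares = if (total > 0) components / total else components * 0,
      ae_breakdown = breakdown,
      ae_per_patient_total_display = aet$per_patient_total_display,
      ae_per_patient_total_exact = aet$per_patient_total_exact
    ),
    class = "cost_report"
  )
}
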