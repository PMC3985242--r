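# Hemodialysis comparator arm and incremental strategy comparison.

#' Annual cost report for the hemodialysis arm
#'
#' Costs the scenario in which the whole cohort receives hospital-based
#' hemodialysis for a year instead of transplantation: session tariff x
#' sessions/year x patients, plus the annual adjunct medication bundle per
#' patient.  Adverse events are excluded from this arm.
#'
#' @param arm A [dialysis_arm()].
#' @param rate Exchange rate in IRR per USD.
#' @return A `cost_report` with components `dialysis` and
#'   `adjunct_treatment`.
#' @export
dialysis_annual_cost <- function(arm, rate = 12260) {
  stopifnot(inherits(arm, "dialysis_arm"))
  n <- arm$cohort$n_patients
  components <- c(
    dialysis = arm$session_tariff * arm$sessions_per_year * n,
    adjunct_treatment = arm$adjunct_annual_per_patient * n
  )
  total <- sum(components)
  if (n == 0 && total > 0) {
    stop("per-patient cost is undefined: zero patients with non-zero costs",
         call. = FALSE)
  }
  structure(
    list(
      strategy = "hemodialysis",
      n_patients = n,
      rate = rate,
      components_irr = components,
      total_irr = total,
      per_patient_irr_exact = if (n == 0) 0 else total / n,
      per_patient_irr = if (n == 0) 0 else ratio_round_half_away(total, n),
      components_usd = vapply(components, to_usd, numeric(1), rate = rate),
      total_usd = to_usd(total, rate),
      per_patient_usd = if (n == 0) 0 else
        to_usd(ratio_round_half_away(total, n), rate),
      shares = if (total > 0) components / total else components * 0,
      ae_breakdown = data.frame(),
      ae_per_patient_total_display = 0,
      ae_per_patient_total_exact = 0
    ),
    class = "cost_report"
  )
}

#' Incremental comparison of two cost reports
#'
#' Budget-impact difference of arm B relative to arm A: signed
#' incremental cohort and per-patient costs, per-component deltas over the
#' union of component names, and the ratio of per-patient costs as an
#' exact reduced fraction plus its decimal value.  Mismatched cohort sizes
#' or exchange rates are reported as warnings on the result (the
#' per-patient comparison is still emitted).
#'
#' @param report_a Baseline `cost_report` (arm A).
#' @param report_b Comparator `cost_report` (arm B).
#' @return An object of class `comparison_report`.
#' @export
compare_strategies <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "cost_report"),
            inherits(report_b, "cost_report"))
  warn <- character()
  if (report_a$n_patients != report_b$n_patients) {
    warn <- c(warn, sprintf(
      "cohort sizes differ (%d vs %d); cohort-level increments mix populations",
      report_a$n_patients, report_b$n_patients))
  }
  if (report_a$rate != report_b$rate) {
    warn <- c(warn, sprintf("exchange rates differ (%s vs %s)",
                            format(report_a$rate), format(report_b$rate)))
  }
  for (w in warn) warning(w, call. = FALSE)

  comps <- union(names(report_a$components_irr),
                 names(report_b$components_irr))
  get0n <- function(r, nm) {
    v <- r$components_irr[nm]
    ifelse(is.na(v), 0, v)
  }
  delta_components <- stats::setNames(
    vapply(comps, function(nm) get0n(report_b, nm) - get0n(report_a, nm),
           numeric(1)),
    comps)

  ppa <- report_a$per_patient_irr
  ppb <- report_b$per_patient_irr
  ratio <- if (ppa > 0) {
    g <- gcd(ppb, ppa)
    list(num = ppb / g, den = ppa / g, value = ppb / ppa)
  } else {
    list(num = NA_real_, den = NA_real_, value = NA_real_)
  }

  structure(
    list(
      arm_a = report_a$strategy,
      arm_b = report_b$strategy,
      rate = report_a$rate,
      total_irr = c(a = report_a$total_irr, b = report_b$total_irr),
      total_usd = c(a = report_a$total_usd, b = report_b$total_usd),
      per_patient_irr = c(a = ppa, b = ppb),
      per_patient_usd = c(a = report_a$per_patient_usd,
                          b = report_b$per_patient_usd),
      incremental_total_irr = report_b$total_irr - report_a$total_irr,
      incremental_total_usd = to_usd(report_b$total_irr - report_a$total_irr,
                                     report_a$rate),
      incremental_per_patient_irr = ppb - ppa,
      delta_components_irr = delta_components,
      per_patient_ratio = ratio,
      warnings = warn
    ),
    class = "comparison_report"
  )
}

# Euclid on non-negative integer-valued doubles.
gcd <- function(a, b) {
  while (b > 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}
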