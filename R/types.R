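# Domain types: lightweight S3 records with validating constructors.

#' Cohort specification
#'
#' Describes the incident patient cohort the strategy is costed over: the
#' number of patients transplanted in the study year, the costing horizon,
#' and a reference body weight used only to sanity-check weight-based
#' dosing (never for costing).
#'
#' @param n_patients Number of incident patients (positive integer).
#' @param horizon_days Costing horizon in days; default 365 (first year).
#' @param patient_weight_kg Reference adult weight in kg; default 70.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(2200)
cohort_spec <- function(n_patients, horizon_days = 365,
                        patient_weight_kg = 70) {
  assert_count(n_patients, "n_patients", min = 0)
  assert_count(horizon_days, "horizon_days", min = 1)
  assert_nonneg(patient_weight_kg, "patient_weight_kg")
  if (patient_weight_kg <= 0) {
    stop("`patient_weight_kg` must be positive", call. = FALSE)
  }
  structure(
    list(n_patients = as.numeric(n_patients),
         horizon_days = as.numeric(horizon_days),
         patient_weight_kg = as.numeric(patient_weight_kg)),
    class = "cohort_spec"
  )
}

#' Global hospitalization tariff
#'
#' A lump-sum episode-of-care reimbursement expressed as a multiple of the
#' surgical tariff base unit K: `multiplier` x `k_value` Rials per
#' recipient-donor operation pair, regardless of realized length of stay.
#'
#' @param k_value Value of one K unit in IRR.
#' @param multiplier Number of K units (positive integer).
#' @return An object of class `global_tariff`.
#' @export
#' @examples
#' global_tariff(k_value = 60000, multiplier = 650)
global_tariff <- function(k_value, multiplier) {
  assert_money(k_value, "k_value")
  assert_count(multiplier, "multiplier", min = 1)
  structure(list(k_value = as.numeric(k_value),
                 multiplier = as.numeric(multiplier)),
            class = "global_tariff")
}

#' Maintenance or miscellaneous regimen line
#'
#' One drug line dispensed daily over a duration.  Costing is driven
#' either per patient (`units_per_day` x `unit_price` x `n_eligible`) or,
#' when the per-patient composition is an unresolvable mixture of dosage
#' forms, by a `cohort_daily_cost` override giving the total daily cost of
#' the whole eligible sub-cohort.  Setting the override together with a
#' non-zero per-patient computation is rejected as ambiguous.
#'
#' @param drug Drug name.
#' @param dosage_form Free-text dosage form (informational).
#' @param units_per_day Units dispensed per patient per day.
#' @param unit_price Price per unit in IRR.
#' @param n_eligible Number of patients on this line.
#' @param duration_days Days of therapy (positive integer).
#' @param cohort_daily_cost Optional IRR/day for the whole eligible
#'   sub-cohort; when set, the per-patient fields are informational only.
#' @return An object of class `regimen_line`.
#' @seealso [regimen_line_cohort_cost()], [mixture_daily_cost()]
#' @export
regimen_line <- function(drug, dosage_form = "", units_per_day = 0,
                         unit_price = 0, n_eligible = 0, duration_days,
                         cohort_daily_cost = NULL) {
  stopifnot(is.character(drug), length(drug) == 1L)
  assert_nonneg(units_per_day, "units_per_day")
  assert_money(unit_price, "unit_price")
  assert_count(n_eligible, "n_eligible", min = 0)
  assert_count(duration_days, "duration_days", min = 1)
  if (!is.null(cohort_daily_cost)) {
    assert_money(cohort_daily_cost, "cohort_daily_cost")
    if (units_per_day * unit_price * n_eligible > 0) {
      stop("ambiguous regimen line `", drug, "`: both cohort_daily_cost ",
           "and a non-zero per-patient computation are specified",
           call. = FALSE)
    }
  }
  structure(
    list(drug = drug, dosage_form = dosage_form,
         units_per_day = as.numeric(units_per_day),
         unit_price = as.numeric(unit_price),
         n_eligible = as.numeric(n_eligible),
         duration_days = as.numeric(duration_days),
         cohort_daily_cost = if (is.null(cohort_daily_cost)) NULL else
           as.numeric(cohort_daily_cost)),
    class = "regimen_line"
  )
}

#' Billed element of an adverse-event treatment bundle
#'
#' @param kind One of `"drug_course"` (units/day x price x days),
#'   `"procedure"` (price x sessions), `"hospitalization"`
#'   (price/day x days) or `"fixed_tariff"` (the price, once).
#' @param label Item label.
#' @param unit_price Price per unit, session or day, or the fixed amount
#'   (IRR).
#' @param duration Days for drug courses and hospitalization, session
#'   count for procedures; ignored for fixed tariffs.
#' @param units_per_day Units dispensed per day (drug courses only).
#' @return An object of class `treatment_item`.
#' @seealso [treatment_item_cost()]
#' @export
#' @examples
#' treatment_item("drug_course", "Ganciclovir", unit_price = 250000,
#'                duration = 7, units_per_day = 2)
treatment_item <- function(kind, label, unit_price, duration = 0,
                           units_per_day = 0) {
  kind <- match.arg(kind, c("drug_course", "procedure", "hospitalization",
                            "fixed_tariff"))
  stopifnot(is.character(label), length(label) == 1L)
  assert_money(unit_price, "unit_price")
  assert_nonneg(duration, "duration")
  assert_nonneg(units_per_day, "units_per_day")
  if (kind == "drug_course" && units_per_day == 0) {
    stop("drug_course item `", label, "` needs units_per_day > 0",
         call. = FALSE)
  }
  structure(
    list(kind = kind, label = label, unit_price = as.numeric(unit_price),
         duration = as.numeric(duration),
         units_per_day = as.numeric(units_per_day)),
    class = "treatment_item"
  )
}

#' Adverse-event profile
#'
#' A named first-year adverse event with its per-patient occurrence
#' probability and the treatment bundle billed when it occurs.  The
#' probability is stored together with its exact decimal-rational form so
#' that expected costs are computed without floating-point error.
#'
#' @param name Event name.
#' @param probability Per-patient first-year occurrence probability in
#'   \[0, 1\], written as a decimal.
#' @param items List of [treatment_item()] objects.
#' @return An object of class `ae_profile`.
#' @seealso [ae_unit_cost_per_patient()], [ae_expected_costs()]
#' @export
adverse_event_profile <- function(name, probability, items = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.list(items))
  assert_prob(probability)
  for (it in items) {
    if (!inherits(it, "treatment_item")) {
      stop("`items` must all be treatment_item objects", call. = FALSE)
    }
  }
  rat <- decimal_rational(probability, max_digits = 6)
  structure(
    list(name = name, probability = as.numeric(probability),
         prob_num = as.numeric(rat$num), prob_den = as.numeric(rat$den),
         items = items),
    class = "ae_profile"
  )
}

#' Complete therapy strategy
#'
#' Bundles everything needed to cost one therapy strategy over a cohort:
#' an optional per-patient global hospitalization tariff, maintenance
#' regimen lines, adverse-event profiles and miscellaneous medication
#' lines.  All component lists may be empty; an empty strategy costs zero.
#'
#' @param name Strategy name.
#' @param cohort A [cohort_spec()].
#' @param hospitalization Optional [global_tariff()] applied once per
#'   patient.
#' @param maintenance List of [regimen_line()] objects (immunosuppressive
#'   maintenance therapy).
#' @param adverse_events List of [adverse_event_profile()] objects.
#' @param misc List of [regimen_line()] objects (miscellaneous medicines).
#' @return An object of class `strategy_definition`.
#' @seealso [strategy_report()]
#' @export
strategy_definition <- function(name, cohort, hospitalization = NULL,
                                maintenance = list(),
                                adverse_events = list(), misc = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(cohort, "cohort_spec"))
  if (!is.null(hospitalization) &&
      !inherits(hospitalization, "global_tariff")) {
    stop("`hospitalization` must be NULL or a global_tariff", call. = FALSE)
  }
  for (l in maintenance) {
    if (!inherits(l, "regimen_line")) {
      stop("`maintenance` must contain regimen_line objects", call. = FALSE)
    }
  }
  for (l in misc) {
    if (!inherits(l, "regimen_line")) {
      stop("`misc` must contain regimen_line objects", call. = FALSE)
    }
  }
  for (a in adverse_events) {
    if (!inherits(a, "ae_profile")) {
      stop("`adverse_events` must contain adverse_event_profile objects",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, cohort = cohort, hospitalization = hospitalization,
         maintenance = maintenance, adverse_events = adverse_events,
         misc = misc),
    class = "strategy_definition"
  )
}

#' Hemodialysis comparator arm
#'
#' Annual hospital-based hemodialysis for the same cohort: a per-session
#' tariff times sessions per year, plus an annual per-patient adjunct
#' medication bundle (erythropoietin and calcitriol).  Adverse events are
#' deliberately excluded from this arm.
#'
#' @param session_tariff IRR per hemodialysis session.
#' @param sessions_per_year Sessions per patient per year; default 156
#'   (three per week).
#' @param adjunct_annual_per_patient Annual adjunct medication cost per
#'   patient in IRR.
#' @param cohort A [cohort_spec()].
#' @return An object of class `dialysis_arm`.
#' @seealso [dialysis_annual_cost()]
#' @export
dialysis_arm <- function(session_tariff, sessions_per_year = 156,
                         adjunct_annual_per_patient, cohort) {
  assert_money(session_tariff, "session_tariff")
  assert_count(sessions_per_year, "sessions_per_year", min = 0)
  assert_money(adjunct_annual_per_patient, "adjunct_annual_per_patient")
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(
    list(session_tariff = as.numeric(session_tariff),
         sessions_per_year = as.numeric(sessions_per_year),
         adjunct_annual_per_patient = as.numeric(adjunct_annual_per_patient),
         cohort = cohort),
    class = "dialysis_arm"
  )
}

#' Units per day implied by a weight-based dose
#'
#' Converts an mg/kg dosing rule into dispensed units per day at a
#' reference body weight, rounding each administered dose up to whole
#' dispensing units (vials or tablets are not split).  Used to check that
#' a regimen line's `units_per_day` is consistent with its labelled dose;
#' costing itself always uses the stated `units_per_day`.
#'
#' @param mg_per_kg_per_dose Dose in mg per kg of body weight.
#' @param doses_per_day Administrations per day.
#' @param weight_kg Reference body weight in kg.
#' @param unit_mg Strength of one dispensing unit in mg.
#' @return Implied whole units per day.
#' @export
#' @examples
#' units_for_weight_dose(5, 2, 70, 500)   # ganciclovir: 2 vials/day
#' units_for_weight_dose(0.1, 2, 70, 0.5) # tacrolimus: 28 tablets/day
units_for_weight_dose <- function(mg_per_kg_per_dose, doses_per_day,
                                  weight_kg, unit_mg) {
  assert_nonneg(mg_per_kg_per_dose, "mg_per_kg_per_dose")
  assert_count(doses_per_day, "doses_per_day", min = 1)
  assert_nonneg(weight_kg, "weight_kg")
  assert_nonneg(unit_mg, "unit_mg")
  if (unit_mg <= 0) stop("`unit_mg` must be positive", call. = FALSE)
  doses_per_day * ceiling(mg_per_kg_per_dose * weight_kg / unit_mg)
}

#' Cohort daily cost of a dosage-form mixture
#'
#' Helper for regimen lines where the eligible sub-cohort splits across
#' several dosage-form combinations (for example cyclosporine dispensed as
#' mixtures of 25/50/100 mg capsules).  Given the proportion of patients
#' on each combination, the units per day and unit price of each, returns
#' the total daily cost of the sub-cohort, rounded to whole Rials, for use
#' as a `cohort_daily_cost` override.
#'
#' @param proportions Proportions of eligible patients on each form
#'   combination; must sum to 1.
#' @param units_per_day Units per day for each combination.
#' @param unit_prices IRR per unit for each combination.
#' @param n_eligible Number of eligible patients.
#' @return Cohort daily cost in whole IRR.
#' @export
mixture_daily_cost <- function(proportions, units_per_day, unit_prices,
                               n_eligible) {
  stopifnot(length(proportions) == length(units_per_day),
            length(proportions) == length(unit_prices))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  assert_count(n_eligible, "n_eligible", min = 0)
  round_half_away(n_eligible * sum(proportions * units_per_day * unit_prices))
}
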