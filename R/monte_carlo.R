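# Patient-level Monte Carlo cohort simulation.
#
# Each adverse event occurs independently per patient as a Bernoulli draw
# at its first-year probability; a patient's adverse-event cost is the sum
# of the bundle costs of the events that occurred.  Replicated cohorts of
# the study size give a distribution of mean per-patient costs against
# which the analytic expectation sum(p_e * c_e) is checked.

#' Simulation configuration
#'
#' @param n_patients Patients per simulated cohort.
#' @param n_replicates Number of independent cohort replicates.
#' @param seed RNG seed (Mersenne-Twister); mandatory so runs are
#'   reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 2200, n_replicates = 500, seed) {
  assert_count(n_patients, "n_patients", min = 1)
  assert_count(n_replicates, "n_replicates", min = 1)
  assert_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(n_patients = n_patients, n_replicates = n_replicates, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate one patient's adverse-event cost
#'
#' Draws one Bernoulli outcome per event from R's current RNG stream and
#' returns the summed bundle costs of the events that occurred.
#'
#' @param aes List of [adverse_event_profile()] objects.
#' @return Simulated first-year adverse-event cost for one patient (IRR).
#' @export
simulate_patient <- function(aes) {
  if (length(aes) == 0) return(0)
  p <- vapply(aes, `[[`, numeric(1), "probability")
  cost <- vapply(aes, ae_unit_cost_per_patient, numeric(1))
  sum(cost[stats::runif(length(p)) < p])
}

#' Simulate replicated cohorts and summarize mean adverse-event cost
#'
#' Runs `n_replicates` independent cohorts of `n_patients` and records
#' each replicate's mean per-patient adverse-event cost.  The result
#' carries the analytic expectation (the exact, unrounded
#' `sum(p_e * c_e)`) for comparison.  Identical configuration and seed
#' give a bit-identical result.
#'
#' @param cfg A [simulation_config()].
#' @param aes List of [adverse_event_profile()] objects.
#' @return An object of class `simulation_result` with fields
#'   `replicate_means`, `grand_mean`, `min`, `max`, `sd`,
#'   `analytic_expectation`, `n_patients`, `n_replicates`, `seed`.
#' @export
simulate_cohort <- function(cfg, aes) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- vapply(aes, `[[`, numeric(1), "probability")
  cost <- vapply(aes, ae_unit_cost_per_patient, numeric(1))
  exact <- if (length(aes) == 0) 0 else
    sum(vapply(aes, function(a) a$prob_num * ae_unit_cost_per_patient(a) /
                 a$prob_den, numeric(1)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  k <- length(p)
  n <- cfg$n_patients
  means <- vapply(seq_len(cfg$n_replicates), function(r) {
    if (k == 0) return(0)
    occ <- matrix(stats::runif(n * k), nrow = n) <
      matrix(p, nrow = n, ncol = k, byrow = TRUE)
    sum(occ %*% cost) / n
  }, numeric(1))

  structure(
    list(
      replicate_means = means,
      grand_mean = mean(means),
      min = min(means),
      max = max(means),
      sd = stats::sd(means),
      analytic_expectation = exact,
      n_patients = n,
      n_replicates = cfg$n_replicates,
      seed = cfg$seed
    ),
    class = "simulation_result"
  )
}

#' Check simulated mean against the analytic expectation
#'
#' Passes when the grand mean over replicates lies within
#' `tol_se_multiples` standard errors (sd of replicate means divided by
#' `sqrt(n_replicates)`) of the analytic expectation.  A degenerate
#' simulation (zero spread) passes only on exact agreement.
#'
#' @param result A [simulate_cohort()] result.
#' @param tol_se_multiples Tolerance in standard errors; default 4.
#' @return A list with `converged` (logical), `deviation` (IRR),
#'   `se`, `z` (standardized deviation, `NA` when `se` is 0) and
#'   `message` (diagnostic text).
#' @export
convergence_check <- function(result, tol_se_multiples = 4) {
  stopifnot(inherits(result, "simulation_result"))
  assert_nonneg(tol_se_multiples, "tol_se_multiples")
  dev <- result$grand_mean - result$analytic_expectation
  se <- if (is.na(result$sd)) 0 else result$sd / sqrt(result$n_replicates)
  if (se == 0) {
    ok <- dev == 0
    msg <- if (ok) {
      "degenerate simulation (zero spread): grand mean equals the analytic expectation exactly"
    } else {
      sprintf("FAILURE: zero spread across replicates but grand mean deviates from the analytic expectation by %.1f IRR", dev)
    }
    return(list(converged = ok, deviation = dev, se = 0, z = NA_real_,
                message = msg))
  }
  z <- dev / se
  ok <- abs(z) <= tol_se_multiples
  msg <- sprintf(
    "grand mean %.1f vs analytic expectation %.1f IRR: deviation %.1f = %.2f standard errors (tolerance %.1f) -> %s",
    result$grand_mean, result$analytic_expectation, dev, z,
    tol_se_multiples, if (ok) "converged" else "NOT converged")
  list(converged = ok, deviation = dev, se = se, z = z, message = msg)
}
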