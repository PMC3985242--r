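# Independent brute-force cost oracle over reduced-fraction rationals.
#
# This walks the raw fields of a strategy and re-derives every total with
# its own arithmetic (gcd-reduced num/den pairs, integer-only rounding);
# it shares no code path with the engine it checks.

r_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b; a <- b; b <- t
  }
  if (a == 0) 1 else a
}

rat <- function(num, den = 1) {
  g <- r_gcd(num, den)
  list(num = num / g, den = den / g)
}

rat_add <- function(x, y) rat(x$num * y$den + y$num * x$den, x$den * y$den)

rat_mul <- function(x, y) rat(x$num * y$num, x$den * y$den)

# decimal string -> rational, without touching the package's parser
rat_from_decimal <- function(p) {
  s <- format(p, digits = 15, scientific = FALSE, trim = TRUE)
  if (!grepl(".", s, fixed = TRUE)) return(rat(as.numeric(s)))
  frac <- sub("^-?[0-9]*\\.", "", s)
  rat(round(p * 10^nchar(frac)), 10^nchar(frac))
}

# nearest integer, half away from zero, by integer ops only
rat_round <- function(x) {
  s <- if (x$num < 0) -1 else 1
  a <- abs(x$num)
  q <- a %/% x$den
  r <- a - q * x$den
  s * (q + (2 * r >= x$den))
}

oracle_item_cost <- function(it) {
  switch(it$kind,
    drug_course = it$units_per_day * it$unit_price * it$duration,
    procedure = it$unit_price * it$duration,
    hospitalization = it$unit_price * it$duration,
    fixed_tariff = it$unit_price)
}

oracle_line_cost <- function(l) {
  if (!is.null(l$cohort_daily_cost)) {
    l$cohort_daily_cost * l$duration_days
  } else {
    l$units_per_day * l$unit_price * l$n_eligible * l$duration_days
  }
}

# per-event: p * bundle (exact), display rounded, cohort total rounded at
# the end only -- the documented rounding policy, re-derived.
oracle_ae <- function(ae, n) {
  unit <- if (length(ae$items) == 0) 0 else
    sum(vapply(ae$items, oracle_item_cost, numeric(1)))
  p <- rat_from_decimal(ae$probability)
  exp_rat <- rat_mul(p, rat(unit))
  list(unit = unit,
       expected_exact = exp_rat$num / exp_rat$den,
       expected_display = rat_round(exp_rat),
       cohort_total = rat_round(rat_mul(exp_rat, rat(n))))
}

oracle_strategy_totals <- function(s) {
  n <- s$cohort$n_patients
  hosp <- if (is.null(s$hospitalization)) 0 else
    s$hospitalization$multiplier * s$hospitalization$k_value * n
  maint <- if (length(s$maintenance) == 0) 0 else
    sum(vapply(s$maintenance, oracle_line_cost, numeric(1)))
  misc <- if (length(s$misc) == 0) 0 else
    sum(vapply(s$misc, oracle_line_cost, numeric(1)))
  aes <- lapply(s$adverse_events, oracle_ae, n = n)
  ae_cohort <- if (length(aes) == 0) 0 else
    sum(vapply(aes, `[[`, numeric(1), "cohort_total"))
  ae_pp_display <- if (length(aes) == 0) 0 else
    sum(vapply(aes, `[[`, numeric(1), "expected_display"))
  list(hospitalization = hosp, immunosuppressive = maint,
       adverse_events = ae_cohort, miscellaneous = misc,
       ae_per_patient_display = ae_pp_display,
       total = hosp + maint + ae_cohort + misc)
}
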