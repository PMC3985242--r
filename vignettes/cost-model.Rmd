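---
title: "Modelling first-year renal-transplantation treatment costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling first-year renal-transplantation treatment costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcost)
```

## The model

`txcost` estimates the first-year cost of renal transplantation therapy
(RTT) to a health-insurance payer for an incident cohort of transplant
recipients, and compares it against an all-hemodialysis scenario.  The
payer's total is the sum of four components:

$$
C = n \cdot T \;+\; \sum_{\ell \in \text{lines}} u_\ell p_\ell n_\ell d_\ell
\;+\; n \sum_{e \in \text{AEs}} \pi_e c_e \;+\;
\sum_{m \in \text{misc}} u_m p_m n_m d_m
$$

where $n$ is the cohort size, $T$ the global hospitalization tariff paid
once per recipient-donor operation pair (a multiple of the surgical base
unit K), each regimen line $\ell$ dispenses $u_\ell$ units per day at
unit price $p_\ell$ to $n_\ell$ eligible patients for $d_\ell$ days,
$\pi_e$ is the first-year occurrence probability of adverse event $e$ and
$c_e$ the cost of its treatment bundle per affected patient.  Adverse
events enter as *expected* costs: the model is a one-year, undiscounted,
deterministic cohort expectation from the payer perspective.  There is no
Markov structure, no discounting, no quality-adjustment, and no
out-of-pocket component — deliberately, since all of those sit outside
the payer question the model answers.

Treatment bundles are lists of typed items: drug courses
($u \cdot p \cdot d$), procedures (price $\times$ sessions),
hospitalization days (daily tariff $\times$ days) and fixed tariffs
(charged once — e.g. re-transplantation after graft failure is billed at
the same 650 K global tariff, within the first year and with no further
downstream costs).  Events are treated as marginally specified and
mutually independent; the expected-cost sum is agnostic to the joint
distribution, so only the simulator (below) depends on the independence
assumption.

## Exact arithmetic and the rounding policy

Every published cell the model reproduces is a whole number of Iranian
Rials (IRR), and reproducing them *bit-exactly* is a design goal, so the
engine never lets binary floating point touch a total:

* Money is whole IRR stored in doubles; all quantities in scope are far
  below $2^{53}$, where double arithmetic on integers is exact.
* Probabilities are carried as exact decimal rationals
  (`decimal_rational(0.105)` is 105/1000), so an expectation
  $\pi_e c_e$ is an integer product divided once at the end.
* Rounding is half-away-from-zero everywhere, applied exactly once per
  displayed figure: per-event expected costs are rounded for the
  per-patient *display* column (whose column total therefore sums the
  rounded values), while cohort totals multiply the **unrounded**
  expectation by $n$ first.  The hypertension line shows why both paths
  are needed: $0.67 \times 54{,}750 = 36{,}682.5$ displays as 36,683,
  but the cohort total is $36{,}682.5 \times 2{,}200 = 80{,}701{,}500$
  exactly.
* Per-patient strategy totals divide the cohort total by $n$ and round
  half away from zero (the bundled inputs give
  $170{,}718{,}326{,}900 / 2{,}200 = 77{,}599{,}239.5 \to 77{,}599{,}240$).
* USD conversion divides by the exchange rate (12,260 IRR/USD in the
  study year) and rounds half away from zero; decimal rates are handled
  by exact integer scaling.

Because per-event cohort rounding happens after the multiplication by
$n$, doubling the cohort doubles cohort totals exactly on the unrounded
expectations; the rounded figures can differ by at most half a Rial per
event.  Invariant tests therefore assert scaling on the exact values,
which the engine exposes alongside the rounded ones.

## The bundled inputs

`iran_rtt_2011()` returns the complete input set for the 2011–2012
Iranian incident cohort: 2,200 patients aged 18–70, a 650 × 60,000 IRR
global tariff, four maintenance immunosuppressive lines, eight
adverse-event profiles, five miscellaneous medication lines, and the
hemodialysis comparator tariffs, at 12,260 IRR/USD.  Notable modelling
choices baked into that file:

* **Cyclosporine** (90% of the cohort, mean 150 mg/day) is dispensed as
  patient-specific mixtures of 25/50/100 mg capsules whose proportions
  come from unpublished pharmacy records, so the line carries a
  cohort-level `cohort_daily_cost` of 5,167,800 IRR/day rather than a
  per-patient computation.  Users with their own records can build the
  override with `mixture_daily_cost()`.  (The published unit-price list
  for the three capsule strengths is internally ambiguous — the 50 mg
  price exceeds the 100 mg price — which the override sidesteps.)
* **Tacrolimus** covers the roughly 10% of patients on a second or later
  graft: 0.2 mg/kg/day at the 70 kg reference weight is 14 mg/day, i.e.
  28 half-milligram tablets.  The 70 kg reference also reproduces the
  ganciclovir vial counts (5 mg/kg per dose, one 500 mg vial per dose);
  it is used only by `units_for_weight_dose()` for consistency checking,
  never for costing.  Sirolimus is excluded: it had no insurance
  coverage in the study year.
* The hemodialysis arm uses 156 sessions/year (3 per week × 52 — the
  value consistent with the published annual dialysis total) at the
  743,200 IRR session tariff, plus an opaque adjunct bundle
  (erythropoietin + calcitriol) of 21,230,400 IRR/patient/year derived
  from the published cohort figure.  The arm excludes adverse events.

```{r fixture}
fx <- iran_rtt_2011()
strategy_report(fx$strategy, fx$rate)
```

## Monte Carlo validation

`simulate_cohort()` draws one Bernoulli outcome per event per patient
(independent across events and patients — the occurrence probabilities
are specified marginally, and independence is the minimal completion
consistent with the additive expectation) and records each replicate
cohort's mean per-patient adverse-event cost.  A certain event
($\pi = 1$, as for the prophylactic-infection bundle) contributes its
constant 651,600 IRR to every patient.  The default is 500 replicates of
the full 2,200-patient cohort; the seed is mandatory, set via R's
Mersenne-Twister, and the caller's RNG state is restored afterwards so
simulation never perturbs surrounding code.

`convergence_check()` compares the grand mean against the analytic
expectation $\sum_e \pi_e c_e$ (19,645,884.5 IRR on the bundled inputs)
at a tolerance of 4 standard errors of the replicate means — wide enough
that a correct engine fails with probability well below $10^{-4}$, tight
enough that a 10% bias in any major event's expectation is caught
essentially always.  No noise is placed on unit prices by default; the
generator's `price_jitter_cv` knob exists purely to stress the rounding
policy.

```{r mc}
sim <- simulate_cohort(simulation_config(2200, 100, seed = 1),
                       fx$strategy$adverse_events)
convergence_check(sim)$message
```

## Comparator

`dialysis_annual_cost()` costs the all-hemodialysis scenario and
`compare_strategies()` reports signed incremental totals, per-component
deltas and the per-patient cost ratio as an exact reduced fraction plus
its decimal value.  Budget-impact questions about substituting a drug are
expressed by editing the strategy (replace or add lines) and comparing —
no dedicated scenario machinery is needed, because strategies are plain
data.

```{r compare}
cmp <- compare_strategies(strategy_report(fx$strategy, fx$rate),
                          dialysis_annual_cost(fx$dialysis, fx$rate))
cmp$per_patient_ratio$value
```

## The synthetic generator, and what the tests do and do not show

`generate_strategy()` draws structurally valid random strategies:
uniform integer prices and durations, probabilities on a 1/1000 grid,
a mix of override-driven and per-patient regimen lines, one to five
events with one to four typed items each.  Its job is *structural
coverage* of the input space — every code path of the engine, the
serializer and the simulator exercised under exact arithmetic — not
clinical realism.  The property suite checks, over a thousand generated
strategies under fixed seeds, that engine totals equal an independent
reduced-fraction rational oracle, that totals are additive and monotone
in prices and probabilities, that comparison is antisymmetric, and that
configurations survive serialization round-trips identically.

Passing those tests shows the *arithmetic* is right under the model's
assumptions.  It does not validate the assumptions against real claims
data: real adverse events are correlated (graft failure and delayed graft
function are not independent), real prices drift within a year, real
cohorts are not closed, and real probabilities are estimates with
sampling error that the model takes as fixed inputs.  The Monte Carlo
band quantifies only Bernoulli sampling noise, not parameter uncertainty.

## Numerical and design notes

* Problem sizes used by the test suite — 500-replicate simulations at
  cohort sizes up to 2,200 and a thousand generated strategies — were
  chosen so the whole suite runs in well under a minute while leaving
  statistical margins (a 500-replicate standard-deviation estimate has
  ~3% relative error, comfortably inside the 20% band the
  variance-scaling check allows around the theoretical $1/\sqrt{n}$).
* Degenerate inputs are defined, not errors: empty component lists, zero
  probabilities and zero prices all cost zero; a zero-patient cohort
  with genuinely non-zero costs is the one rejected case, because a
  per-patient figure has no meaning there.
* A regimen line whose per-patient product is fractional in Rials is
  rejected with advice to use the cohort override — silent rounding
  inside a line would break the exactness contract.
* Configs are YAML or JSON with unknown fields rejected by name, so a
  typo cannot silently drop a cost component; numbers on disk are plain
  integers, with thousands separators applied only at render time.
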