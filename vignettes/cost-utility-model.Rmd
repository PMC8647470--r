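---
title: "A Markov cohort cost-utility model of triple versus dual inhaler therapy in asthma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of triple versus dual inhaler therapy in asthma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(asthmacea)
library(ggplot2)
```

## The decision problem

A substantial fraction of patients with moderate-severe asthma remain
uncontrolled on dual inhaler therapy (inhaled corticosteroid plus
long-acting beta2-agonist, ICS+LABA). Adding a long-acting muscarinic
antagonist (LAMA) — triple therapy — reduces the rate of severe
exacerbations, at the price of an additional drug acquisition cost. In a
resource-constrained health system the question is whether the QALYs gained
by fewer exacerbations justify that extra cost at the local
willingness-to-pay (WTP) threshold, here US$19,000 per QALY (three times GDP
per capita, costs expressed in US dollars at a fixed COP$3,500 exchange
rate).

`asthmacea` answers this with a discrete-time Markov cohort model evaluated
deterministically (base case, one-way sensitivity analysis) and
probabilistically (second-order Monte Carlo), plus an individual-level
microsimulation that serves as a brute-force validation oracle for the
cohort engine.

## Model structure

Six ordered states: `CONTROLLED`, the three escalating exacerbation levels
`EXAC_OCS` (oral corticosteroid burst), `EXAC_ED` (emergency department
visit), `EXAC_HOSP` (hospitalization), and two absorbing death states
(`DEATH_ASTHMA`, `DEATH_OTHER`). The cycle length is 2 weeks (26 cycles per
52-week year), matching the clinical time scale of an exacerbation episode.

The exacerbation states are *single-cycle tunnel states*: a patient who
suffers a burst either escalates to an emergency visit in the next cycle
(probability `p_ocs_to_ed` = 0.47), dies, or returns to `CONTROLLED`;
likewise an emergency visit escalates to hospitalization with
`p_ed_to_hosp` = 0.15. The per-cycle probability of leaving the controlled
state for a burst is `p_controlled_to_ocs` = 0.12, multiplied by the
exacerbation relative risk (RR = 0.85, 95% interval 0.78-0.92) while a
patient is on triple therapy. Dual therapy is the RR = 1 reference.

Two competing mortality mechanisms act each cycle:

* background (all-cause) mortality at the cohort's current age, converted
  from the annual life-table probability `q` by
  `1 - (1 - q)^(1/26)`, applied **first**, with all disease transitions
  scaled by the surviving fraction `1 - q_cycle` so every row of the
  transition matrix sums to exactly 1 for any admissible inputs;
* asthma-related mortality at a per-cycle probability of 0.0002 from each
  exacerbation state (a `hospital_only` variant restricts it to the
  hospitalized state).

### Treatment persistence

Real-world adherence is poor: 37% of triple-therapy and 44% of dual-therapy
patients discontinue within 52 weeks. At the end of cycle 26 the alive
cohort therefore splits into a persistent sub-cohort (63% / 56%) that keeps
the treatment effect and drug cost, and a discontinued sub-cohort with
RR = 1. Discontinued triple-arm patients revert to the dual-therapy drug
cost; discontinued dual-arm patients keep the dual drug cost and RR = 1, so
dual-arm discontinuation is economically neutral — no "untreated"
natural-history inputs exist, and inventing them would add nothing but
noise. The two sub-cohorts are propagated in parallel and re-aggregated in
the reported trace.

## Accounting conventions

**Costs.** Drug acquisition costs are quoted per 4-week cycle (tiotropium
$60, umeclidinium $32, glycopyrronium $32, ICS+LABA $27) and scaled to the
2-week model cycle. The LAMA component of triple therapy is a market-share
weighted mix, equal thirds by default (`triple_drug_mix`). Event costs are
charged once on entry to an exacerbation state: $26 per emergency visit,
$80 per hospital day times the length of stay `hosp_los_days` (default 5
days — a typical asthma admission; no length of stay is part of the printed
inputs, so it is an explicit, sensitivity-testable setting), and an oral
corticosteroid burst cost that defaults to $0 because no defensible price
was available (zero-valued costs are automatically excluded from
sensitivity analyses rather than pretending precision).

**QALYs.** The controlled state carries utility 0.74; exacerbations carry
decrements of 0.10 (burst), 0.15 (emergency visit) and 0.20
(hospitalization). The utility inputs are specified on an *annual* scale,
and the default accrual convention (`decrement_basis = "per_event_annual"`)
therefore charges each exacerbation entry a one-off QALY loss equal to its
decrement — the decrement is the *total* QALY loss attributed to an event,
capturing the symptomatic episode plus its aftermath, not a utility dip
confined to the 2-week cycle. The alternative reading
(`decrement_basis = "per_cycle"`), in which the decrement reduces the state
utility only for the single cycle spent in the state, is a settings switch;
it yields per-event losses 26 times smaller and correspondingly small
incremental QALYs. Both conventions leave the cohort trace untouched — they
differ only in the reward accounting.

**Half-cycle correction and discounting.** Per-cycle cost and QALY streams
are evaluated on the trace rows `t = 0..T` with trapezoidal weights (half
weight on the first and final row) and discounted at
`(1 + r)^(-t/26)` with `r` = 5%/year (range 0-6% in the sensitivity
analysis). With the correction disabled the start-of-cycle convention
(rows `0..T-1`) is used, which makes a disease-free, undiscounted year
accrue exactly 1 QALY under either convention.

**Horizon.** The cohort starts 100% controlled at age 18 (a configurable
choice: the modelled population is adolescents and adults) and runs to age
100 or an alive mass below 1e-9, whichever comes first.

### Reporting scales

Lifetime totals and per-person-year normalizations answer different
questions and are reported separately: `incremental()` returns the lifetime
discounted `delta_cost`, `delta_qaly` and their unit-consistent ratio (the
ICER), *and* `delta_cost_per_person_year` / `delta_qaly_per_person_year`
(each arm's total divided by its discounted person-years, then differenced).
Quoting an incremental cost per person-year next to a lifetime QALY gain —
a tempting summary because both numbers are small — produces a ratio that is
not an ICER in any consistent unit system; the package never mixes the two
scales inside a ratio.

## Parameter uncertainty

Every uncertain input is a `(base, low, high)` range with a semantic role.
Printed ranges are used as given (the relative-risk bounds are stored
reordered so `low <= high`; the controlled-to-burst row's printed high
equals its base, and `strict_25pct = TRUE` recomputes it from the rule
below). Where a bound is absent the range is base ± 25%, clipped to the
role's bounds.

**Distribution fitting** treats each range as a 95% interval,
`sd = (high - low)/3.92`, and moment-matches:

* beta for the relative risk, utilities, decrements and persistence
  proportions: `alpha = m(m(1-m)/s^2 - 1)`, `beta = alpha(1-m)/m`;
* gamma for costs: `shape = (m/s)^2`, `scale = s^2/m`;
* Dirichlet for transition probabilities, one fit per source state: the
  concentration total `N` solves the beta-marginal identity
  `p(1-p)/(N+1) = s^2` for the largest branch, the residual (stay/return)
  branch takes the remaining mass. With a single uncertain branch the
  Dirichlet's sampling distribution is exactly its beta marginal, which is
  how draws are generated.

Degenerate (zero-width) ranges become fixed points; the discount rate is
varied only in the deterministic analysis. Every fit reproduces its target
mean exactly (to floating point) and its target sd in closed form.

**PSA.** Each of the (default) 1000 replicates draws one value per
uncertain parameter — parameters common to both arms (utilities, event
costs, transition probabilities) share the same draw within a replicate,
which is the minimal-assumption correlation structure; fully independent
per-arm draws are available via `shared_draws = FALSE` — then runs the
cohort model for both arms. Structurally invalid draws (a decrement
exceeding the drawn utility under the per-cycle basis) are rejected and
redrawn, with a hard error above 5% rejections. Results are bit-reproducible
given the seed. Summaries: the probabilistic ICER is the ratio of the mean
incremental cost to the mean incremental QALYs (per-replicate ICERs are
unstable near zero QALY differences); quadrant proportions assign exact-zero
boundary points to the north-east quadrant; the acceptability curve counts
strictly positive net monetary benefit (`NMB = WTP x dQALY - dCost`), so
ties count against the intervention — all deliberately conservative toward
the intervention.

**One-way analysis.** Each parameter in turn is set to its low and high
bound and the deterministic ICER recomputed; rows are sorted by spread into
the tornado table, and a robustness flag records whether any one-way ICER
exceeds the WTP threshold.

## Synthetic inputs and the validation oracle

**Life table.** Background mortality defaults to a synthetic
Gompertz-Makeham table, `q(x) = 1 - exp(-(a + b e^{cx}))` with
`a = 5e-4`, `b = 3e-5`, `c = 0.09` — roughly 6.5 per 10,000 at age 18 and
4% at age 80, a realistic middle-income adult mortality schedule. It
emulates the *shape and order of magnitude* of a national life table, not
any country's actual values, and carries no sex structure, cohort trends or
infant-mortality hump; conclusions that hinge on precise background
mortality (absolute life expectancy, costs accumulated late in life) should
be re-run with a real table via `read_life_table()`, which takes precedence
everywhere.

**Microsimulation oracle.** `simulate_patients()` pushes individual
patients through the *same* per-cycle matrices with the same entry-charging,
tunnel, half-cycle and discounting conventions, making its patient-mean
cost and QALYs unbiased estimators of the cohort model's totals. Agreement
within Monte-Carlo error (3 standard errors at n = 50,000 in the shipped
checks) validates the cohort algebra end-to-end — it cannot, of course,
validate the model's clinical assumptions.

**Parameter fuzzing.** `random_parameter_table()` draws structurally valid
random bundles (probabilities below 0.9, utilities in (0.3, 1) with
compatible decrements, costs in (1, 500), RR in (0.5, 1)) used by the
property checks: trace conservation to 1e-10, monotone death occupancy,
zero-discount equivalence, and exact currency-scaling invariance of the
ICER.

## Worked example

```{r base-case}
params <- asthma_parameters()
bc <- base_case(params)
bc$results
tidy(bc$incremental)
```

The deterministic lifetime comparison trades roughly $6,400 of additional
discounted cost (mostly the LAMA acquisition price, diluted by the 63%
persistence) for roughly 0.78 additional discounted QALYs, an ICER around
$8,300 per QALY — cost-effective at the $19,000 threshold with a wide
margin, which is the substantive conclusion every analysis in the package
reproduces.

```{r psa, fig.width = 6, fig.height = 4}
psa <- run_psa(params, n_reps = 200, seed = 7)
glance(psa)
autoplot(psa)
plot_ceac(ceac(psa, wtp_grid = seq(0, 20000, by = 250)))
```

```{r dsa, fig.width = 6, fig.height = 4}
dsa <- one_way_dsa(params)
head(tidy(dsa), 5)
attr(dsa, "robust")
autoplot(dsa)
```

## Numerical choices and problem sizes

* Trace conservation tolerance 1e-10; alive-mass cutoff 1e-9; transition
  row sums exact to 1e-12 by construction.
* QALY differences below 1e-12 are treated as exact ties (undefined ICER)
  rather than divided by.
* The shipped checks use 1000 PSA replicates, 100 fuzzed bundles and a
  50,000-patient microsimulation — sizes at which Monte-Carlo error is well
  below every decision margin in the model while a full run stays in the
  minutes range on a single core.
* The CEAC grid defaults to $0-$2,000 in $50 steps plus the $19,000
  decision threshold; under the package's defaults the curve crosses 0.5
  near the base-case ICER (around $8,000-$9,000), far above $700-style
  crossings that would only arise with a much smaller incremental cost.

## Known limitations

* No within-cycle continuous-time dynamics; an exacerbation's severity
  ladder resolves one rung per 2-week cycle.
* No age- or sex-specific utilities, costs or treatment effects; the
  synthetic life table is sex-averaged.
* Indirect (productivity) costs are not modelled — only direct drug and
  event costs enter.
* The discontinued state is absorbing for treatment (no re-initiation), and
  persistence applies as a single 52-week split rather than a continuous
  hazard; the stored ranges treat the printed adherence bounds as bounds on
  the 52-week persistent fraction.
* No value-of-information or budget-impact analysis.
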