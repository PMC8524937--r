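---
title: "rtflow: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rtflow: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtflow)
```

## The system being modelled

A radiotherapy department treats referred patients in two coupled stages.
The *preparation* stage bundles everything between referral and the first
fraction — mould, CT/MR imaging, target contouring, dose planning and QA —
into a single capacity-limited step with a fixed lead time, because the
department books it as one pipeline and its internal sub-steps share
staff. The *treatment* stage delivers one fraction per working day per
patient on the linac pool until the prescribed fraction count is reached.
The pain point is the legally mandated summer vacation: several weeks of
reduced capacity in both stages whose depth, length and relative timing
are management decisions. The package simulates those decisions.

`rtflow` implements a deterministic continuous (stock-and-flow)
simulation: stocks are real-valued patient quantities, flows are rate
limited by capacity, and there is no within-run randomness. Randomness
enters only through the synthetic referral generator, which is seeded.

## State, clock, and the daily update

The clock ticks in working days (default 5 per week; weekends deliver no
fractions). A week's referrals enter on its first working day — referral
systems batch bookings weekly, and finer inter-arrival structure is not
observable in a weekly extract anyway.

Per workflow group (a diagnosis × intent class sharing a fraction count),
the state is:

* `awaiting_prep` — referred, not yet started preparation;
* `in_prep` — a conveyor with one slot per remaining lead day; entries
  exit exactly `prep_lead_working_days` after entry;
* `ready_to_start` — preparations complete, waiting for a linac slot,
  kept FIFO by completion day;
* `in_treatment` — an aging chain indexed by remaining fractions,
  advanced one slot per working day;
* `completed`.

The daily update order is: arrivals; preparation starts (capacity-limited,
allocated across groups proportionally to their awaiting stock); conveyor
advance; ongoing treatment demand served unconditionally; new treatment
starts from residual capacity (FIFO by completion day, proportional across
groups within a day); chain advance and completion. Two accounting
identities hold by construction and are re-derived from independent
bookkeeping at every step (the engine records the largest residuals):
cumulative arrivals equal the sum of all stocks plus completions, and a
completed course has received exactly its prescribed fractions — also when
a pooled group carries a fractional mean fraction count, in which case the
final treatment day consumes the fractional remainder.

## Parameters

| parameter | unit | default | why |
|---|---|---|---|
| `prep_capacity_per_week` | patients/week | 100 | lowest round level that leaves the preparation queue stable under the default scaled inflow (≈89 courses/week) |
| `treat_capacity_per_day` | fraction-units/day | 330 | lowest round level that keeps the ready queue stable under the same inflow |
| `treatment_days_per_week` | days | 5 | weekday-only fractionation |
| `prep_lead_working_days` | working days | 8 | ≈1.5 five-day weeks from mould to QA, rounded up to whole conveyor slots; results are insensitive within 5–10 days |
| `first_fraction_weight` | fraction-units | 2 | the first fraction takes about twice the linac time (patient information, technical verification) |
| `pareto_share` | — | 0.8 | the 80/20 rule: keep the high-volume workflows, pool the tail |
| `treat_start_week` | week | 27 | early summer in a 70-week horizon starting in January |

Two policies deserve emphasis because they shape every result. First,
*ongoing treatments are never interrupted*: when reduced capacity cannot
cover the patients already under treatment, the excess is delivered as
overtime. Clinically, pausing a fractionation schedule compromises tumour
control, so departments absorb the load instead. Second, *preparation
capacity limits starts* (conveyor entry), not completions — the
booking-slot interpretation — so a capacity change reaches the ready queue
only one lead time (≈1.6 weeks) later.

## The synthetic booking generator

`generate_bookings()` emulates a two-stage booking extract: one row per
scheduled treatment course with referral week, diagnosis label, intent and
fraction count. Its defaults define the study conditions used throughout
the tests:

* weekly referral counts are homogeneous Poisson with mean 52.4
  courses/week over 70 weeks (≈3670 courses), matching the volume of a
  70-week departmental extract; an optional sinusoidal seasonality flag
  exists but is off by default;
* intent is Bernoulli with curative share 0.65;
* diagnoses follow a Zipf law over 128 raw diagnosis × intent groups with
  exponent 1.4. The exponent is calibrated so that an 80/20 Pareto
  aggregation of a generated extract retains roughly 21 workflow groups
  (15–30 across seeds) — the case-mix concentration a real department
  exhibits;
* fraction counts are uniform per intent: curative 15–29, palliative
  1–10. The curative range is set jointly with the inflow so that the
  default baselines (100/week, 330/day) are the lowest stable round
  levels after scaling by 1.7: a longer curative mix would overload a
  330-unit treatment day at this inflow. Mean demand sits near 93% of
  treatment and 89% of preparation capacity — tight, as a "lowest stable
  level" calibration implies;
* duplicates and invalid rows (zero fractions, unknown intent) can be
  injected at known rates, and `clean_bookings()` must recover exactly
  the injected counts — this closes the loop on the cleaning rules.

What the generator does **not** emulate: real referral seasonality (the
summer dip in particular), correlated arrivals, diagnosis-specific
fractionation schedules (including the long conventional courses of 33–39
fractions some curative diagnoses use), re-irradiation structure, and
priority classes. Passing tests on synthetic data therefore demonstrate
the mechanics and internal consistency of the pipeline, not calibration to
any particular clinic.

## Scenario metrics and calibration

`compute_metrics()` reports the peak of the ready-to-start queue and its
week, total and weekly overtime and idle units, and mean treatment
utilization (delivered/capacity) in the vacation window and in 4-week
windows before and after it; utilization can exceed 1 when overtime is
worked. Reports aggregate to weeks; the engine stays daily internally.

`calibrate_baseline()` bisects on one part's capacity until a no-vacation
run stops building a *persistent* queue. Persistence is judged on
low-water marks: the minimum of the daily queue over the last four weeks
must not exceed the minimum over the four weeks around mid-horizon by more
than one patient. Minima are used because the weekly arrival pulse and
Poisson referral noise leave transient spikes at any capacity; a genuinely
undersized capacity ratchets the low-water mark upward, a transient does
not. On constant-inflow instances the result matches the closed-form load
(`rate × (fractions + first_fraction_weight − 1) / 5` units/day) to one
capacity unit.

## Numerical choices

* Stocks stay real-valued everywhere; integer patients exist only in the
  per-patient oracle simulator used by the tests.
* Pareto ordering breaks count ties lexicographically on the group label;
  the group that crosses the cumulative threshold is included. Pooled
  tail groups get the patient-weighted mean fraction count, and kept
  groups the mean of their members.
* Week indexing is ISO (Monday-start), 1-based from the earliest
  referral.
* Scaled weekly counts are not rounded — rounding would distort
  low-volume groups in a continuous model.
* Degenerate inputs are defined, not errors: empty schedules simulate to
  all-zero flows with full idle capacity; zero treatment capacity
  accumulates every preparation completion in the ready queue; a
  zero-capacity calibration target returns 0.
* The simulated horizon is 70 weeks with the vacation placed at week 27,
  so the ~15 weeks before the window double as warm-up from the empty
  initial state; no warm-up shortcut is applied.
* The conveyor uses a fixed (pipeline) delay rather than a first-order
  exponential delay: preparation takes what it takes, it does not decay.

## Validation strategy

The test-suite validation mirrors how continuous simulation models are
checked in practice: structural checks (conservation identities at every
step on stochastic paper-scale runs), extreme-value tests (zero inflow,
zero capacity, blocked downstream), closed-form limits (a Little's-law
census of `rate × fractions / 5` patients under ample capacity, exact
positive homogeneity of all trajectories under joint scaling of inflow
and capacities), and exact equivalence with an independently coded
per-patient event-list simulator on integer instances where continuous
allocation never splits a patient.

Problem sizes are chosen to keep the full suite fast: 70-week horizons at
~6300 scaled courses for stochastic runs, ≤20-week integer instances for
the oracle, and ≤60-week constant-inflow instances for calibration.

## Known limitations

* Linac downtime/maintenance, treatment-technique time differences,
  machine assignment and intra-day scheduling are out of scope.
* No medical priority classes: admission is strictly FIFO. Real
  departments expedite palliative and emergency courses.
* The model's vacation-scenario comparisons are sensitive to the case-mix
  composition. Two behaviours reported from practice are *not* robustly
  reproduced under the default synthetic conditions, and the mechanism is
  instructive. (a) Moving the preparation vacation four weeks ahead of
  the treatment vacation lets preparation return to full capacity while
  treatment is still reduced; the catch-up flood of completions then
  builds a ready queue at least as large as the simultaneous-vacation
  scenarios unless full-capacity treatment absorption exceeds the
  preparation capacity. (b) Under a four-week 70% reduction, overtime in
  the final vacation week requires a sizeable share of courses longer
  than ~35 fractions; with the default 15–29 fraction curative mix the
  ongoing-treatment census decays below the reduced capacity after about
  three weeks. Both hinge on the long-course tail of the real case mix,
  which the uniform synthetic fraction distribution deliberately lacks.
* With tight baselines (the "lowest stable level" setting), metrics vary
  noticeably across generator seeds; scenario comparisons should be read
  per-seed on identical schedules, which `run_suite()` guarantees.
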