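---
title: "A microsimulation model of osteoporosis treatment sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A microsimulation model of osteoporosis treatment sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosim)
```

## The decision problem

Community-dwelling osteoporotic women without a prior fragility fracture can
be offered injectable anti-resorptive therapy. Two realistic strategies are
compared here from the perspective of a payer responsible for healthcare
(and, in the primary analysis, long-term care) costs in Japan:

* **Zoledronic acid (ZA)** — one intravenous infusion per year for a planned
  3 years.
* **Sequential denosumab/alendronate (D/A)** — subcutaneous denosumab every
  6 months for 3 years, followed, *only among women persistent through the
  full denosumab course*, by weekly oral alendronate for 3 years.

The outputs are lifetime discounted costs (yen, displayed also in dollars at
a fixed ¥105/$) and quality-adjusted life-years (QALYs), compared as an
incremental cost-effectiveness ratio (ICER) or a dominance verdict, plus
deterministic and probabilistic sensitivity analyses.

## Model structure

Each woman is simulated one cycle (one year) at a time from her starting age
(65, 70, 75 or 80) until death or age 105. Tracker variables carry her
memory between cycles: fracture counts and recency, and the state of her
treatment episode. Within a cycle the fixed order is:

1. **Treatment update.** The cycle's relative risks of hip and clinical
   vertebral fracture are determined by the treatment rules below.
2. **Fracture draw.** At most one fracture per cycle: the hip draw comes
   first, the vertebral draw only if no hip fracture occurred. Hip fractures
   are capped at two per lifetime; vertebral fractures are unlimited. The
   per-cycle probability is the general-population incidence rate times the
   age-banded osteoporosis relative risk, the same-site prior-fracture
   relative risk (2.3 hip, 4.4 vertebral), and the treatment relative risk.
3. **Death draw.** The life-table annual death probability, inflated after a
   hip fracture by `1 + f (RH - 1)` with hazard ratio 2.87 in the fracture
   year and 1.73 lifelong thereafter, attenuated by the attributable
   fraction `f = 0.25` (comorbidity explains the rest of the observed excess
   mortality). Vertebral fractures carry no excess mortality in the base
   case; a scenario flag gives them the hip values. A second hip fracture
   restarts the first-year hazard; multipliers never stack.
4. **Accrual.** Costs and utilities for the cycle, discounted at 2%/year
   with the first cycle undiscounted (`(1+r)^-(t-1)`; no half-cycle
   correction on the per-cycle weights).

Women dying in a cycle still accrue that cycle's fracture cost (acute care
happens) but no utility and no long-term care cost.

### Events happen mid-cycle

Two accrual rules follow a single declared stance: a fracture or a
treatment stop occurs, on average, in the middle of a cycle.

* **Offset ramp.** After stopping a bisphosphonate, the relative risk
  returns to 1 linearly over a period equal to the number of years treated.
  The engine evaluates this continuous ramp at the mid-year of each
  post-treatment cycle (`(t - 0.5) / years_on`), so a 3-year completer
  retains partial protection in post-years 1–3 and none afterwards — the
  direct-plus-residual effect spans exactly 6 years. Evaluating at cycle
  ends instead would silently cut the residual period to 2 years and, in
  our exact cohort computations, reverses the sign of the QALY increment
  between the arms; the mid-cycle rule reproduces the small positive QALY
  gain for ZA at every starting age.
* **Long-term care.** The post-hip state costs ¥876,000/year and the
  post-vertebral state ¥213,000/year (post-hip dominates), charged for every
  cycle survived in the state; the fracture cycle itself accrues the average
  of the entry and exit states — half a year of the new state for a first
  fracture.

### Treatment rules

* **Effect while persistent.** A woman receives a drug's protective relative
  risk in a cycle only if she is still persistent at the end of that cycle.
  The year in which she discontinues confers no protection, and the offset
  clock starts the following cycle with `years_on` equal to her completed
  years.
* **Adherence.** Oral alendronate's effectiveness scales linearly with
  adherence: `RR_eff = 1 - adherence (1 - RR_trial)`, with adherence
  declining linearly from 70.6% (year 1) to 60.9% (year 5) and held flat
  beyond. Injectables count as fully adherent while persistent.
* **Denosumab cliff.** Denosumab's effect disappears at the end of the cycle
  of the final dose: no offset, whether she stopped early or completed.
  Denosumab stoppers never start alendronate; completers hand over to
  alendronate immediately, and alendronate (a bisphosphonate) earns its own
  offset afterwards.
* **Discontinuation.** The year of stopping is drawn once per episode from
  the differenced cumulative persistence curve — e.g. ZA (100, 52, 36)%
  gives stop-year probabilities (0, 0.48, 0.16) and completion 0.36. Because
  this is the only randomness in a treatment path, each arm reduces to a
  small set of deterministic trajectory schedules; individuals draw a
  trajectory with one uniform. The derived curves (denosumab's sixth-dose
  37% from the dose-2→4 ratio; year-4+ extensions chaining the last
  year-on-year ratio, unrounded) are computed, not hard-coded.

### Costs

All costs are 2020 yen. Persistent years are charged medication (adherence-
scaled for alendronate, plus its ¥1,700 annual pharmacy charge), the drug's
visit schedule (ZA: 2 visits + 2 blood tests; denosumab: 4 + 4, or 2 + 2
under the reduced-visit scenario; alendronate: 4 visits + 2 tests; the
first visit of an episode at the first-visit fee) and ¥2,900 per blood
test. Discontinuation years are charged half of each annual component, with
two floors taken from the fee schedule: an alendronate year-1 stopper pays
one filled 3-month prescription, and a denosumab year-1 stopper one dose.
DXA scans (¥4,500) are charged to everyone alive at the end of years 3 and
6 in both treatment arms (not in the no-intervention validation arm).
Fracture events cost ¥1,726,000 (hip), ¥420,000 (first vertebral) or
¥842,000 (subsequent vertebral). The healthcare-only perspective simply
drops the long-term care component, which is tracked separately.

### Utilities

Age-band utilities (0.862 at 65–69 down to 0.684 at 85+) are multiplied by
the event-year disutility of this cycle's fracture (0.776 hip, 0.724
vertebral — the vertebral event multiplier applies even in a post-hip
woman) or otherwise by the lifelong post-state multiplier (0.855 post-hip,
which dominates, else 0.868 post-vertebral).

## Random numbers and reproducibility

All uniform draws for an arm are pre-generated from the seed in a fixed
layout (trajectory, then hip/vertebral/death blocks per cycle), so a run is
bit-reproducible from `(config, seed, n_trials)` and two arms run with the
same seed share their randomness individual-by-individual. These common
random numbers make incremental results far more stable than independent
arms would be, which matters because the true QALY increment is of order
0.001. The same effect could be had with counter-based per-individual
substreams; pre-generated blocks are the idiomatic way to get it in base R.

## Verification strategy

The package carries an exact verification path alongside the sampler:

* `cohort_oracle()` — a deterministic expanded-state chain over (hip count
  0–2) × (any vertebral fracture), applying identical cycle rules, for
  no-treatment configurations.
* `arm_expectation()` — the same chain run per enumerated treatment
  trajectory and mixed by the trajectory probabilities, giving exact arm
  means with no sampling at all.

The test suite holds the microsimulation to within 3 Monte-Carlo standard
errors of these expectations, and checks degenerate configurations (zero
incidence and mortality, utility 1, no discounting) against closed forms
(exactly 40 undiscounted QALYs from age 65, zero cost).

## The synthetic life tables

Nothing downloads at build or test time. Two tables ship in code:

* `make_synthetic_life_table()` — a two-parameter Gompertz hazard
  (`q65 = 0.005`, log-slope 0.12/year), used by the fast test
  configuration. It reproduces the qualitative behaviour the engine needs
  (monotone hazards; >99% of 65-year-olds dead by 105).
* `japan_like_life_table()` — a synthetic reconstruction of a 2018 Japanese
  female abridged table: 5-year anchor probabilities chosen to match the
  published summary behaviour of that table (life expectancy at 65 of 24.5
  years; >99% death by 105), filled to single years by log-linear
  interpolation. It is *not* the official table; `load_life_table()`
  accepts the official CSV as a drop-in where exact national mortality is
  required. Fracture-risk validation against published lifetime
  probabilities therefore carries the reconstruction's residual error,
  which is why those checks use a ±2-percentage-point band.

Neither table emulates cohort trends, seasonal mortality, or
cause-of-death structure; passing tests say the engine composes mortality,
incidence and treatment rules correctly, not that any specific population's
absolute risk is reproduced.

## Problem sizes and numerical choices

Base-case and validation runs use 100,000 trials, matching the scale the
results tables were produced at; the probabilistic sensitivity analysis is
run at 200 parameter draws × 20,000 trials in the tests and acceptance
script (the full 1000 × 100,000 is a few hours of CPU and changes the
acceptability probabilities by less than a percentage point, as the exact
per-draw expectations confirm). Probabilities are truncated at 1 after risk
multiplication; fracture-capped states (two hip fractures) set the hip
probability to zero. Beta and gamma PSA distributions are fitted by exact
matching of the 2.5% and 97.5% quantiles to the published intervals
(Nelder–Mead on log shape parameters, verified to 1e-3 relative error);
triangular distributions take the base value as mode. Persistence curves
are sampled with a single shared quantile across years so every sampled
curve is monotone; all other parameters are drawn independently.

## Known limitations

* Only hip and clinical vertebral fractures are modelled; other sites
  (forearm, humerus) and atypical femur fractures are out of scope.
* The denosumab discontinuation "rebound" above baseline risk is exposed as
  a configuration flag for forward compatibility, but the engine refuses to
  run it: no published magnitude exists to parameterise it, and a quick
  reversal to baseline (the conservative reading) is the implemented
  behaviour.
* The post-denosumab strategy space is fixed (alendronate or nothing);
  zoledronic acid after denosumab is not modelled.
* Cost levels are 2020 Japanese fee-schedule values with no inflation
  adjustment, and no male life tables are provided.
* The healthcare-only cost level is more sensitive than the combined
  perspective to the life-table reconstruction, because fracture counts
  scale with old-age survival while long-term care years partially offset
  them in the combined total.
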