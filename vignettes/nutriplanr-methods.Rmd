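---
title: "Models and methods behind nutriplanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nutriplanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriplanr)
library(dplyr)
```

nutriplanr implements the computational core of a nutritionist/user
food-plan workflow: estimating how much energy a person spends, turning
that estimate into a macronutrient-balanced food plan, logging what was
actually eaten and drunk (including device exports from smart bottles and
smartwatches), learning food preferences from those logs, and estimating
the human–computer interaction cost of the logging tasks themselves with
the keystroke-level model (KLM). This vignette explains each model, its
assumptions, the tunable parameters, and the design choices taken where
the problem left them open.

## Energy expenditure

The accounting identity at the top of the hierarchy is the caloric
balance

$$CB = CC - PEE - REE - TEF,$$

where $CC$ is caloric consumption, $PEE$ the physical-activity energy
expenditure (observable from smartwatch active-calorie logs), $REE$ the
resting energy expenditure, and $TEF$ the thermic effect of food.
`caloric_balance()` computes $CB$ exactly from its inputs. TEF
contributes roughly 3–10% of total expenditure but is notoriously hard to
measure, so it is a pass-through parameter defaulting to 0; nothing in
the package tries to estimate it.

$REE$ is treated as equivalent to basal metabolic rate and estimated by
four interchangeable equations, each increasing in body (or lean) mass:

* Harris–Benedict (original coefficients; sex-specific, takes weight in
  kg, height in **cm**, age in years);
* Mifflin-St Jeor ($10W + 6.25H - 5A + 5$ for men, $-161$ for women);
* Katch-McArdle ($370 + 21.6 \cdot \mathrm{LBM}$);
* Cunningham ($500 + 22 \cdot \mathrm{LBM}$).

The coefficient sets are frozen as package constants, verified by unit
tests, so results do not depend on any external calculator. Two of the
equations need lean body mass, obtained as `fat_free_mass(weight,
fat_mass)` when a body-composition measurement is available. A deliberate
unit split — metres for `bmi()`, centimetres for the BMR equations — follows
each formula's native convention; `m_to_cm()`/`cm_to_m()` make the
conversion explicit at call sites.

Total energy expenditure scales REE by the physical activity level:
$PAL = TEE/REE$, so `tee(ree, pal) = ree * pal` and the quotient recovers
PAL to machine precision. PAL itself comes from either of two methods,
and deliberately takes no sex argument (BMR already absorbs the sex
difference in energy needs):

* **Lifestyle category** (`pal_from_lifestyle()`): sedentary/light
  1.40–1.69, moderately active 1.70–1.99, vigorous 2.00–2.40. The range
  midpoint is returned as a convenient default, but the bounds are
  exposed because the choice of a working value inside the range is a
  clinical judgement, not a computation; `energy_report()` uses the
  midpoint.
* **24-hour time allocation** (`pal_from_time_allocation()`): each
  habitual activity contributes hours × PAR (physical activity ratio, a
  multiple of BMR with PAR = 1 at rest), and PAL is the total divided
  by 24. Hours must partition the day exactly (tolerance $10^{-9}$ h) and
  every PAR must be ≥ 1. The function returns the intermediate
  $\sum h \cdot PAR$, the exact quotient, and a one-decimal value rounded
  half-up, the convention used when a population-group PAL is reported
  (e.g. the reference nine-activity day: $42.6 / 24 = 1.775$, reported
  as 1.8). Half-up rounding is used rather than R's default round-to-even
  because reported PALs and task times follow the half-up convention.

## From energy target to food plan

A plan's daily energy target (normally the TEE estimate) is split across
macronutrients by energy-share fractions $\alpha$ (protein), $\gamma$
(carbohydrate) and $\beta$ (lipid) with $\alpha + \gamma + \beta = 1$:
the fractions multiply *energy*, not grams. Gram equivalents follow from
the Atwater factors 4/4/9 kcal per g. Fiber and water carry zero calories
here: soluble fiber can be partially absorbed, but there is no accepted
conversion factor, so it stays out of the energy ledger while remaining a
tracked nutrient with its own gram target.

All accounting runs through a single currency, the *nutrient vector*: a
one-row tibble with energy, the three macros, fiber, water, and four
control micronutrients (iron, calcium, sodium, magnesium — chosen for
their relevance across population groups; the set is fixed in this
implementation). Food compositions are stored per 100 g, the dominant
food-table convention, and scaled by `quantity/100`; addition and scaling
are exact component-wise bookkeeping with no hidden rounding.

`plan_totals()` aggregates a plan variant per meal or per day, and
`validate_plan()` compares day totals (and, when the plan records
per-meal energy fractions, each meal's energy) against targets using the
relative error $|actual - target| / \max(target, \varepsilon)$ with
$\varepsilon = 10^{-9}$. A zero-target nutrient with nonzero intake thus
reports a huge relative error rather than `NA`; this is intentional — a
target of zero that is violated should surface loudly. Only nutrients
beyond the caller's tolerance are reported, so an empty result means the
plan meets its targets.

**Substitution search.** `equivalent_foods()` defines nutritional
equivalence on the three caloric macronutrients: a candidate's quantity
is solved so its energy matches the reference serving (foods with zero
energy density are skipped — they cannot match on energy), and the
candidate survives if each macro at that quantity is within a relative
tolerance (default 15%) of the reference's. Micronutrients are reported
as informational deltas rather than filters, because tightening all ten
dimensions would leave almost no candidates in a realistic table.
Ranking is by summed relative macro error with ties broken
lexicographically by `food_id`, which makes the output invariant under
food-table row order.

**Hydration rules.** A plan's water goal is a base volume plus
temperature-triggered increments: every rule whose threshold is
*strictly* exceeded adds its extra volume, cumulatively. This makes
`adjust_water_goal()` monotone non-decreasing in temperature and equal to
the base at or below the first threshold. Strict crossing and cumulative
increments are design choices; the source material only states that such
rules exist in the plan.

## Intake logging

The log is a plain tibble, one row per event, each keyed by the
timestamp's calendar date or by an event label (`"train"`,
`"competition"`) that overrides the date. Seven kinds of entry cover the
user-domain actions: full-meal confirmation, partial intake (a single
percentage applied uniformly to all items of the meal), substitution of
one planned food by another, removal of a planned food, extra food
outside the plan, water, and activity calories.

Replay semantics were the main open design question. The rules used:

* `confirm` and `partial` are mutually exclusive per (key, meal) —
  re-logging raises a conflict rather than double counting;
* substitutions and removals *modify* the planned meal and by themselves
  mark it consumed (they are meal-level logging actions, and several may
  stack on one meal); a partial percentage, if present, scales the
  modified meal;
* extra food counts against the day total, not any particular meal,
  since a snack between meals has no natural meal slot.

`daily_stats()` is a pure function of the entry multiset — order of
entries never matters — and pairs consumed totals with plan targets,
passing the water target through `adjust_water_goal()` when a
temperature reading is supplied. Fractions of target are `NA` (never a
division error) where the target is zero. The logged activity calories
are the observed PEE, ready for `caloric_balance()`.

Device exports are ingested from two-column `timestamp,value` CSVs.
Malformed rows are rejected with their line number but never abort the
batch, and duplicate timestamps are skipped first-wins (in file order,
and against rows already ingested for the same kind), so re-ingesting
overlapping exports is idempotent.

## Preference learning

The recommendation layer needs a per-user, per-context food preference
signal. Reinforcement learning is a natural fit in the long run, but with
no defined state/action/reward structure to target, this package provides
a deliberately simple, deterministic baseline that is testable and
swappable: exponential-decay acceptance scoring. Each (food, context)
pair — context being (meal type, day of week) — carries a score in
$[0, 1]$, starting at a `prior` (default 0.5) and updated per event as

$$s \leftarrow s \cdot decay + (1 - decay) \cdot reward$$

with reward 1 for acceptance (meal confirmed, extra food logged,
substitution *towards* the food) and 0 for rejection (substitution *away*
from the food). Rewarding the incoming food of a substitution is an
extension of the base rule: the user actively chose it. The default
`decay` of 0.8 keeps roughly five events of memory; both parameters are
configurable. Scores are provably confined to $[0, 1]$ for any event
sequence, and updates are order-dependent but reproducible from an
ordered log.

`recommend()` ranks the nutrient-equivalence candidate set by score
(descending), then macro error, then food id — preference dominates
*within* the equivalence set, never overrides it. Parameter-recovery
tests plant a favourite food per context, simulate 200 choice events, and
verify the favourite is ranked first in at least 90% of contexts.

## Interaction-cost model (KLM)

The keystroke-level model prices an expert's task as
$T_{task} = T_{acquire} + T_{execute}$, with
$T_{execute} = \sum_{op} n_{op} \cdot t_{op}$ over seven operators:
K keystroke (0.12 s), P point (1.1 s), H homing (0.4 s), B button press
(0.1 s), M mental preparation (1.35 s), plus D (draw) and R (system
response), which are interface-specific measurements and therefore
injectable parameters defaulting to 0.

Operator strings use a compact grammar in which a positive integer prefix
repeats the *next single operator* only: `42K` is forty-two keystrokes
(multi-operator grouping is not part of the notation). `klm_parse()`
reports illegal characters and dangling digits with their position;
execution time is linear under concatenation, and reported times are
rounded half-up to 2 decimals to match published interaction tables.

`klm_reference_tasks()` carries the application's task inventory with its
published times, and `klm_report()` recomputes every row from its
sequence (with $T_{acquire} = 0$, consistent with all reconcilable rows)
and flags recomputations differing by more than 0.005 s. Two rows flag by
design rather than being silently matched: the statistics view (`PBPB`
recomputes to 2.40 s against a published 1.20 s — the published value is
inconsistent with its own operator constants) and the Fitbit consent task
(`PBPBPBR` published at 4.60 s, implying a measured R of 1.0 s; R stays a
parameter, and `klm_operator_times(R = 1)` reconciles the row).

## Synthetic data

Because no real food tables, plans or logs ship with the package, seeded
generators stand in for them; every generator is a pure function of its
seed.

* `generate_food_table()` cycles six broad food classes (protein-rich,
  grain, vegetable, fruit, dairy, fat-rich) with class-typical per-100 g
  macro ranges, and sets each food's energy *exactly* to its Atwater
  value, so generated tables are energy-consistent by construction.
* `generate_meal_plan()` builds one variant per weekday (plus optional
  event variants) of four meals, scaling quantities so each variant's
  energy equals the target exactly (shares 25/35/10/30% across
  breakfast, lunch, afternoon snack, dinner, split equally within a
  meal).
* `generate_week()` simulates seven days of logging: each planned meal
  is logged with probability `adherence` (default 1) — as a substitution
  with probability `substitution_p` (default 0), otherwise a confirmation
  — plus Poisson-distributed bottle sips (mean 6/day, 100–350 mL) and one
  truncated-normal activity record per day (mean 350, sd 100 kcal).
  At full adherence and no substitutions the simulated consumption
  reproduces plan totals exactly, which ties the generator to the
  logging arithmetic.
* `generate_preference_log()` simulates context-dependent choices with a
  planted favourite chosen with probability 0.85 per event.

What the generators deliberately do **not** emulate: measurement error in
food-composition values, under-reporting and skipped logging days beyond
a uniform adherence probability, correlated food choices within a meal,
seasonal or weather-driven preference drift, and device clock skew.
Passing tests therefore demonstrate the *bookkeeping and ranking logic*
on clean, well-formed data, not robustness to the noise of real-world
diet records.

## Numerical choices and problem sizes

All comparisons against targets use relative error with an $\varepsilon =
10^{-9}$ denominator guard; fraction sums ($\alpha+\gamma+\beta$, 24-hour
partitions) are checked to $10^{-9}$; reported values round half-up
(PAL to 1 decimal, task times to 2). Property suites run on modest sizes
chosen to exercise the logic thoroughly while keeping the whole test
suite under half a minute: 15–30-food tables, week-long plans, 20–30
fuzz iterations per invariant, and 200-event preference simulations.

## Known limitations

* Skinfold and body-composition estimators (3-site skinfold, muscle-mass
  and segment equations) are out of scope; lean mass must be supplied.
* Plan composition is assistive, not generative: the package validates
  and totals plans a nutritionist composes, it does not optimise one.
* The preference baseline has no pathway for nutritionist feedback and
  no notion of food similarity across contexts.
* Live device APIs are out of scope; ingestion is file-based by design.
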