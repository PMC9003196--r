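# nutriplanr

Precision nutrition depends on a tight loop between a nutritionist who
builds a food plan and a person who follows it: the plan must match the
person's energy expenditure, intake must be logged meal by meal (and sip
by sip), and the logging itself must cost so little effort that people do
not give up. `nutriplanr` implements the computational core of that loop
as a tidyverse-style R package:

* **Energy expenditure** — REE/BMR by Harris–Benedict, Mifflin-St Jeor,
  Katch-McArdle and Cunningham; physical activity level (PAL) from
  lifestyle categories or from a 24-hour time allocation of activities
  (PAL = Σ hours·PAR / 24); TEE = REE × PAL; caloric balance
  CB = CC − PEE − REE − TEF.
* **Plan building** — macronutrient energy split
  E = αE_protein + γE_carbs + βE_lipids with Atwater 4/4/9 gram
  conversion; per-meal and per-day nutrient totals; validation against
  targets; nutrient-equivalent food substitution; temperature-adjusted
  hydration goals.
* **Intake logging** — meal confirmations, partial intakes,
  substitutions, extra foods, water and smartwatch activity calories;
  device-export CSV ingestion with duplicate-safe replay; daily
  statistics paired with plan targets.
* **Preference learning** — a deterministic exponential-decay acceptance
  model over (food, meal type, day of week) contexts, ranking
  substitution candidates by learned preference within the
  nutrient-equivalence set.
* **Interaction cost (KLM)** — a keystroke-level-model engine
  (T_task = T_acquire + T_execute, T_execute = Σ n_op · t_op over
  operators K/P/H/B/M/R/D, with repeat prefixes like `42K`) that
  recomputes the application's published task-time table and flags
  inconsistent rows.
* **Synthetic data** — seeded generators for food tables, week-long
  plans, adherence logs and preference histories, so everything is
  testable with no external data.

Functions take data frames first and return tibbles, so calls chain with
the pipe; result objects have `tidy()`/`glance()` methods and
`autoplot()` plots.

## Worked example

```r
library(nutriplanr)

# appointment: 31-year-old woman, 62 kg, 1.68 m, 14 kg fat mass,
# moderately active
energy_report("female", 62, 1.68, 31, lifestyle = "moderate",
              fat_mass_kg = 14)
#>   equation        ree_kcal   pal tee_kcal   bmi
#> 1 harris_benedict    1414.  1.84    2608.  22.0
#> 2 mifflin_st_jeor    1354   1.84    2498.  22.0
#> 3 katch_mcardle      1407.  1.84    2596.  22.0
#> 4 cunningham         1556   1.84    2871.  22.0
```

Four REE estimates (kcal/day), each multiplied by the moderate-lifestyle
PAL midpoint 1.845 to give a TEE around 2500–2900 kcal/day. Splitting a
2452 kcal target 25/50/25 across protein/carbs/lipids:

```r
macro_energy_split(2452, alpha = 0.25, gamma = 0.5, beta = 0.25)
#>   energy_protein energy_carbs energy_lipids grams_protein grams_carbs ...
#> 1            613         1226           613          153.        306. ...
```

613 kcal of protein is 153 g (Atwater 4 kcal/g); lipids convert at
9 kcal/g. Build a synthetic plan and check it against those targets:

```r
ft   <- generate_food_table(30, seed = 42)
plan <- generate_meal_plan(ft, plan_targets(2452, 0.25, 0.5, 0.25,
                                            fiber_g = 28, water_ml = 2000),
                           seed = 42)
validate_plan(plan, ft, "monday", tolerance = 0.08)
#>   scope meal_type nutrient  target actual relative_error
#> 1 day   <NA>      protein_g  153.    185.          0.204
#> 2 day   <NA>      carbs_g    306.    166.          0.458
#> 3 day   <NA>      lipids_g    68.1   117.          0.712
#> 4 day   <NA>      water_ml  2000     775.          0.612
```

The generator matches the plan's *energy* exactly (no energy row
appears), but its randomly drawn foods miss the macro split — exactly the
feedback a nutritionist uses to rebalance food choices. Simulate a
logged week at 90% adherence and summarise Monday:

```r
week <- generate_week(plan, ft, adherence = 0.9, substitution_p = 0.1,
                      seed = 7)
daily_stats(week, plan, ft, "monday", "2022-03-07")
#> <daily_stats> 2022-03-07
#>   nutrient    consumed target fraction_of_target
#> 1 energy_kcal   1839   2452                0.75
#> ...
#> water: 2453 / 2000 mL; logged activity: 320 kcal

caloric_balance(cc = 1839, pee = 320, ree = 1404)
#>     cc   pee   ree   tef    cb
#> 1 1839  320.  1404     0  115.
```

The user ate 75% of the energy target, over-drank the water goal, and
the day closes 115 kcal above balance once resting and activity
expenditure are subtracted. Finally, the interaction-cost table:

```r
klm_report()[c(3, 5, 12), c("task", "sequence", "published_s",
                            "estimated_s", "flagged")]
#>   task                 sequence        published_s estimated_s flagged
#> 1 Log food intake      PBPBMHKKKMHPBPB        8.66        8.66 FALSE
#> 2 Log food intake      PBPBPB                 3.6         3.6  FALSE
#> 3 Visualize statistics PBPB                   1.2         2.4  TRUE
```

Adding an extra food costs 8.66 s of interaction; the statistics-view
row is flagged because its published 1.20 s is inconsistent with its own
`PBPB` operator sequence (which prices at 2.40 s).

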