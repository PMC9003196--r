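# Synthetic data generators. Every generator is a pure function of its
# `seed` (withr::with_seed restores the caller's RNG state), so stochastic
# tests are replayable and a written fixture can always be regenerated.

# per-100 g macro density ranges (g) by food class; broadly realistic for
# composition-table entries of each class
food_classes <- tibble::tribble(
  ~class, ~protein_lo, ~protein_hi, ~carbs_lo, ~carbs_hi, ~lipids_lo, ~lipids_hi, ~fiber_hi, ~water_hi,
  "protein_rich", 18, 30, 0, 3, 2, 15, 0.5, 75,
  "grain", 6, 13, 45, 75, 1, 8, 10, 14,
  "vegetable", 1, 4, 3, 10, 0.1, 1, 5, 95,
  "fruit", 0.3, 2, 8, 20, 0.1, 1, 4, 90,
  "dairy", 3, 12, 3, 6, 1, 10, 0, 88,
  "fat_rich", 0, 25, 0, 20, 30, 80, 8, 5
)

#' Generate a synthetic food-composition table
#'
#' Draws `n_foods` foods cycling over six broad classes (protein-rich,
#' grain, vegetable, fruit, dairy, fat-rich) with class-typical macro
#' density ranges, fills in the four control micronutrients at plausible
#' per-100 g levels, and sets each food's energy exactly to its Atwater
#' value 4*protein + 4*carbs + 9*lipids, so generated tables are
#' energy-consistent by construction.
#'
#' @param n_foods Number of foods (> 0).
#' @param seed Integer seed; same seed, same table.
#' @return Food-composition tibble (see [read_food_table()] for columns).
#' @export
generate_food_table <- function(n_foods, seed = 1) {
  check_positive(n_foods, "n_foods")
  withr::with_seed(seed, {
    cls <- food_classes[rep_len(seq_len(nrow(food_classes)), n_foods), ]
    protein <- stats::runif(n_foods, cls$protein_lo, cls$protein_hi)
    carbs <- stats::runif(n_foods, cls$carbs_lo, cls$carbs_hi)
    lipids <- stats::runif(n_foods, cls$lipids_lo, cls$lipids_hi)
    tibble::tibble(
      food_id = sprintf("f%03d", seq_len(n_foods)),
      name = paste0(cls$class, "_", seq_len(n_foods)),
      energy_kcal = 4 * protein + 4 * carbs + 9 * lipids,
      protein_g = protein, carbs_g = carbs, lipids_g = lipids,
      fiber_g = stats::runif(n_foods, 0, cls$fiber_hi),
      water_ml = stats::runif(n_foods, 0, cls$water_hi),
      iron_mg = stats::runif(n_foods, 0.1, 5),
      calcium_mg = stats::runif(n_foods, 5, 150),
      sodium_mg = stats::runif(n_foods, 1, 600),
      magnesium_mg = stats::runif(n_foods, 5, 80)
    )
  })
}

#' Generate a week-long synthetic food plan
#'
#' Builds one variant per weekday (plus optional event variants such as
#' `"train"`), each with four meals whose quantities are scaled so every
#' variant's total energy equals the target exactly: meal energy shares
#' are 25% breakfast, 35% lunch, 10% afternoon snack, 30% dinner, split
#' equally over the foods drawn for each meal.
#'
#' @param food_table Food-composition tibble (energies must be > 0).
#' @param targets A [plan_targets()] object.
#' @param seed Integer seed.
#' @param extra_variants Character vector of event variant keys to add
#'   (e.g. `c("train", "competition")`).
#' @param foods_per_meal Foods drawn per meal (default 2).
#' @return A [food_plan()] object whose targets carry the meal energy
#'   fractions used.
#' @export
generate_meal_plan <- function(food_table, targets, seed = 1,
                               extra_variants = character(),
                               foods_per_meal = 2) {
  stopifnot(all(food_table$energy_kcal > 0))
  meal_frac <- c(breakfast = 0.25, lunch = 0.35, afternoon_snack = 0.10,
                 dinner = 0.30)
  variants <- c(day_names, extra_variants)
  meals <- withr::with_seed(seed, {
    purrr::map(variants, function(v) {
      purrr::map(names(meal_frac), function(mt) {
        rows <- dplyr::slice_sample(food_table, n = foods_per_meal)
        item_energy <- meal_frac[[mt]] * targets$energy_kcal / foods_per_meal
        tibble::tibble(
          variant = v, meal_type = mt, food_id = rows$food_id,
          quantity_g = 100 * item_energy / rows$energy_kcal
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  targets$meal_energy_fractions <- meal_frac
  food_plan(
    plan_id = paste0("plan-seed", seed), person_id = "anon",
    meals = meals, targets = targets, food_table = food_table
  )
}

#' Simulate a week of intake, water and activity logging
#'
#' Emulates a user following a plan for seven days starting `start_date`
#' (each day follows its weekday's variant): every planned meal is logged
#' with probability `adherence` -- as a substitution of one random planned
#' item by a random other food (at the planned quantity) with probability
#' `substitution_p`, otherwise as a plain confirmation. Water arrives as
#' smart-bottle sips (count ~ Poisson(`sips_per_day`), volume uniform
#' 100-350 mL) and one smartwatch active-calorie record per day
#' (normal, truncated at 0).
#'
#' @param plan A [food_plan()] with weekday variants.
#' @param food_table Food-composition tibble.
#' @param start_date ISO date of day 1.
#' @param adherence Probability a planned meal is logged at all.
#' @param substitution_p Probability a logged meal carries a substitution.
#' @param sips_per_day Mean bottle sips per day.
#' @param activity_mean_kcal,activity_sd_kcal Daily active-calorie draw.
#' @param seed Integer seed.
#' @return Intake log tibble covering the seven days.
#' @export
generate_week <- function(plan, food_table, start_date = "2022-03-07",
                          adherence = 1, substitution_p = 0,
                          sips_per_day = 6, activity_mean_kcal = 350,
                          activity_sd_kcal = 100, seed = 1) {
  stopifnot(adherence >= 0, adherence <= 1,
            substitution_p >= 0, substitution_p <= 1)
  meal_hour <- c(breakfast = "08:00:00", morning_snack = "10:30:00",
                 lunch = "13:00:00", afternoon_snack = "16:30:00",
                 dinner = "20:00:00", supper = "22:30:00",
                 event = "18:00:00")
  withr::with_seed(seed, {
    log <- new_intake_log()
    for (d in 0:6) {
      date <- as.Date(start_date) + d
      key <- format(date, "%Y-%m-%d")
      variant <- day_names[as.integer(format(date, "%u"))]
      day_meals <- plan_variant_meals(plan, variant)
      for (mt in unique(day_meals$meal_type)) {
        ts <- paste0(key, "T", meal_hour[[mt]])
        if (stats::runif(1) > adherence) next
        if (stats::runif(1) < substitution_p) {
          items <- dplyr::filter(day_meals, .data$meal_type == mt)
          old <- dplyr::slice_sample(items, n = 1)
          candidates <- setdiff(food_table$food_id, old$food_id)
          log <- substitute_food(log, plan, variant, mt, old$food_id,
                                 sample(candidates, 1), old$quantity_g,
                                 food_table, ts)
        } else {
          log <- confirm_meal(log, plan, variant, mt, ts)
        }
      }
      n_sips <- stats::rpois(1, sips_per_day)
      if (n_sips > 0) {
        for (s in seq_len(n_sips)) {
          ts <- sprintf("%sT%02d:%02d:00", key, sample(7:22, 1),
                        sample(0:59, 1))
          log <- log_water(log, round(stats::runif(1, 100, 350)), ts,
                           source = "bottle")
        }
      }
      kcal <- max(0, stats::rnorm(1, activity_mean_kcal, activity_sd_kcal))
      log <- log_activity(log, kcal, paste0(key, "T21:00:00"))
    }
    log
  })
}

#' Simulate context-dependent food choices for preference learning
#'
#' Emulates a user with a planted favourite food per (meal type, day of
#' week) context: at each event a context is drawn uniformly, and the user
#' logs an extra food that is the context's favourite with probability
#' `favour_p`, otherwise a uniformly drawn other food. Used to test that
#' [update_preferences()] recovers the planted favourites.
#'
#' @param food_table Food-composition tibble.
#' @param planted Tibble with columns `meal_type`, `day_of_week`,
#'   `favourite_id`.
#' @param n_events Number of simulated choice events.
#' @param favour_p Probability the favourite is chosen (default 0.85).
#' @param seed Integer seed.
#' @return Intake log tibble of `extra_food` entries (with `meal_type` set,
#'   keyed to dates matching each context's weekday).
#' @export
generate_preference_log <- function(food_table, planted, n_events = 200,
                                    favour_p = 0.85, seed = 1) {
  stopifnot(all(c("meal_type", "day_of_week", "favourite_id") %in%
                  names(planted)))
  # a fixed Monday-anchored week, so each day_of_week maps to a real date
  week_dates <- format(as.Date("2022-03-07") + 0:6, "%Y-%m-%d")
  names(week_dates) <- day_names
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_events), function(i) {
      ctx <- planted[sample.int(nrow(planted), 1), ]
      pick_fav <- stats::runif(1) < favour_p
      fid <- if (pick_fav) {
        ctx$favourite_id
      } else {
        sample(setdiff(food_table$food_id, ctx$favourite_id), 1)
      }
      tibble::tibble(
        timestamp = sprintf("%sT%02d:%02d:%02d", week_dates[[ctx$day_of_week]],
                            sample(7:22, 1), sample(0:59, 1), i %% 60),
        key = week_dates[[ctx$day_of_week]], kind = "extra_food",
        meal_type = ctx$meal_type, food_id = fid,
        new_food_id = NA_character_, amount = 100, source = NA_character_
      )
    })
    dplyr::arrange(purrr::list_rbind(rows), .data$timestamp)
  })
}
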