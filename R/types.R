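#' Meal-type vocabulary
#'
#' Six daily meal slots plus `"event"` for logs tied to an occasion (sports
#' practice, competition) rather than a clock slot.
#' @return Character vector.
#' @export
meal_types <- function() {
  c("breakfast", "morning_snack", "lunch", "afternoon_snack", "dinner",
    "supper", "event")
}

#' Goal metrics a nutritionist may target in an appointment
#' @return Character vector of the seven tracked goal metrics.
#' @export
goal_metrics <- function() {
  c("weight", "body_fat", "visceral_fat", "fat_free_mass", "muscle_mass",
    "body_mass_index", "exercise_performance")
}

#' Construct a person record
#'
#' Only an opaque `id` identifies the person: names and contact details are
#' deliberately kept out of these records so plan and log data remain
#' useful while anonymous.
#'
#' @param id Opaque identifier (character).
#' @param sex `"male"` or `"female"`.
#' @param age_y Age in years (>= 0).
#' @param weight_kg Weight in kg (> 0).
#' @param height_m Height in metres (> 0).
#' @param fat_mass_kg Optional fat mass in kg (< weight).
#' @return A `person_record` object (named list).
#' @export
person_record <- function(id, sex, age_y, weight_kg, height_m,
                          fat_mass_kg = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  sex <- check_sex(sex)
  check_nonnegative(age_y, "age_y")
  check_positive(weight_kg, "weight_kg")
  check_positive(height_m, "height_m")
  if (!is.null(fat_mass_kg)) {
    check_nonnegative(fat_mass_kg, "fat_mass_kg")
    if (fat_mass_kg >= weight_kg) {
      rlang::abort("`fat_mass_kg` must be smaller than `weight_kg`")
    }
  }
  structure(
    list(id = id, sex = sex, age_y = age_y, weight_kg = weight_kg,
         height_m = height_m, fat_mass_kg = fat_mass_kg),
    class = "person_record"
  )
}

#' Construct an appointment record
#'
#' Captures what the nutritionist records in a consultation: the person's
#' metrics, measurable goals, lifestyle category (which drives PAL), and
#' free-text context relevant to plan making.
#'
#' @param person A [person_record()] object.
#' @param date Appointment date, ISO-8601 `"YYYY-MM-DD"`.
#' @param goals Named list/vector, names drawn from [goal_metrics()].
#' @param lifestyle One of `"sedentary_light"`, `"moderate"`, `"vigorous"`.
#' @param context Named list of free-text context (bowel function, sleep
#'   quality, wake/sleep times, race, food likes/dislikes, night shifts,
#'   job, clinical conditions, current water intake). Unconstrained keys.
#' @return An `appointment` object.
#' @export
appointment <- function(person, date, goals = list(),
                        lifestyle = "sedentary_light", context = list()) {
  stopifnot(inherits(person, "person_record"))
  date <- as.character(date)
  if (is.na(as.Date(date, format = "%Y-%m-%d"))) {
    rlang::abort("`date` must be an ISO-8601 date (YYYY-MM-DD)")
  }
  bad_goals <- setdiff(names(goals), goal_metrics())
  if (length(bad_goals) > 0) {
    rlang::abort(paste0("unknown goal metrics: ",
                        paste(bad_goals, collapse = ", ")))
  }
  if (!lifestyle %in% c("sedentary_light", "moderate", "vigorous")) {
    rlang::abort("`lifestyle` must be sedentary_light, moderate or vigorous")
  }
  structure(
    list(person = person, date = date, goals = as.list(goals),
         lifestyle = lifestyle, context = as.list(context)),
    class = "appointment"
  )
}

#' Construct plan targets
#'
#' The daily targets a food plan is validated against: total energy (the TEE
#' estimate), the macronutrient energy-share fractions
#' (`alpha` protein, `gamma` carbohydrate, `beta` lipid, summing to 1),
#' fiber, water and optional micronutrient targets, plus optional per-meal
#' energy fractions chosen by the nutritionist.
#'
#' @param energy_kcal Daily energy target (kcal, > 0), typically a TEE
#'   estimate.
#' @param alpha,gamma,beta Energy-share fractions for protein, carbs,
#'   lipids; each in `[0, 1]`, summing to 1 within 1e-9.
#' @param fiber_g Daily fiber target (g).
#' @param water_ml Daily base water target (mL).
#' @param micronutrients Named list of micronutrient targets
#'   (`iron_mg`, `calcium_mg`, `sodium_mg`, `magnesium_mg`), any subset.
#' @param meal_energy_fractions Optional named numeric: fraction of daily
#'   energy per meal type (names from [meal_types()]); enables per-meal
#'   energy validation.
#' @return A `plan_targets` object.
#' @export
plan_targets <- function(energy_kcal, alpha, gamma, beta,
                         fiber_g = 0, water_ml = 0,
                         micronutrients = list(),
                         meal_energy_fractions = NULL) {
  check_positive(energy_kcal, "energy_kcal")
  for (f in list(alpha = alpha, gamma = gamma, beta = beta)) {
    if (f < 0 || f > 1) rlang::abort("macronutrient fractions must lie in [0, 1]")
  }
  s <- alpha + gamma + beta
  if (abs(s - 1) > 1e-9) {
    rlang::abort(sprintf("alpha + gamma + beta must equal 1, got %.12g", s))
  }
  check_nonnegative(fiber_g, "fiber_g")
  check_nonnegative(water_ml, "water_ml")
  micro_allowed <- c("iron_mg", "calcium_mg", "sodium_mg", "magnesium_mg")
  bad <- setdiff(names(micronutrients), micro_allowed)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown micronutrient targets: ",
                        paste(bad, collapse = ", ")))
  }
  if (!is.null(meal_energy_fractions)) {
    bad_m <- setdiff(names(meal_energy_fractions), meal_types())
    if (length(bad_m) > 0) {
      rlang::abort(paste0("unknown meal types in meal_energy_fractions: ",
                          paste(bad_m, collapse = ", ")))
    }
  }
  structure(
    list(energy_kcal = energy_kcal, alpha = alpha, gamma = gamma, beta = beta,
         fiber_g = fiber_g, water_ml = water_ml,
         micronutrients = as.list(micronutrients),
         meal_energy_fractions = meal_energy_fractions),
    class = "plan_targets"
  )
}

#' Construct a hydration rule table
#'
#' Each rule adds `extra_ml` to the base water goal once the environment
#' temperature rises strictly above `threshold_c`; increments are cumulative
#' over crossed thresholds.
#'
#' @param threshold_c Numeric vector of temperature thresholds (deg C),
#'   strictly increasing.
#' @param extra_ml Numeric vector of extra water (mL, >= 0), same length.
#' @return Tibble with columns `threshold_c`, `extra_ml`.
#' @export
hydration_rules <- function(threshold_c = numeric(), extra_ml = numeric()) {
  stopifnot(length(threshold_c) == length(extra_ml))
  if (length(threshold_c) > 1 && any(diff(threshold_c) <= 0)) {
    rlang::abort("`threshold_c` must be strictly increasing")
  }
  check_nonnegative(extra_ml, "extra_ml")
  tibble::tibble(threshold_c = as.numeric(threshold_c),
                 extra_ml = as.numeric(extra_ml))
}

#' Construct a food plan
#'
#' A food plan holds one or more variants -- keyed by day of week
#' (`"monday"` ... `"sunday"`) or by event label (`"train"`,
#' `"competition"`) -- each a set of meals, where a meal is a list of
#' (food, quantity in g) items; plus the daily targets and hydration rules.
#'
#' @param plan_id,person_id Opaque identifiers.
#' @param meals Data frame with columns `variant`, `meal_type` (from
#'   [meal_types()]), `food_id`, `quantity_g` (> 0).
#' @param targets A [plan_targets()] object.
#' @param water_rules A [hydration_rules()] tibble.
#' @param food_table Optional food table; when given, every `food_id` in
#'   `meals` is checked to resolve against it.
#' @return A `food_plan` object.
#' @export
food_plan <- function(plan_id, person_id, meals, targets,
                      water_rules = hydration_rules(), food_table = NULL) {
  stopifnot(is.data.frame(meals), inherits(targets, "plan_targets"))
  req <- setdiff(c("variant", "meal_type", "food_id", "quantity_g"), names(meals))
  if (length(req) > 0) {
    rlang::abort(paste0("`meals` is missing columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(meals) == 0) rlang::abort("a food plan needs at least one variant with meals")
  if (any(meals$quantity_g <= 0)) rlang::abort("every `quantity_g` must be > 0")
  bad_mt <- setdiff(unique(meals$meal_type), meal_types())
  if (length(bad_mt) > 0) {
    rlang::abort(paste0("unknown meal types: ", paste(bad_mt, collapse = ", ")))
  }
  if (!is.null(food_table)) {
    unresolved <- setdiff(unique(meals$food_id), food_table$food_id)
    if (length(unresolved) > 0) {
      rlang::abort(paste0("food ids not in food table: ",
                          paste(unresolved, collapse = ", ")))
    }
  }
  structure(
    list(plan_id = plan_id, person_id = person_id,
         meals = tibble::as_tibble(meals), targets = targets,
         water_rules = tibble::as_tibble(water_rules)),
    class = "food_plan"
  )
}

#' @export
print.food_plan <- function(x, ...) {
  cat("<food_plan>", x$plan_id, "for person", x$person_id, "\n")
  cat("  variants:", paste(unique(x$meals$variant), collapse = ", "), "\n")
  cat(sprintf("  targets: %.0f kcal/day (alpha=%.2f gamma=%.2f beta=%.2f)\n",
              x$targets$energy_kcal, x$targets$alpha, x$targets$gamma,
              x$targets$beta))
  invisible(x)
}

plan_variant_meals <- function(plan, variant_key) {
  m <- dplyr::filter(plan$meals, .data$variant == variant_key)
  if (nrow(m) == 0) {
    rlang::abort(paste0("plan has no variant '", variant_key, "'"))
  }
  m
}
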