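#' Atwater energy-density factors
#'
#' Standard food-labelling energy densities: 4 kcal/g protein, 4 kcal/g
#' carbohydrate, 9 kcal/g lipid. Fiber and water carry 0 kcal here (soluble
#' fiber can be partially absorbed, but no accepted conversion exists, so it
#' is excluded from the energy ledger).
#'
#' @return Named numeric vector `c(protein = 4, carbs = 4, lipids = 9)`.
#' @export
atwater_factors <- function() c(protein = 4, carbs = 4, lipids = 9)

#' Split a daily energy target across macronutrients
#'
#' Implements the energy breakdown
#' \eqn{E = \alpha E + \gamma E + \beta E} where `alpha`, `gamma`, `beta`
#' are the energy-share fractions assigned to protein, carbohydrate and
#' lipid. Gram equivalents follow from the Atwater factors
#' (4/4/9 kcal per g).
#'
#' @param energy_kcal Daily energy target in kcal (> 0), typically TEE.
#' @param alpha,gamma,beta Fractions in `[0, 1]` summing to 1 (within 1e-9).
#' @return One-row tibble: `energy_protein`, `energy_carbs`, `energy_lipids`
#'   (kcal) and `grams_protein`, `grams_carbs`, `grams_lipids` (g).
#' @examples
#' macro_energy_split(2000, alpha = 0.3, gamma = 0.5, beta = 0.2)
#' @export
macro_energy_split <- function(energy_kcal, alpha, gamma, beta) {
  check_positive(energy_kcal, "energy_kcal")
  s <- alpha + gamma + beta
  if (abs(s - 1) > 1e-9) {
    rlang::abort(sprintf("alpha + gamma + beta must equal 1, got %.12g", s))
  }
  at <- atwater_factors()
  tibble::tibble(
    energy_protein = alpha * energy_kcal,
    energy_carbs = gamma * energy_kcal,
    energy_lipids = beta * energy_kcal,
    grams_protein = alpha * energy_kcal / at[["protein"]],
    grams_carbs = gamma * energy_kcal / at[["carbs"]],
    grams_lipids = beta * energy_kcal / at[["lipids"]]
  )
}

#' Grams per kilogram of body weight (and back)
#'
#' Macronutrient prescriptions are conventionally quoted in g per kg of
#' body weight; these helpers convert a daily total both ways.
#'
#' @param total_g Total grams per day.
#' @param weight_kg Body weight (kg, > 0).
#' @return `grams_per_kg()`: g/kg; `grams_from_per_kg()`: total g.
#' @export
grams_per_kg <- function(total_g, weight_kg) {
  check_positive(weight_kg, "weight_kg")
  total_g / weight_kg
}

#' @rdname grams_per_kg
#' @param g_per_kg Grams per kg of body weight.
#' @export
grams_from_per_kg <- function(g_per_kg, weight_kg) {
  check_positive(weight_kg, "weight_kg")
  g_per_kg * weight_kg
}

# Resolve the items of one variant against the food table and scale each
# per-100 g composition to its planned quantity.
resolve_items <- function(items, food_table) {
  unresolved <- setdiff(unique(items$food_id), food_table$food_id)
  if (length(unresolved) > 0) {
    rlang::abort(paste0("food ids not in food table: ",
                        paste(unresolved, collapse = ", ")))
  }
  items |>
    dplyr::inner_join(food_table, by = "food_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(nutrient_cols()),
                                ~ .x * .data$quantity_g / 100))
}

#' Nutrient totals of a plan variant
#'
#' Scales every planned item's per-100 g composition to its quantity and
#' sums, per meal or over the whole day. Exact bookkeeping: no rounding.
#'
#' @param plan A [food_plan()].
#' @param food_table Food-composition tibble (see [read_food_table()]).
#' @param variant_key Which variant (day of week or event label) to total.
#' @param by `"day"` (default) for the one-row day total, `"meal"` for one
#'   row per meal type.
#' @return Tibble of nutrient totals; with `by = "meal"` a `meal_type`
#'   column is prepended.
#' @export
plan_totals <- function(plan, food_table, variant_key, by = c("day", "meal")) {
  by <- match.arg(by)
  items <- resolve_items(plan_variant_meals(plan, variant_key), food_table)
  if (by == "day") return(nv_sum(items))
  items |>
    dplyr::group_by(.data$meal_type) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nutrient_cols()), sum),
                     .groups = "drop")
}

# Day-level targets as a nutrient-name -> amount table, derived from the
# plan's targets (macros in grams via the Atwater split).
targets_table <- function(targets) {
  split <- macro_energy_split(targets$energy_kcal, targets$alpha,
                              targets$gamma, targets$beta)
  base <- tibble::tibble(
    nutrient = c("energy_kcal", "protein_g", "carbs_g", "lipids_g",
                 "fiber_g", "water_ml"),
    target = c(targets$energy_kcal, split$grams_protein, split$grams_carbs,
               split$grams_lipids, targets$fiber_g, targets$water_ml)
  )
  if (length(targets$micronutrients) > 0) {
    base <- dplyr::bind_rows(base, tibble::tibble(
      nutrient = names(targets$micronutrients),
      target = unlist(targets$micronutrients, use.names = FALSE)
    ))
  }
  base
}

#' Validate a plan variant against its targets
#'
#' Compares the variant's day totals with the plan targets -- energy, the
#' three macronutrient gram targets implied by the energy split, fiber,
#' water and any micronutrient targets -- and, when the targets carry
#' per-meal energy fractions, each meal's energy with its share. A nutrient
#' is reported only when its relative error
#' \eqn{|actual - target| / \max(target, \epsilon)} exceeds `tolerance`;
#' an empty result means the plan meets its targets.
#'
#' @inheritParams plan_totals
#' @param tolerance Maximum accepted relative error (fraction, >= 0).
#' @return Tibble of deviations: `scope` (`"day"`/`"meal"`), `meal_type`
#'   (`NA` for day scope), `nutrient`, `target`, `actual`, `relative_error`.
#' @export
validate_plan <- function(plan, food_table, variant_key, tolerance = 0.05) {
  check_nonnegative(tolerance, "tolerance")
  day <- plan_totals(plan, food_table, variant_key, by = "day")
  day_long <- tidyr::pivot_longer(day, dplyr::everything(),
                                  names_to = "nutrient", values_to = "actual")
  dev <- targets_table(plan$targets) |>
    dplyr::inner_join(day_long, by = "nutrient") |>
    dplyr::mutate(scope = "day", meal_type = NA_character_,
                  relative_error = rel_err(.data$actual, .data$target))
  frac <- plan$targets$meal_energy_fractions
  if (!is.null(frac)) {
    meal_energy <- plan_totals(plan, food_table, variant_key, by = "meal") |>
      dplyr::select("meal_type", actual = "energy_kcal")
    meal_dev <- tibble::tibble(
      meal_type = names(frac),
      target = unname(frac) * plan$targets$energy_kcal
    ) |>
      dplyr::inner_join(meal_energy, by = "meal_type") |>
      dplyr::mutate(scope = "meal", nutrient = "energy_kcal",
                    relative_error = rel_err(.data$actual, .data$target))
    dev <- dplyr::bind_rows(dev, meal_dev)
  }
  dev |>
    dplyr::filter(.data$relative_error > tolerance) |>
    dplyr::select("scope", "meal_type", "nutrient", "target", "actual",
                  "relative_error")
}

#' Nutritionally equivalent substitution candidates
#'
#' For a reference food at a served quantity, finds the other foods of the
#' table that can stand in for it: each candidate's quantity is solved so
#' its energy matches the reference serving, then the candidate is kept only
#' if its protein, carbohydrate and lipid amounts at that quantity are each
#' within `tolerance` (relative) of the reference's. Candidates are ranked
#' by the summed relative macro error, ties broken by `food_id` -- so the
#' ranking is independent of food-table row order, and the reference food
#' itself always ranks first with error 0.
#'
#' @param food_table Food-composition tibble.
#' @param food_id Reference food id (must resolve in `food_table`).
#' @param quantity_g Served quantity of the reference food (g, > 0).
#' @param tolerance Maximum relative deviation per macronutrient (> 0).
#' @return Tibble ranked best-first: `food_id`, `name`, `quantity_g` (the
#'   energy-matched quantity), per-macro relative errors
#'   (`err_protein`, `err_carbs`, `err_lipids`), `macro_error` (their sum),
#'   and informational micronutrient deltas (`delta_iron_mg`, ...).
#' @export
equivalent_foods <- function(food_table, food_id, quantity_g, tolerance = 0.15) {
  check_positive(quantity_g, "quantity_g")
  check_positive(tolerance, "tolerance")
  ref <- dplyr::filter(food_table, .data$food_id == .env$food_id)
  if (nrow(ref) == 0) {
    rlang::abort(paste0("food id not in food table: ", food_id))
  }
  ref_s <- nv_scale(ref, quantity_g / 100)
  if (ref_s$energy_kcal <= 0) {
    rlang::abort("reference food has zero energy; cannot match on energy")
  }
  food_table |>
    dplyr::filter(.data$energy_kcal > 0) |>
    dplyr::mutate(quantity_g = 100 * ref_s$energy_kcal / .data$energy_kcal) |>
    dplyr::mutate(
      err_protein = rel_err(.data$protein_g * .data$quantity_g / 100, ref_s$protein_g),
      err_carbs = rel_err(.data$carbs_g * .data$quantity_g / 100, ref_s$carbs_g),
      err_lipids = rel_err(.data$lipids_g * .data$quantity_g / 100, ref_s$lipids_g),
      macro_error = .data$err_protein + .data$err_carbs + .data$err_lipids,
      delta_iron_mg = .data$iron_mg * .data$quantity_g / 100 - ref_s$iron_mg,
      delta_calcium_mg = .data$calcium_mg * .data$quantity_g / 100 - ref_s$calcium_mg,
      delta_sodium_mg = .data$sodium_mg * .data$quantity_g / 100 - ref_s$sodium_mg,
      delta_magnesium_mg = .data$magnesium_mg * .data$quantity_g / 100 - ref_s$magnesium_mg
    ) |>
    dplyr::filter(.data$err_protein <= tolerance, .data$err_carbs <= tolerance,
                  .data$err_lipids <= tolerance) |>
    dplyr::arrange(.data$macro_error, .data$food_id) |>
    dplyr::select("food_id", "name", "quantity_g", "err_protein", "err_carbs",
                  "err_lipids", "macro_error", dplyr::starts_with("delta_"))
}

#' Temperature-adjusted water goal
#'
#' Adds the extra volume of every hydration rule whose threshold is
#' strictly exceeded by the environment temperature; increments are
#' cumulative, so the goal is monotone non-decreasing in temperature and
#' equals the base at or below the first threshold.
#'
#' @param base_ml Base daily water goal (mL, >= 0).
#' @param temperature_c Environment temperature (deg C).
#' @param rules A [hydration_rules()] tibble.
#' @return Adjusted goal in mL.
#' @examples
#' adjust_water_goal(2000, 27, hydration_rules(c(25, 30), c(300, 500)))
#' @export
adjust_water_goal <- function(base_ml, temperature_c, rules = hydration_rules()) {
  check_nonnegative(base_ml, "base_ml")
  base_ml + sum(rules$extra_ml[rules$threshold_c < temperature_c])
}
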