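#' Read and write food-composition tables
#'
#' CSV with header `food_id,name,energy_kcal,protein_g,carbs_g,lipids_g,
#' fiber_g,water_ml,iron_mg,calcium_mg,sodium_mg,magnesium_mg`; amounts are
#' per 100 g of food. UTF-8, comma separator, `.` decimal.
#'
#' @param path CSV path.
#' @return `read_food_table()`: tibble with one row per food.
#' @export
read_food_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    food_id = readr::col_character(), name = readr::col_character(),
    .default = readr::col_double()
  ))
  missing_cols <- setdiff(c("food_id", "name", nutrient_cols()), names(out))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("food table is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(out$food_id)) {
    rlang::abort("duplicate food_id in food table")
  }
  if (any(out$energy_kcal < 0)) rlang::abort("negative energy in food table")
  out
}

#' @rdname read_food_table
#' @param food_table Food-composition tibble.
#' @export
write_food_table <- function(food_table, path) {
  readr::write_csv(food_table, path)
  invisible(path)
}

# Log CSV contract: timestamp,key,kind,ref,amount. `ref` packs the entry's
# references: meal_type for confirm/partial; food_id for extra food;
# "meal|old>new" for substitution; "meal|food" for removal; the device
# source for water/activity.
pack_ref <- function(log) {
  dplyr::case_when(
    log$kind %in% c("meal_confirm", "partial") ~ log$meal_type,
    log$kind == "extra_food" ~ log$food_id,
    log$kind == "substitution" ~ paste0(log$meal_type, "|", log$food_id, ">",
                                        log$new_food_id),
    log$kind == "food_removed" ~ paste0(log$meal_type, "|", log$food_id),
    log$kind %in% c("water", "activity_calories") ~ log$source,
    TRUE ~ NA_character_
  )
}

#' Read and write intake logs
#'
#' CSV with header `timestamp,key,kind,ref,amount`. `ref` holds the meal
#' type, food id, `meal|old>new` substitution reference or device source
#' depending on `kind`; `amount` holds the percentage, quantity (g),
#' volume (mL) or kcal as appropriate. Round-trips [new_intake_log()]
#' tibbles losslessly.
#'
#' @param path CSV path.
#' @return `read_intake_log()`: intake log tibble.
#' @export
read_intake_log <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(), key = readr::col_character(),
    kind = readr::col_character(), ref = readr::col_character(),
    amount = readr::col_double()
  ))
  raw |>
    dplyr::mutate(
      meal_type = dplyr::case_when(
        .data$kind %in% c("meal_confirm", "partial") ~ .data$ref,
        .data$kind %in% c("substitution", "food_removed") ~
          stringr::str_extract(.data$ref, "^[^|]+"),
        TRUE ~ NA_character_
      ),
      food_id = dplyr::case_when(
        .data$kind == "extra_food" ~ .data$ref,
        .data$kind == "substitution" ~
          stringr::str_match(.data$ref, "\\|([^>]+)>")[, 2],
        .data$kind == "food_removed" ~
          stringr::str_extract(.data$ref, "(?<=\\|).+$"),
        TRUE ~ NA_character_
      ),
      new_food_id = dplyr::if_else(
        .data$kind == "substitution",
        stringr::str_extract(.data$ref, "(?<=>).+$"), NA_character_),
      source = dplyr::if_else(
        .data$kind %in% c("water", "activity_calories"), .data$ref,
        NA_character_)
    ) |>
    dplyr::select("timestamp", "key", "kind", "meal_type", "food_id",
                  "new_food_id", "amount", "source")
}

#' @rdname read_intake_log
#' @param log Intake log tibble.
#' @export
write_intake_log <- function(log, path) {
  out <- tibble::tibble(
    timestamp = log$timestamp, key = log$key, kind = log$kind,
    ref = pack_ref(log), amount = log$amount
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and write food plans as JSON
#'
#' The JSON document carries `plan_id`, `person_id`, `targets` (including
#' the macronutrient fractions and optional per-meal energy fractions and
#' micronutrient targets), `meals` (records of variant, meal_type, food_id,
#' quantity_g) and `water_rules`.
#'
#' @param path JSON path.
#' @return `read_plan_json()`: a [food_plan()] object.
#' @export
read_plan_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  t <- j$targets
  mef <- t$meal_energy_fractions
  if (!is.null(mef)) mef <- unlist(mef)
  food_plan(
    plan_id = j$plan_id, person_id = j$person_id,
    meals = tibble::as_tibble(j$meals),
    targets = plan_targets(
      energy_kcal = t$energy_kcal, alpha = t$alpha, gamma = t$gamma,
      beta = t$beta, fiber_g = t$fiber_g %||% 0,
      water_ml = t$water_ml %||% 0,
      micronutrients = as.list(t$micronutrients %||% list()),
      meal_energy_fractions = mef
    ),
    water_rules = if (!is.null(j$water_rules) && length(j$water_rules) > 0) {
      hydration_rules(j$water_rules$threshold_c, j$water_rules$extra_ml)
    } else {
      hydration_rules()
    }
  )
}

#' @rdname read_plan_json
#' @param plan A [food_plan()] object.
#' @export
write_plan_json <- function(plan, path) {
  t <- plan$targets
  doc <- list(
    plan_id = plan$plan_id, person_id = plan$person_id,
    targets = list(
      energy_kcal = t$energy_kcal, alpha = t$alpha, gamma = t$gamma,
      beta = t$beta, fiber_g = t$fiber_g, water_ml = t$water_ml,
      micronutrients = t$micronutrients,
      meal_energy_fractions = as.list(t$meal_energy_fractions)
    ),
    meals = plan$meals,
    water_rules = plan$water_rules
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write appointments as JSON
#'
#' @param path JSON path.
#' @return `read_appointment_json()`: an [appointment()] object.
#' @export
read_appointment_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$person
  appointment(
    person = person_record(id = p$id, sex = p$sex, age_y = p$age_y,
                    weight_kg = p$weight_kg, height_m = p$height_m,
                    fat_mass_kg = p$fat_mass_kg),
    date = j$date, goals = as.list(j$goals %||% list()),
    lifestyle = j$lifestyle, context = as.list(j$context %||% list())
  )
}

#' @rdname read_appointment_json
#' @param appt An [appointment()] object.
#' @export
write_appointment_json <- function(appt, path) {
  jsonlite::write_json(unclass_deep(appt), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
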