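#' Create an empty intake log
#'
#' The intake log is a tibble with one row per event. Every entry carries a
#' timestamp and a `key` -- the local calendar date of the timestamp, or an
#' event label (e.g. `"train"`) that overrides the date, since all logs
#' attach either to a specific day or to an event.
#'
#' Entry kinds: `meal_confirm`, `partial`, `substitution`, `food_removed`,
#' `extra_food`, `water`, `activity_calories`.
#'
#' @return Empty log tibble with columns `timestamp`, `key`, `kind`,
#'   `meal_type`, `food_id`, `new_food_id`, `amount`, `source`.
#' @export
new_intake_log <- function() {
  tibble::tibble(
    timestamp = character(), key = character(), kind = character(),
    meal_type = character(), food_id = character(),
    new_food_id = character(), amount = numeric(), source = character()
  )
}

log_key <- function(timestamp, key = NULL) {
  if (!is.null(key)) return(as.character(key))
  d <- substr(as.character(timestamp), 1, 10)
  if (is.na(as.Date(d, format = "%Y-%m-%d"))) {
    rlang::abort("`timestamp` must start with an ISO date (YYYY-MM-DD...) or `key` must be given")
  }
  d
}

append_entry <- function(log, ..., timestamp, key) {
  dplyr::bind_rows(log, tibble::tibble(
    timestamp = as.character(timestamp), key = key, ...
  ))
}

# one meal-level consumption event (confirm or partial) per (key, meal_type)
check_meal_conflict <- function(log, key, meal_type) {
  clash <- log |>
    dplyr::filter(.data$key == .env$key, .data$meal_type == .env$meal_type,
                  .data$kind %in% c("meal_confirm", "partial"))
  if (nrow(clash) > 0) {
    rlang::abort(paste0("meal '", meal_type, "' already logged for '", key,
                        "' (", clash$kind[1], ")"))
  }
}

check_meal_exists <- function(plan, variant_key, meal_type) {
  m <- plan_variant_meals(plan, variant_key)
  if (!meal_type %in% m$meal_type) {
    rlang::abort(paste0("variant '", variant_key, "' has no meal '",
                        meal_type, "'"))
  }
}

#' Confirm a planned meal as eaten
#'
#' Records that the meal was eaten exactly as planned. Re-confirming the
#' same meal on the same day (or logging a percentage for it as well) is a
#' conflict.
#'
#' @param log Intake log tibble.
#' @param plan A [food_plan()].
#' @param variant_key Plan variant the day follows.
#' @param meal_type Which meal (must exist in the variant).
#' @param timestamp ISO-8601 timestamp string.
#' @param key Optional day/event key; defaults to the timestamp's date.
#' @return Updated log.
#' @export
confirm_meal <- function(log, plan, variant_key, meal_type, timestamp,
                         key = NULL) {
  check_meal_exists(plan, variant_key, meal_type)
  key <- log_key(timestamp, key)
  check_meal_conflict(log, key, meal_type)
  append_entry(log, kind = "meal_confirm", meal_type = meal_type,
               timestamp = timestamp, key = key)
}

#' Log a partial meal intake
#'
#' Records that `percentage` of the planned meal was eaten; the fraction
#' applies uniformly to every item of the meal (the interface logs a single
#' percentage per meal).
#'
#' @inheritParams confirm_meal
#' @param percentage In `(0, 100]`; 100 is equivalent to [confirm_meal()].
#' @return Updated log.
#' @export
log_partial <- function(log, plan, variant_key, meal_type, percentage,
                        timestamp, key = NULL) {
  if (!is.numeric(percentage) || length(percentage) != 1 ||
      is.na(percentage) || percentage <= 0 || percentage > 100) {
    rlang::abort("`percentage` must lie in (0, 100]")
  }
  check_meal_exists(plan, variant_key, meal_type)
  key <- log_key(timestamp, key)
  check_meal_conflict(log, key, meal_type)
  append_entry(log, kind = "partial", meal_type = meal_type,
               amount = percentage, timestamp = timestamp, key = key)
}

#' Log food eaten outside the plan
#'
#' @inheritParams confirm_meal
#' @param food_table Food-composition tibble (the food must resolve).
#' @param food_id Food eaten.
#' @param quantity_g Quantity in g (> 0).
#' @return Updated log.
#' @export
log_extra_food <- function(log, food_table, food_id, quantity_g, timestamp,
                           key = NULL) {
  if (!food_id %in% food_table$food_id) {
    rlang::abort(paste0("food id not in food table: ", food_id))
  }
  check_positive(quantity_g, "quantity_g")
  append_entry(log, kind = "extra_food", food_id = food_id,
               amount = quantity_g, timestamp = timestamp,
               key = log_key(timestamp, key))
}

#' Substitute one food of a planned meal
#'
#' Records the meal as consumed with `old_food_id` replaced by
#' `quantity_g` of `new_food_id`; the substitution event is also the signal
#' the preference model learns from (away from the old food, towards the
#' new). Several substitutions/removals may stack on the same meal.
#'
#' @inheritParams log_extra_food
#' @param old_food_id Planned food being replaced (must be in the meal).
#' @param new_food_id Replacement food (must resolve in `food_table`).
#' @param quantity_g Quantity of the replacement (g, > 0).
#' @return Updated log.
#' @export
substitute_food <- function(log, plan, variant_key, meal_type, old_food_id,
                            new_food_id, quantity_g, food_table, timestamp,
                            key = NULL) {
  check_meal_exists(plan, variant_key, meal_type)
  m <- plan_variant_meals(plan, variant_key) |>
    dplyr::filter(.data$meal_type == .env$meal_type)
  if (!old_food_id %in% m$food_id) {
    rlang::abort(paste0("food '", old_food_id, "' is not in the planned meal '",
                        meal_type, "'"))
  }
  if (!new_food_id %in% food_table$food_id) {
    rlang::abort(paste0("food id not in food table: ", new_food_id))
  }
  check_positive(quantity_g, "quantity_g")
  append_entry(log, kind = "substitution", meal_type = meal_type,
               food_id = old_food_id, new_food_id = new_food_id,
               amount = quantity_g, timestamp = timestamp,
               key = log_key(timestamp, key))
}

#' Remove a food from a planned meal's consumption
#'
#' Planned-minus-item semantics: the meal counts as consumed without this
#' item.
#'
#' @inheritParams substitute_food
#' @param food_id Planned food that was not eaten.
#' @return Updated log.
#' @export
remove_food <- function(log, plan, variant_key, meal_type, food_id, timestamp,
                        key = NULL) {
  check_meal_exists(plan, variant_key, meal_type)
  m <- plan_variant_meals(plan, variant_key) |>
    dplyr::filter(.data$meal_type == .env$meal_type)
  if (!food_id %in% m$food_id) {
    rlang::abort(paste0("food '", food_id, "' is not in the planned meal '",
                        meal_type, "'"))
  }
  append_entry(log, kind = "food_removed", meal_type = meal_type,
               food_id = food_id, timestamp = timestamp,
               key = log_key(timestamp, key))
}

#' Log water intake
#'
#' @inheritParams confirm_meal
#' @param volume_ml Volume in mL (> 0).
#' @param source `"manual"` (phone/watch entry) or `"bottle"` (smart-bottle
#'   export); accounting is source-agnostic, the source is kept for audit.
#' @return Updated log.
#' @export
log_water <- function(log, volume_ml, timestamp, key = NULL,
                      source = c("manual", "bottle")) {
  source <- match.arg(source)
  check_positive(volume_ml, "volume_ml")
  append_entry(log, kind = "water", amount = volume_ml, source = source,
               timestamp = timestamp, key = log_key(timestamp, key))
}

#' Log activity calories
#'
#' Smartwatch-style active-calorie record; feeds the PEE term of the
#' caloric balance.
#'
#' @inheritParams confirm_meal
#' @param kcal Active calories (>= 0).
#' @param source Free-text device label.
#' @return Updated log.
#' @export
log_activity <- function(log, kcal, timestamp, key = NULL, source = "watch") {
  check_nonnegative(kcal, "kcal")
  append_entry(log, kind = "activity_calories", amount = kcal, source = source,
               timestamp = timestamp, key = log_key(timestamp, key))
}

#' Ingest a device export CSV
#'
#' Reads a two-column `timestamp,value` CSV as exported (via gateway) by a
#' smart bottle (`kind = "water"`, values in mL) or a smartwatch
#' (`kind = "activity"`, values in kcal). Malformed rows are rejected with
#' their line number but never abort the batch; duplicate timestamps --
#' within the file or against already-ingested rows of the same kind -- are
#' skipped first-wins, so re-ingesting an overlapping export is idempotent.
#'
#' @param log Intake log tibble.
#' @param path CSV path with header `timestamp,value`.
#' @param kind `"water"` or `"activity"`.
#' @return List with `log` (updated) and `report` (tibble: `line`,
#'   `timestamp`, `status` in accepted/rejected/duplicate, `reason`).
#' @export
ingest_device_csv <- function(log, path, kind = c("water", "activity")) {
  kind <- match.arg(kind)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("timestamp", "value") %in% names(raw))) {
    rlang::abort("device CSV must have header `timestamp,value`")
  }
  entry_kind <- if (kind == "water") "water" else "activity_calories"
  source <- if (kind == "water") "bottle" else "watch"
  seen <- log$timestamp[log$kind == entry_kind]
  report <- list()
  for (i in seq_len(nrow(raw))) {
    ts <- raw$timestamp[i]
    val <- suppressWarnings(as.numeric(raw$value[i]))
    line <- i + 1L  # header is line 1
    if (is.na(ts) || is.na(as.Date(substr(ts, 1, 10), format = "%Y-%m-%d"))) {
      report[[i]] <- tibble::tibble(line = line, timestamp = ts %||% NA_character_,
                                    status = "rejected", reason = "bad timestamp")
      next
    }
    if (is.na(val) || (kind == "water" && val <= 0) || val < 0) {
      report[[i]] <- tibble::tibble(line = line, timestamp = ts,
                                    status = "rejected", reason = "bad value")
      next
    }
    if (ts %in% seen) {
      report[[i]] <- tibble::tibble(line = line, timestamp = ts,
                                    status = "duplicate", reason = "timestamp already ingested")
      next
    }
    seen <- c(seen, ts)
    log <- append_entry(log, kind = entry_kind, amount = val, source = source,
                        timestamp = ts, key = log_key(ts))
    report[[i]] <- tibble::tibble(line = line, timestamp = ts,
                                  status = "accepted", reason = NA_character_)
  }
  report <- if (length(report) == 0) {
    tibble::tibble(line = integer(), timestamp = character(),
                   status = character(), reason = character())
  } else {
    dplyr::bind_rows(report)
  }
  list(log = log, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consumed nutrient vector of one day/event key, replaying the entries.
# Pure function of the entry multiset: grouping by meal makes the result
# order-independent.
consumed_for_key <- function(log, plan, food_table, variant_key, key) {
  entries <- dplyr::filter(log, .data$key == .env$key)
  total <- nv_zero()
  meal_entries <- dplyr::filter(entries, .data$kind %in%
    c("meal_confirm", "partial", "substitution", "food_removed"))
  for (mt in unique(meal_entries$meal_type)) {
    me <- dplyr::filter(meal_entries, .data$meal_type == mt)
    planned <- plan_variant_meals(plan, variant_key) |>
      dplyr::filter(.data$meal_type == mt) |>
      dplyr::select("food_id", "quantity_g")
    # apply removals, then substitutions (replace old item with new@qty)
    removed <- me$food_id[me$kind == "food_removed"]
    planned <- dplyr::filter(planned, !.data$food_id %in% removed)
    subs <- dplyr::filter(me, .data$kind == "substitution")
    for (j in seq_len(nrow(subs))) {
      planned <- planned |>
        dplyr::filter(.data$food_id != subs$food_id[j]) |>
        dplyr::bind_rows(tibble::tibble(food_id = subs$new_food_id[j],
                                        quantity_g = subs$amount[j]))
    }
    frac <- if (any(me$kind == "partial")) me$amount[me$kind == "partial"][1] / 100 else 1
    meal_vec <- nv_scale(resolve_items(planned, food_table), frac)
    total <- nv_add(total, meal_vec)
  }
  extras <- dplyr::filter(entries, .data$kind == "extra_food")
  if (nrow(extras) > 0) {
    extra_vec <- resolve_items(
      dplyr::select(extras, "food_id", quantity_g = "amount"), food_table)
    total <- nv_add(total, extra_vec)
  }
  total
}

#' Daily statistics versus plan targets
#'
#' Aggregates all log entries of one day (or event) into consumed nutrient
#' totals, water and logged activity calories, paired with the plan's
#' target values -- the numbers a daily-statistics screen monitors. The
#' water target passes through [adjust_water_goal()] when a temperature
#' reading is supplied; the logged activity calories are the observed PEE
#' for [caloric_balance()].
#'
#' @inheritParams confirm_meal
#' @param food_table Food-composition tibble.
#' @param key Day (ISO date) or event key to aggregate.
#' @param temperature_c Optional temperature reading for the water goal.
#' @return A `daily_stats` object: list with `key`, `nutrients` (tibble
#'   `nutrient`, `consumed`, `target`, `fraction_of_target` -- `NA` where
#'   the target is 0), `water_consumed_ml`, `water_target_ml`,
#'   `pee_logged_kcal`.
#' @export
daily_stats <- function(log, plan, food_table, variant_key, key,
                        temperature_c = NULL) {
  consumed <- consumed_for_key(log, plan, food_table, variant_key, key)
  entries <- dplyr::filter(log, .data$key == .env$key)
  water <- sum(entries$amount[entries$kind == "water"])
  pee <- sum(entries$amount[entries$kind == "activity_calories"])
  water_target <- plan$targets$water_ml
  if (!is.null(temperature_c)) {
    water_target <- adjust_water_goal(water_target, temperature_c,
                                      plan$water_rules)
  }
  nut <- targets_table(plan$targets) |>
    dplyr::left_join(
      tidyr::pivot_longer(consumed, dplyr::everything(),
                          names_to = "nutrient", values_to = "consumed"),
      by = "nutrient"
    ) |>
    dplyr::mutate(
      consumed = dplyr::coalesce(.data$consumed, 0),
      fraction_of_target = dplyr::if_else(.data$target > 0,
                                          .data$consumed / .data$target,
                                          NA_real_)
    ) |>
    dplyr::select("nutrient", "consumed", "target", "fraction_of_target")
  structure(
    list(key = key, nutrients = nut, consumed = consumed,
         water_consumed_ml = water, water_target_ml = water_target,
         pee_logged_kcal = pee),
    class = "daily_stats"
  )
}

#' @export
print.daily_stats <- function(x, ...) {
  cat("<daily_stats>", x$key, "\n")
  print(x$nutrients)
  cat(sprintf("water: %.0f / %.0f mL; logged activity: %.0f kcal\n",
              x$water_consumed_ml, x$water_target_ml, x$pee_logged_kcal))
  invisible(x)
}

#' Tidy a daily_stats object
#'
#' @param x A `daily_stats` object.
#' @param ... Unused.
#' @return Long tibble with one row per tracked quantity (the ten nutrient
#'   rows plus water), columns `key`, `metric`, `consumed`, `target`,
#'   `fraction_of_target`.
#' @method tidy daily_stats
#' @export
tidy.daily_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$nutrients, metric = .data$nutrient, .keep = "unused"),
    tibble::tibble(
      metric = "water_ml_logged", consumed = x$water_consumed_ml,
      target = x$water_target_ml,
      fraction_of_target = if (x$water_target_ml > 0)
        x$water_consumed_ml / x$water_target_ml else NA_real_
    )
  ) |>
    dplyr::mutate(key = x$key, .before = 1)
}

#' One-row summary of a daily_stats object
#'
#' @inheritParams tidy.daily_stats
#' @return One-row tibble: `key`, `energy_consumed_kcal`,
#'   `energy_target_kcal`, `pee_logged_kcal`, `water_consumed_ml`,
#'   `water_target_ml`, `n_nutrients_on_target` (relative error within 5%).
#' @method glance daily_stats
#' @export
glance.daily_stats <- function(x, ...) {
  e <- dplyr::filter(x$nutrients, .data$nutrient == "energy_kcal")
  on_target <- sum(rel_err(x$nutrients$consumed, x$nutrients$target) <= 0.05)
  tibble::tibble(
    key = x$key,
    energy_consumed_kcal = e$consumed, energy_target_kcal = e$target,
    pee_logged_kcal = x$pee_logged_kcal,
    water_consumed_ml = x$water_consumed_ml,
    water_target_ml = x$water_target_ml,
    n_nutrients_on_target = on_target
  )
}

#' Plot daily consumption against targets
#'
#' Bar chart of fraction-of-target per tracked nutrient (and water), with
#' the 100% line marked.
#'
#' @param object A `daily_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot daily_stats
#' @export
autoplot.daily_stats <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(!is.na(.data$fraction_of_target))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric,
                                  y = .data$fraction_of_target)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of daily target",
                  title = paste("Daily intake vs targets:", object$key))
}
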