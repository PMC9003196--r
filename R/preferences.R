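#' Create an empty food-preference model
#'
#' A deterministic exponential-decay acceptance model: each (food, context)
#' pair carries a score in `[0, 1]` starting at `prior`; every observed
#' acceptance (meal confirmation, extra food, substitution towards the
#' food) moves the score towards 1, every rejection (substitution away)
#' towards 0, by `score <- score * decay + (1 - decay) * reward`. The
#' context is (meal type, day of week), so the same food can be loved at
#' breakfast and shunned at dinner.
#'
#' @param decay Per-event retention factor in `(0, 1]`; smaller adapts
#'   faster. Default 0.8.
#' @param prior Score assigned to foods never observed in a context;
#'   default 0.5 (indifference).
#' @return A `preference_model` object.
#' @export
preference_model <- function(decay = 0.8, prior = 0.5) {
  if (decay <= 0 || decay > 1) rlang::abort("`decay` must lie in (0, 1]")
  if (prior < 0 || prior > 1) rlang::abort("`prior` must lie in [0, 1]")
  structure(
    list(
      scores = tibble::tibble(food_id = character(), meal_type = character(),
                              day_of_week = character(), score = numeric()),
      decay = decay, prior = prior
    ),
    class = "preference_model"
  )
}

day_names <- c("monday", "tuesday", "wednesday", "thursday", "friday",
               "saturday", "sunday")

# locale-independent weekday of an ISO date key; event keys pass through
key_day_of_week <- function(key) {
  d <- as.Date(key, format = "%Y-%m-%d")
  ifelse(is.na(d), key, day_names[as.integer(format(d, "%u"))])
}

resolve_variant <- function(plan, key) {
  variants <- unique(plan$meals$variant)
  if (key %in% variants) return(key)
  dow <- key_day_of_week(key)
  if (dow %in% variants) return(dow)
  NULL
}

pref_update_one <- function(model, food_id, meal_type, day_of_week, reward) {
  s <- model$scores
  idx <- which(s$food_id == food_id & s$meal_type == meal_type &
                 s$day_of_week == day_of_week)
  old <- if (length(idx) == 0) model$prior else s$score[idx]
  new <- old * model$decay + (1 - model$decay) * reward
  if (length(idx) == 0) {
    model$scores <- dplyr::bind_rows(s, tibble::tibble(
      food_id = food_id, meal_type = meal_type, day_of_week = day_of_week,
      score = new))
  } else {
    model$scores$score[idx] <- new
  }
  model
}

#' Update a preference model from an intake log
#'
#' Replays the log in timestamp order. Meal confirmations reward every food
#' of the planned meal (requires `plan` to resolve the foods; the variant
#' is taken from the entry key -- an event key matching a plan variant, or
#' the key's weekday). Extra-food entries reward the logged food.
#' Substitutions penalise the outgoing food (reward 0) and reward the
#' incoming one. Entries whose context cannot be resolved are skipped.
#'
#' @param model A [preference_model()].
#' @param log Intake log tibble.
#' @param plan Optional [food_plan()], needed to expand meal confirmations
#'   into their foods.
#' @return Updated `preference_model`.
#' @export
update_preferences <- function(model, log, plan = NULL) {
  stopifnot(inherits(model, "preference_model"))
  log <- dplyr::arrange(log, .data$timestamp)
  for (i in seq_len(nrow(log))) {
    e <- log[i, ]
    dow <- key_day_of_week(e$key)
    if (e$kind == "extra_food") {
      mt <- if (is.na(e$meal_type)) "unspecified" else e$meal_type
      model <- pref_update_one(model, e$food_id, mt, dow, 1)
    } else if (e$kind == "substitution") {
      model <- pref_update_one(model, e$food_id, e$meal_type, dow, 0)
      model <- pref_update_one(model, e$new_food_id, e$meal_type, dow, 1)
    } else if (e$kind == "meal_confirm" && !is.null(plan)) {
      variant <- resolve_variant(plan, e$key)
      if (is.null(variant)) next
      foods <- plan_variant_meals(plan, variant) |>
        dplyr::filter(.data$meal_type == e$meal_type) |>
        dplyr::pull("food_id")
      for (f in foods) model <- pref_update_one(model, f, e$meal_type, dow, 1)
    }
  }
  model
}

#' Look up preference scores
#'
#' @param model A [preference_model()].
#' @param food_id Character vector of foods.
#' @param meal_type,day_of_week Context; scalars recycled over `food_id`.
#' @return Numeric scores (the prior for unseen combinations).
#' @export
preference_score <- function(model, food_id, meal_type, day_of_week) {
  q <- tibble::tibble(food_id = food_id, meal_type = meal_type,
                      day_of_week = day_of_week)
  q |>
    dplyr::left_join(model$scores,
                     by = c("food_id", "meal_type", "day_of_week")) |>
    dplyr::pull("score") |>
    dplyr::coalesce(model$prior)
}

#' Recommend substitution candidates ranked by preference
#'
#' Takes the nutrient-equivalence candidate set from [equivalent_foods()]
#' and re-ranks it by learned preference: score descending, then macro
#' error ascending, then `food_id` -- so preference dominates inside the
#' equivalence set, and with all scores equal the ordering degenerates to
#' the plain equivalence ranking.
#'
#' @inheritParams equivalent_foods
#' @param model A [preference_model()].
#' @param meal_type,day_of_week Context of the recommendation.
#' @return The [equivalent_foods()] tibble with a `score` column, re-ranked.
#' @export
recommend <- function(model, food_table, food_id, quantity_g,
                      tolerance = 0.15, meal_type = "lunch",
                      day_of_week = "monday") {
  equivalent_foods(food_table, food_id, quantity_g, tolerance) |>
    dplyr::mutate(score = preference_score(model, .data$food_id, meal_type,
                                           day_of_week)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$macro_error, .data$food_id)
}

#' @export
print.preference_model <- function(x, ...) {
  cat(sprintf("<preference_model> decay=%.2f prior=%.2f, %d scored (food, context) pairs\n",
              x$decay, x$prior, nrow(x$scores)))
  invisible(x)
}

#' Tidy a preference model
#'
#' @param x A `preference_model`.
#' @param ... Unused.
#' @return Tibble of scores: `food_id`, `meal_type`, `day_of_week`, `score`.
#' @method tidy preference_model
#' @export
tidy.preference_model <- function(x, ...) x$scores

#' One-row summary of a preference model
#'
#' @inheritParams tidy.preference_model
#' @return Tibble: `n_pairs`, `n_foods`, `n_contexts`, `decay`, `prior`,
#'   `mean_score`.
#' @method glance preference_model
#' @export
glance.preference_model <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$scores),
    n_foods = dplyr::n_distinct(x$scores$food_id),
    n_contexts = nrow(dplyr::distinct(x$scores, .data$meal_type,
                                      .data$day_of_week)),
    decay = x$decay, prior = x$prior,
    mean_score = if (nrow(x$scores) > 0) mean(x$scores$score) else NA_real_
  )
}

#' Plot a preference model
#'
#' Heatmap of scores by food and context.
#'
#' @param object A `preference_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot preference_model
#' @export
autoplot.preference_model <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(context = paste(.data$day_of_week, .data$meal_type))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$food_id,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", midpoint = object$prior,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score",
                  title = "Learned food preferences by context") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
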