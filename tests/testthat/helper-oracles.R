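# Independent brute-force oracles: plain loops, no shared code with the
# implementation paths they check.

oracle_plan_totals <- function(meals, food_table) {
  acc <- stats::setNames(numeric(length(nutrient_cols())), nutrient_cols())
  for (i in seq_len(nrow(meals))) {
    row <- food_table[food_table$food_id == meals$food_id[i], ]
    for (col in nutrient_cols()) {
      acc[col] <- acc[col] + row[[col]] * meals$quantity_g[i] / 100
    }
  }
  acc
}

oracle_pal <- function(activities) {
  total <- 0
  for (i in seq_len(nrow(activities))) {
    total <- total + activities$hours[i] * activities$par[i]
  }
  total / 24
}

# exhaustive filter over every candidate food, returning ids in rank order
oracle_equivalent <- function(food_table, ref_id, quantity_g, tolerance) {
  ref <- food_table[food_table$food_id == ref_id, ]
  serving <- quantity_g / 100
  ref_e <- ref$energy_kcal * serving
  keep <- list()
  for (i in seq_len(nrow(food_table))) {
    cand <- food_table[i, ]
    if (cand$energy_kcal <= 0) next
    q <- 100 * ref_e / cand$energy_kcal
    errs <- numeric(3)
    macros <- c("protein_g", "carbs_g", "lipids_g")
    ok <- TRUE
    for (m in seq_along(macros)) {
      target <- ref[[macros[m]]] * serving
      actual <- cand[[macros[m]]] * q / 100
      errs[m] <- abs(actual - target) / max(target, 1e-9)
      if (errs[m] > tolerance) ok <- FALSE
    }
    if (ok) {
      keep[[length(keep) + 1]] <- data.frame(
        food_id = cand$food_id, quantity_g = q, macro_error = sum(errs)
      )
    }
  }
  if (length(keep) == 0) {
    return(data.frame(food_id = character(), quantity_g = numeric(),
                      macro_error = numeric()))
  }
  out <- do.call(rbind, keep)
  out[order(out$macro_error, out$food_id), , drop = FALSE]
}
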