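#' Nutrient column names
#'
#' The ten accounting columns every nutrient vector carries: energy plus the
#' three caloric macronutrients, fiber, water, and the four control
#' micronutrients (iron, calcium, sodium, magnesium) routinely tracked across
#' population groups.
#'
#' @return Character vector of column names, in canonical order.
#' @export
nutrient_cols <- function() {
  c(
    "energy_kcal", "protein_g", "carbs_g", "lipids_g", "fiber_g",
    "water_ml", "iron_mg", "calcium_mg", "sodium_mg", "magnesium_mg"
  )
}

#' Construct a nutrient vector
#'
#' A nutrient vector is a one-row tibble with the ten [nutrient_cols()]
#' columns. It is the universal accounting currency of the package: food
#' compositions (per 100 g), meal totals, day totals, plan targets and
#' consumed amounts are all nutrient vectors, so plan validation and daily
#' statistics reduce to exact component-wise bookkeeping.
#'
#' @param energy_kcal Energy (kcal).
#' @param protein_g,carbs_g,lipids_g Macronutrients (g).
#' @param fiber_g Fiber (g).
#' @param water_ml Water (mL).
#' @param iron_mg,calcium_mg,sodium_mg,magnesium_mg Micronutrients (mg).
#'
#' @return One-row tibble with the [nutrient_cols()] columns.
#' @examples
#' nv(energy_kcal = 250, protein_g = 10, carbs_g = 30, lipids_g = 8)
#' @export
nv <- function(energy_kcal = 0, protein_g = 0, carbs_g = 0, lipids_g = 0,
               fiber_g = 0, water_ml = 0, iron_mg = 0, calcium_mg = 0,
               sodium_mg = 0, magnesium_mg = 0) {
  out <- tibble::tibble(
    energy_kcal = as.numeric(energy_kcal),
    protein_g = as.numeric(protein_g),
    carbs_g = as.numeric(carbs_g),
    lipids_g = as.numeric(lipids_g),
    fiber_g = as.numeric(fiber_g),
    water_ml = as.numeric(water_ml),
    iron_mg = as.numeric(iron_mg),
    calcium_mg = as.numeric(calcium_mg),
    sodium_mg = as.numeric(sodium_mg),
    magnesium_mg = as.numeric(magnesium_mg)
  )
  bad <- names(out)[vapply(out, function(x) any(x < 0), logical(1))]
  if (length(bad) > 0) {
    rlang::abort(paste0("nutrient amounts must be >= 0; negative: ",
                        paste(bad, collapse = ", ")))
  }
  out
}

#' Zero nutrient vector
#' @return One-row tibble of zeros over [nutrient_cols()].
#' @export
nv_zero <- function() nv()

as_nv <- function(x) {
  # accept any data frame carrying the nutrient columns; rows are summed
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(nutrient_cols(), names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing nutrient columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(nv_zero())
  tibble::as_tibble(lapply(x[nutrient_cols()], function(col) sum(as.numeric(col))))
}

#' Add nutrient vectors
#'
#' Component-wise sum. Both arguments may have multiple rows; rows are
#' collapsed by summation first, so `nv_add(meal_items, nv_zero())` also acts
#' as a column-wise total.
#'
#' @param a,b Data frames carrying the [nutrient_cols()] columns.
#' @return One-row nutrient vector.
#' @export
nv_add <- function(a, b) {
  a <- as_nv(a)
  b <- as_nv(b)
  tibble::as_tibble(Map(`+`, a, b))
}

#' Scale a nutrient vector
#'
#' Component-wise product with a non-negative scalar. The canonical use is
#' converting a per-100 g composition to a served quantity:
#' `nv_scale(comp, quantity_g / 100)`.
#'
#' @param v Data frame carrying the [nutrient_cols()] columns.
#' @param factor Non-negative dimensionless scalar.
#' @return One-row nutrient vector.
#' @export
nv_scale <- function(v, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor < 0) {
    rlang::abort("`factor` must be a single non-negative number")
  }
  v <- as_nv(v)
  tibble::as_tibble(lapply(v, function(x) x * factor))
}

#' Sum nutrient columns of a data frame
#'
#' @param x Data frame with [nutrient_cols()] columns (zero or more rows).
#' @return One-row nutrient vector equal to the column sums.
#' @export
nv_sum <- function(x) as_nv(x)
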