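#' Body mass index
#'
#' @param weight_kg Body weight in kg.
#' @param height_m Height in **metres** (BMI's native unit; the BMR equations
#'   below take height in **centimetres** — see [cm_to_m()] / [m_to_cm()]).
#' @return BMI in kg/m^2.
#' @examples
#' bmi(70, 1.75)
#' @export
bmi <- function(weight_kg, height_m) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_m, "height_m")
  weight_kg / height_m^2
}

#' @rdname unit_helpers
#' @title Height unit converters
#' @description BMI takes height in metres; the BMR equations take height in
#'   centimetres. These converters make the unit change explicit at call
#'   sites so the two conventions are never mixed silently.
#' @param x Height value.
#' @return Converted height.
#' @export
m_to_cm <- function(x) x * 100

#' @rdname unit_helpers
#' @export
cm_to_m <- function(x) x / 100

# Coefficients of the original Harris-Benedict equations, by sex.
hb_coef <- list(
  male   = c(intercept = 66.4730, w = 13.7516, h = 5.0033, a = 6.7550),
  female = c(intercept = 655.0955, w = 9.5634, h = 1.8496, a = 4.6756)
)

#' Resting energy expenditure: Harris-Benedict
#'
#' Original Harris-Benedict coefficients. REE is treated as equivalent to
#' basal metabolic rate.
#'
#' @param sex `"male"` or `"female"`.
#' @param weight_kg Weight in kg.
#' @param height_cm Height in **cm**.
#' @param age_y Age in years.
#' @return REE in kcal/day.
#' @examples
#' ree_harris_benedict("male", 70, 175, 30)
#' @export
ree_harris_benedict <- function(sex, weight_kg, height_cm, age_y) {
  sex <- check_sex(sex)
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  check_nonnegative(age_y, "age_y")
  k <- hb_coef[[sex]]
  unname(k["intercept"] + k["w"] * weight_kg + k["h"] * height_cm - k["a"] * age_y)
}

#' Resting energy expenditure: Mifflin-St Jeor
#'
#' 10W + 6.25H - 5A + 5 for men, - 161 for women.
#'
#' @inheritParams ree_harris_benedict
#' @return REE in kcal/day.
#' @export
ree_mifflin <- function(sex, weight_kg, height_cm, age_y) {
  sex <- check_sex(sex)
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  check_nonnegative(age_y, "age_y")
  10 * weight_kg + 6.25 * height_cm - 5 * age_y + if (sex == "male") 5 else -161
}

#' Resting energy expenditure: Katch-McArdle
#'
#' 370 + 21.6 x lean body mass; sex-free because lean mass already absorbs
#' body-composition differences.
#'
#' @param lean_mass_kg Lean (fat-free) body mass in kg.
#' @return REE in kcal/day.
#' @export
ree_katch_mcardle <- function(lean_mass_kg) {
  check_nonnegative(lean_mass_kg, "lean_mass_kg")
  370 + 21.6 * lean_mass_kg
}

#' Resting energy expenditure: Cunningham
#'
#' 500 + 22 x lean body mass.
#'
#' @inheritParams ree_katch_mcardle
#' @return REE in kcal/day.
#' @export
ree_cunningham <- function(lean_mass_kg) {
  check_nonnegative(lean_mass_kg, "lean_mass_kg")
  500 + 22 * lean_mass_kg
}

#' Fat-free mass
#'
#' @param weight_kg Total body weight (kg).
#' @param fat_mass_kg Fat mass (kg); must be less than weight.
#' @return Fat-free mass in kg.
#' @export
fat_free_mass <- function(weight_kg, fat_mass_kg) {
  check_positive(weight_kg, "weight_kg")
  check_nonnegative(fat_mass_kg, "fat_mass_kg")
  if (any(fat_mass_kg >= weight_kg)) {
    rlang::abort("`fat_mass_kg` must be smaller than `weight_kg`")
  }
  weight_kg - fat_mass_kg
}

# Lifestyle categories and their PAL ranges. Sex plays no role: the BMR
# already absorbs the gender difference in energy needs.
pal_table <- tibble::tibble(
  lifestyle = c("sedentary_light", "moderate", "vigorous"),
  pal_low = c(1.40, 1.70, 2.00),
  pal_high = c(1.69, 1.99, 2.40)
)

#' Physical activity level from lifestyle category
#'
#' Maps the three physical-intensity lifestyle categories to their PAL
#' ranges (sedentary/light 1.40-1.69, moderate 1.70-1.99, vigorous
#' 2.00-2.40) and the range midpoint. The midpoint is a convenient default
#' multiplier for TEE; a nutritionist may equally pick any value inside the
#' range, which is why the bounds are returned too.
#'
#' @param lifestyle One of `"sedentary_light"`, `"moderate"`, `"vigorous"`.
#' @return One-row tibble: `lifestyle`, `pal_low`, `pal_high`, `pal_mid`.
#' @examples
#' pal_from_lifestyle("moderate")
#' @export
pal_from_lifestyle <- function(lifestyle) {
  if (!is.character(lifestyle) || length(lifestyle) != 1 ||
      !lifestyle %in% pal_table$lifestyle) {
    rlang::abort(paste0("`lifestyle` must be one of: ",
                        paste(pal_table$lifestyle, collapse = ", ")))
  }
  pal_table |>
    dplyr::filter(.data$lifestyle == .env$lifestyle) |>
    dplyr::mutate(pal_mid = (.data$pal_low + .data$pal_high) / 2)
}

#' Physical activity level from a 24-hour time allocation
#'
#' PAL as the time-weighted mean physical activity ratio (PAR) over a full
#' day: each habitual activity contributes hours x PAR, the total is divided
#' by 24. PAR is the energy cost of an activity as a multiple of BMR, so
#' PAR = 1 means no requirement above rest and hours must cover exactly 24.
#'
#' @param activities Data frame with columns `hours` and `par` (an optional
#'   `activity` label column is carried through), one row per activity.
#' @return One-row tibble: `sum_time_par` (the intermediate
#'   \eqn{\sum hours \times PAR}), `pal` (3+ decimals, exact quotient) and
#'   `pal_1dp` (rounded half-up to one decimal, the convention used when a
#'   population-group PAL is reported).
#' @examples
#' pal_from_time_allocation(
#'   tibble::tibble(hours = c(8, 16), par = c(1, 2))
#' )
#' @export
pal_from_time_allocation <- function(activities) {
  stopifnot(is.data.frame(activities))
  req <- setdiff(c("hours", "par"), names(activities))
  if (length(req) > 0) {
    rlang::abort(paste0("`activities` is missing columns: ",
                        paste(req, collapse = ", ")))
  }
  total_h <- sum(activities$hours)
  if (abs(total_h - 24) > 1e-9) {
    rlang::abort(sprintf(
      "activity hours must sum to 24 h, got %.6g (off by %.6g h)",
      total_h, total_h - 24
    ))
  }
  if (any(activities$par < 1)) {
    rlang::abort("every PAR must be >= 1 (PAR is 1 at rest)")
  }
  sum_time_par <- sum(activities$hours * activities$par)
  pal <- sum_time_par / 24
  tibble::tibble(
    sum_time_par = sum_time_par,
    pal = pal,
    pal_1dp = round_half_up(pal, 1)
  )
}

#' Total energy expenditure
#'
#' TEE = REE x PAL; equivalently PAL = TEE/REE, so `tee(ree, pal) / ree`
#' recovers `pal` exactly.
#'
#' @param ree REE in kcal/day (> 0).
#' @param pal Physical activity level (> 0).
#' @return TEE in kcal/day.
#' @export
tee <- function(ree, pal) {
  check_positive(ree, "ree")
  check_positive(pal, "pal")
  ree * pal
}

#' Caloric balance
#'
#' CB = CC - PEE - REE - TEF: the surplus (positive) or deficit (negative)
#' between calories consumed and calories expended. The thermic effect of
#' food contributes 3-10% of total expenditure but is hard to measure, so it
#' is carried as a pass-through parameter defaulting to 0.
#'
#' @param cc Caloric consumption (kcal/day, >= 0).
#' @param pee Physical activity energy expenditure (kcal/day, >= 0), e.g.
#'   smartwatch-logged active calories.
#' @param ree Resting energy expenditure (kcal/day, >= 0).
#' @param tef Thermic effect of food (kcal/day, >= 0); default 0.
#' @return One-row tibble with `cc`, `pee`, `ree`, `tef`, `cb`.
#' @examples
#' caloric_balance(cc = 2500, pee = 400, ree = 1700)
#' @export
caloric_balance <- function(cc, pee, ree, tef = 0) {
  check_nonnegative(cc, "cc")
  check_nonnegative(pee, "pee")
  check_nonnegative(ree, "ree")
  check_nonnegative(tef, "tef")
  tibble::tibble(cc = cc, pee = pee, ree = ree, tef = tef,
                 cb = cc - pee - ree - tef)
}

#' Energy report for a person
#'
#' Convenience wrapper computing BMI, all four REE equations that the
#' person's data permit, PAL (lifestyle midpoint), and TEE per equation.
#'
#' @param sex,weight_kg,age_y Person metrics.
#' @param height_m Height in metres.
#' @param lifestyle Lifestyle category, see [pal_from_lifestyle()].
#' @param fat_mass_kg Optional fat mass; enables the lean-mass equations.
#' @return Tibble with one row per REE equation: `equation`, `ree_kcal`,
#'   `pal`, `tee_kcal`, plus `bmi` repeated for convenience.
#' @export
energy_report <- function(sex, weight_kg, height_m, age_y,
                          lifestyle = "sedentary_light", fat_mass_kg = NULL) {
  pal <- pal_from_lifestyle(lifestyle)$pal_mid
  height_cm <- m_to_cm(height_m)
  out <- tibble::tibble(
    equation = c("harris_benedict", "mifflin_st_jeor"),
    ree_kcal = c(
      ree_harris_benedict(sex, weight_kg, height_cm, age_y),
      ree_mifflin(sex, weight_kg, height_cm, age_y)
    )
  )
  if (!is.null(fat_mass_kg)) {
    lean <- fat_free_mass(weight_kg, fat_mass_kg)
    out <- dplyr::bind_rows(out, tibble::tibble(
      equation = c("katch_mcardle", "cunningham"),
      ree_kcal = c(ree_katch_mcardle(lean), ree_cunningham(lean))
    ))
  }
  out |>
    dplyr::mutate(
      pal = pal,
      tee_kcal = tee(.data$ree_kcal, pal),
      bmi = bmi(weight_kg, height_m)
    )
}
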