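test_that("macro energy split conserves energy and converts via Atwater 4/4/9", {
  s <- macro_energy_split(2000, 0.3, 0.5, 0.2)
  expect_equal(c(s$energy_protein, s$energy_carbs, s$energy_lipids),
               c(600, 1000, 400))
  expect_equal(s$grams_protein, 150)
  expect_equal(s$grams_carbs, 250)
  expect_equal(s$grams_lipids, 400 / 9)

  all_protein <- macro_energy_split(2000, 1, 0, 0)
  expect_equal(all_protein$energy_protein, 2000)
  expect_equal(all_protein$grams_protein, 500)

  expect_error(macro_energy_split(2000, 0.5, 0.5, 0.5), "must equal 1")
  expect_error(macro_energy_split(0, 0.3, 0.5, 0.2), "> 0")
})

test_that("macro split conserves energy for fuzzed valid fractions", {
  withr::with_seed(101, {
    for (i in 1:30) {
      f <- runif(3)
      f <- f / sum(f)
      e <- runif(1, 800, 4500)
      s <- macro_energy_split(e, f[1], f[2], f[3])
      expect_equal(s$energy_protein + s$energy_carbs + s$energy_lipids, e)
      expect_equal(4 * s$grams_protein + 4 * s$grams_carbs + 9 * s$grams_lipids, e)
    }
  })
})

test_that("grams per kg converts both ways", {
  expect_equal(grams_per_kg(150, 75), 2)
  expect_equal(grams_from_per_kg(2, 75), 150)
  expect_equal(grams_per_kg(0, 80), 0)
  expect_error(grams_per_kg(100, 0), "> 0")
})

test_that("plan totals are the scaled sum over items, per meal and per day", {
  ft <- tiny_food_table()
  # single meal, single food at 100 g returns that food's composition
  one <- food_plan("p", "u",
                   tibble::tibble(variant = "monday", meal_type = "lunch",
                                  food_id = "rice", quantity_g = 100),
                   tiny_targets(), food_table = ft)
  expect_equal(plan_totals(one, ft, "monday")$energy_kcal, 130)
  expect_equal(plan_totals(one, ft, "monday")$carbs_g, 28)

  plan <- tiny_plan()
  day <- plan_totals(plan, ft, "monday")
  # hand sum: 1.5*rice + 1*apple + 1.2*chicken + 1*fooda + 2*rice
  expect_equal(day$energy_kcal,
               1.5 * 130 + 52 + 1.2 * 165 + 250 + 2 * 130)
  by_meal <- plan_totals(plan, ft, "monday", by = "meal")
  expect_equal(sum(by_meal$energy_kcal), day$energy_kcal)
  expect_equal(by_meal$energy_kcal[by_meal$meal_type == "dinner"], 260)

  bad <- food_plan("p", "u",
                   tibble::tibble(variant = "monday", meal_type = "lunch",
                                  food_id = "ghost", quantity_g = 50),
                   tiny_targets())
  expect_error(plan_totals(bad, ft, "monday"), "ghost")
})

test_that("plan totals equal a brute-force accumulation on random plans", {
  withr::with_seed(5, {
    for (i in 1:5) {
      ft <- generate_food_table(15, seed = i)
      targets <- plan_targets(2200, 0.25, 0.5, 0.25)
      plan <- generate_meal_plan(ft, targets, seed = i)
      v <- sample(unique(plan$meals$variant), 1)
      got <- plan_totals(plan, ft, v)
      want <- oracle_plan_totals(plan_variant_meals(plan, v), ft)
      expect_equal(unlist(got), want)
    }
  })
})

test_that("validation reports only nutrients beyond tolerance", {
  # single synthetic food with Atwater-exact energy: 500 g gives day totals
  # P=50, C=200, L=50, E=1450
  ft <- tibble::tibble(
    food_id = "mix", name = "mix",
    energy_kcal = 290, protein_g = 10, carbs_g = 40, lipids_g = 10,
    fiber_g = 2, water_ml = 20, iron_mg = 1, calcium_mg = 50, sodium_mg = 100,
    magnesium_mg = 20
  )
  meals <- tibble::tibble(variant = "monday", meal_type = "lunch",
                          food_id = "mix", quantity_g = 500)

  exact <- plan_targets(1450, alpha = 200 / 1450, gamma = 800 / 1450,
                        beta = 450 / 1450, fiber_g = 10, water_ml = 100,
                        micronutrients = list(iron_mg = 5))
  plan <- food_plan("p", "u", meals, exact, food_table = ft)
  expect_equal(nrow(validate_plan(plan, ft, "monday", tolerance = 0.05)), 0)

  # protein target inflated 8%, the 16 kcal taken from carbs (2% shift):
  # at 5% tolerance exactly the protein row must surface
  off <- plan_targets(1450, alpha = 4 * 54 / 1450, gamma = 4 * 196 / 1450,
                      beta = 450 / 1450, fiber_g = 10, water_ml = 100)
  plan_off <- food_plan("p", "u", meals, off, food_table = ft)
  dev <- validate_plan(plan_off, ft, "monday", tolerance = 0.05)
  expect_equal(nrow(dev), 1)
  expect_equal(dev$nutrient, "protein_g")
  expect_equal(dev$relative_error, abs(50 - 54) / 54)

  # an empty intake against a 2000 kcal target is a full-relative-error miss
  dev0 <- validate_plan(
    food_plan("p", "u",
              tibble::tibble(variant = "monday", meal_type = "lunch",
                             food_id = "mix", quantity_g = 1e-9),
              plan_targets(2000, 0.3, 0.5, 0.2), food_table = ft),
    ft, "monday", tolerance = 0.05)
  expect_equal(dev0$relative_error[dev0$nutrient == "energy_kcal"], 1,
               tolerance = 1e-6)
})

test_that("per-meal energy validation uses the plan's meal fractions", {
  ft <- tiny_food_table()
  targets <- plan_targets(1000, 0.3, 0.5, 0.2,
                          meal_energy_fractions = c(breakfast = 0.5,
                                                    lunch = 0.5))
  meals <- tibble::tibble(variant = "monday",
                          meal_type = c("breakfast", "lunch"),
                          food_id = c("e500", "e500"),
                          quantity_g = c(100, 60))
  plan <- food_plan("p", "u", meals, targets, food_table = ft)
  dev <- validate_plan(plan, ft, "monday", tolerance = 0.10)
  meal_rows <- dev[dev$scope == "meal", ]
  expect_equal(meal_rows$meal_type, "lunch")  # 300 vs 500 kcal target
  expect_equal(meal_rows$relative_error, 0.4)
})

test_that("equivalent foods: self-match first, energy-matched quantities", {
  ft <- tiny_food_table()
  eq <- equivalent_foods(ft, "rice", 150, tolerance = 0.15)
  expect_equal(eq$food_id[1], "halfrice")  # exact half density ties at 0 error
  self <- eq[eq$food_id == "rice", ]
  expect_equal(self$quantity_g, 150)
  expect_equal(self$macro_error, 0)
  # halfrice has exactly half the density: double quantity, zero error
  half <- eq[eq$food_id == "halfrice", ]
  expect_equal(half$quantity_g, 300)
  expect_equal(half$macro_error, 0)
  # zero-energy foods can never match on energy
  expect_false("zeroed" %in% eq$food_id)
  expect_error(equivalent_foods(ft, "zeroed", 100), "zero energy")
  expect_error(equivalent_foods(ft, "nope", 100), "nope")
})

test_that("equivalent foods equal an exhaustive filter oracle, order-invariant", {
  withr::with_seed(23, {
    for (i in 1:4) {
      ft <- generate_food_table(sample(10:20, 1), seed = 100 + i)
      ref <- sample(ft$food_id, 1)
      got <- equivalent_foods(ft, ref, 120, tolerance = 0.15)
      want <- oracle_equivalent(ft, ref, 120, tolerance = 0.15)
      expect_equal(got$food_id, want$food_id)
      expect_equal(got$quantity_g, want$quantity_g)
      expect_equal(got$macro_error, want$macro_error)

      shuffled <- ft[sample(nrow(ft)), ]
      expect_equal(equivalent_foods(shuffled, ref, 120, tolerance = 0.15), got)
    }
  })
})

test_that("water goal rises cumulatively with crossed thresholds", {
  rules <- hydration_rules(c(25, 30), c(300, 500))
  expect_equal(adjust_water_goal(2000, 40), 2000)  # no rules
  expect_equal(adjust_water_goal(2000, 27, rules), 2300)
  expect_equal(adjust_water_goal(2000, 32, rules), 2800)
  expect_equal(adjust_water_goal(2000, 25, rules), 2000)  # strict crossing
  expect_equal(adjust_water_goal(2000, 10, rules), 2000)

  withr::with_seed(9, {
    temps <- sort(runif(30, -5, 45))
    goals <- vapply(temps, adjust_water_goal, numeric(1), base_ml = 1500,
                    rules = rules)
    expect_true(all(diff(goals) >= 0))
    expect_true(all(goals[temps <= 25] == 1500))
  })

  expect_error(hydration_rules(c(30, 25), c(1, 1)), "increasing")
})
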