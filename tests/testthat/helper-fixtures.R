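# Hand-built fixtures with easy arithmetic, shared across test files.

tiny_food_table <- function() {
  tibble::tribble(
    ~food_id, ~name, ~energy_kcal, ~protein_g, ~carbs_g, ~lipids_g, ~fiber_g,
    ~water_ml, ~iron_mg, ~calcium_mg, ~sodium_mg, ~magnesium_mg,
    "apple", "apple", 52, 0.3, 14, 0.2, 2.4, 86, 0.1, 6, 1, 5,
    "rice", "boiled rice", 130, 2.7, 28, 0.3, 0.4, 69, 0.2, 10, 1, 12,
    "halfrice", "diluted rice", 65, 1.35, 14, 0.15, 0.2, 34.5, 0.1, 5, 0.5, 6,
    "chicken", "chicken breast", 165, 31, 0, 3.6, 0, 65, 1, 15, 74, 29,
    "fooda", "food a", 250, 10, 30, 8, 1, 40, 0.5, 20, 50, 10,
    "foodb", "food b", 160, 6, 20, 5.3, 1, 60, 0.4, 25, 40, 12,
    "e500", "dense snack", 500, 10, 60, 24, 2, 5, 1, 30, 200, 40,
    "zeroed", "water-like", 0, 0, 0, 0, 0, 99, 0, 2, 1, 1
  )
}

# one-variant plan over the tiny table: breakfast rice+apple, lunch
# chicken+fooda, dinner rice
tiny_plan <- function(targets = tiny_targets()) {
  meals <- tibble::tribble(
    ~variant, ~meal_type, ~food_id, ~quantity_g,
    "monday", "breakfast", "rice", 150,
    "monday", "breakfast", "apple", 100,
    "monday", "lunch", "chicken", 120,
    "monday", "lunch", "fooda", 100,
    "monday", "dinner", "rice", 200
  )
  food_plan("p1", "anon", meals, targets,
            water_rules = hydration_rules(c(25, 30), c(300, 500)),
            food_table = tiny_food_table())
}

tiny_targets <- function() {
  plan_targets(energy_kcal = 2000, alpha = 0.3, gamma = 0.5, beta = 0.2,
               fiber_g = 25, water_ml = 2000,
               micronutrients = list(iron_mg = 10, calcium_mg = 900))
}

# the nine printed activity rows of the population-group time-allocation
# example (hours over a 24 h day and the PAR of each activity)
table4_activities <- function() {
  tibble::tribble(
    ~activity, ~hours, ~par,
    "Sleeping", 6, 1.0,
    "Personal Care (dressing, showering)", 2, 2.3,
    "Eating", 2, 1.5,
    "Walking without a load", 2, 3.2,
    "Sitting", 4, 1.5,
    "Cooking", 2, 2.1,
    "Household work", 2, 2.8,
    "Light leisure activities", 2, 1.4,
    "Driving car", 2, 2.0
  )
}
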