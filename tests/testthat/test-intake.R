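ft <- tiny_food_table()

test_that("confirming a meal consumes exactly the planned meal vector", {
  plan <- tiny_plan()
  log <- new_intake_log() |>
    confirm_meal(plan, "monday", "dinner", "2022-03-07T20:00:00")
  stats <- daily_stats(log, plan, ft, "monday", "2022-03-07")
  expect_equal(stats$consumed$energy_kcal, 260)  # 200 g rice

  # duplicate confirmation and confirm-then-partial both conflict
  expect_error(confirm_meal(log, plan, "monday", "dinner",
                            "2022-03-07T21:00:00"), "already logged")
  expect_error(log_partial(log, plan, "monday", "dinner", 50,
                           "2022-03-07T21:00:00"), "already logged")
  expect_error(confirm_meal(log, plan, "monday", "tea", "2022-03-07T20:00:00"),
               "unknown meal types|no meal")

  # two of three meals: hand sum of breakfast + dinner
  log2 <- confirm_meal(log, plan, "monday", "breakfast", "2022-03-07T08:00:00")
  s2 <- daily_stats(log2, plan, ft, "monday", "2022-03-07")
  expect_equal(s2$consumed$energy_kcal, 260 + 1.5 * 130 + 52)
})

test_that("partial intake scales the planned meal uniformly", {
  plan <- tiny_plan()
  full <- new_intake_log() |>
    confirm_meal(plan, "monday", "dinner", "2022-03-07T20:00:00")
  half <- new_intake_log() |>
    log_partial(plan, "monday", "dinner", 50, "2022-03-07T20:00:00")
  s_full <- daily_stats(full, plan, ft, "monday", "2022-03-07")
  s_half <- daily_stats(half, plan, ft, "monday", "2022-03-07")
  expect_equal(s_half$consumed$energy_kcal, s_full$consumed$energy_kcal / 2)
  expect_equal(s_half$consumed$energy_kcal, 130)

  hundred <- new_intake_log() |>
    log_partial(plan, "monday", "dinner", 100, "2022-03-07T20:00:00")
  expect_equal(daily_stats(hundred, plan, ft, "monday", "2022-03-07")$consumed,
               s_full$consumed)

  expect_error(log_partial(new_intake_log(), plan, "monday", "dinner", 0,
                           "2022-03-07T20:00:00"), "\\(0, 100\\]")
  expect_error(log_partial(new_intake_log(), plan, "monday", "dinner", 150,
                           "2022-03-07T20:00:00"), "\\(0, 100\\]")
})

test_that("extra food adds its scaled composition to the day", {
  plan <- tiny_plan()
  log <- new_intake_log() |>
    log_extra_food(ft, "e500", 30, "2022-03-07T16:00:00")
  s <- daily_stats(log, plan, ft, "monday", "2022-03-07")
  expect_equal(s$consumed$energy_kcal, 150)  # 30 g of 500 kcal/100 g

  log100 <- new_intake_log() |>
    log_extra_food(ft, "apple", 100, "2022-03-07T16:00:00")
  s100 <- daily_stats(log100, plan, ft, "monday", "2022-03-07")
  expect_equal(s100$consumed$carbs_g, 14)

  expect_error(log_extra_food(new_intake_log(), ft, "ghost", 50,
                              "2022-03-07T16:00:00"), "ghost")
})

test_that("substitution replaces an item; removal drops it", {
  # lunch: 100 g fooda (250 kcal/100 g) + 120 g chicken
  plan <- tiny_plan()
  # identity substitution reproduces the planned meal exactly
  ident <- new_intake_log() |>
    substitute_food(plan, "monday", "lunch", "fooda", "fooda", 100, ft,
                    "2022-03-07T13:00:00")
  confirmed <- new_intake_log() |>
    confirm_meal(plan, "monday", "lunch", "2022-03-07T13:00:00")
  expect_equal(daily_stats(ident, plan, ft, "monday", "2022-03-07")$consumed,
               daily_stats(confirmed, plan, ft, "monday", "2022-03-07")$consumed)

  # 100 g fooda (250 kcal) -> 150 g foodb (160 kcal/100 g = 240 kcal): -10
  swap <- new_intake_log() |>
    substitute_food(plan, "monday", "lunch", "fooda", "foodb", 150, ft,
                    "2022-03-07T13:00:00")
  e_conf <- daily_stats(confirmed, plan, ft, "monday", "2022-03-07")$consumed$energy_kcal
  e_swap <- daily_stats(swap, plan, ft, "monday", "2022-03-07")$consumed$energy_kcal
  expect_equal(e_swap - e_conf, -10)

  removed <- new_intake_log() |>
    remove_food(plan, "monday", "lunch", "fooda", "2022-03-07T13:00:00")
  e_rm <- daily_stats(removed, plan, ft, "monday", "2022-03-07")$consumed$energy_kcal
  expect_equal(e_rm, e_conf - 250)

  expect_error(substitute_food(new_intake_log(), plan, "monday", "lunch",
                               "apple", "foodb", 100, ft,
                               "2022-03-07T13:00:00"), "not in the planned meal")
  expect_error(remove_food(new_intake_log(), plan, "monday", "lunch", "rice",
                           "2022-03-07T13:00:00"), "not in the planned meal")
})

test_that("water accumulates across sources and rejects non-positive sips", {
  plan <- tiny_plan()
  log <- new_intake_log() |>
    log_water(200, "2022-03-07T08:30:00") |>
    log_water(150, "2022-03-07T12:30:00", source = "bottle") |>
    log_water(250, "2022-03-07T18:30:00")
  s <- daily_stats(log, plan, ft, "monday", "2022-03-07")
  expect_equal(s$water_consumed_ml, 600)
  expect_error(log_water(new_intake_log(), 0, "2022-03-07T08:30:00"), "> 0")
})

test_that("device CSV ingestion is row-tolerant and duplicate-safe", {
  plan <- tiny_plan()
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("timestamp,value", path)
  empty <- ingest_device_csv(new_intake_log(), path, "water")
  expect_equal(nrow(empty$log), 0)
  expect_equal(nrow(empty$report), 0)

  writeLines(c("timestamp,value",
               "2022-03-07T08:00:00,200",
               "2022-03-07T09:00:00,250",
               "2022-03-07T10:00:00,300",
               "2022-03-07T11:00:00,150",
               "2022-03-07T12:00:00,300"), path)
  res <- ingest_device_csv(new_intake_log(), path, "water")
  expect_equal(sum(res$report$status == "accepted"), 5)
  s <- daily_stats(res$log, plan, ft, "monday", "2022-03-07")
  expect_equal(s$water_consumed_ml, 1200)

  # duplicate timestamp: first wins, in-file and across re-ingestion
  writeLines(c("timestamp,value",
               "2022-03-07T13:00:00,100",
               "2022-03-07T13:00:00,999"), path)
  dup <- ingest_device_csv(res$log, path, "water")
  expect_equal(dup$report$status, c("accepted", "duplicate"))
  again <- ingest_device_csv(dup$log, path, "water")
  expect_equal(again$report$status, c("duplicate", "duplicate"))
  expect_equal(nrow(again$log), nrow(dup$log))

  # malformed rows are reported with their line number, batch continues
  writeLines(c("timestamp,value",
               "not-a-date,100",
               "2022-03-07T14:00:00,abc",
               "2022-03-07T15:00:00,180"), path)
  bad <- ingest_device_csv(new_intake_log(), path, "water")
  expect_equal(bad$report$status, c("rejected", "rejected", "accepted"))
  expect_equal(bad$report$line[1:2], c(2L, 3L))

  writeLines(c("timestamp,value", "2022-03-07T16:00:00,320"), path)
  act <- ingest_device_csv(new_intake_log(), path, "activity")
  expect_equal(act$log$kind, "activity_calories")
  expect_equal(act$log$amount, 320)
})

test_that("daily stats aggregate a mixed day and stay order-independent", {
  plan <- tiny_plan()
  log <- new_intake_log() |>
    confirm_meal(plan, "monday", "breakfast", "2022-03-07T08:00:00") |>
    confirm_meal(plan, "monday", "lunch", "2022-03-07T13:00:00") |>
    log_extra_food(ft, "e500", 50, "2022-03-07T16:00:00") |>
    log_water(800, "2022-03-07T10:00:00") |>
    log_activity(350, "2022-03-07T21:00:00")
  s <- daily_stats(log, plan, ft, "monday", "2022-03-07")

  want <- oracle_plan_totals(
    tibble::tibble(food_id = c("rice", "apple", "chicken", "fooda", "e500"),
                   quantity_g = c(150, 100, 120, 100, 50)), ft)
  expect_equal(unlist(s$consumed), want)
  expect_equal(s$pee_logged_kcal, 350)
  expect_equal(s$water_consumed_ml, 800)

  # caloric balance from the day's numbers
  cb <- caloric_balance(cc = s$consumed$energy_kcal, pee = s$pee_logged_kcal,
                        ree = 1700)
  expect_equal(cb$cb, s$consumed$energy_kcal - 350 - 1700)

  # replaying entries in any order yields identical statistics
  withr::with_seed(31, {
    for (i in 1:5) {
      shuffled <- log[sample(nrow(log)), ]
      s2 <- daily_stats(shuffled, plan, ft, "monday", "2022-03-07")
      expect_equal(s2$nutrients, s$nutrients)
      expect_equal(s2$water_consumed_ml, s$water_consumed_ml)
    }
  })
})

test_that("removing an entry lowers consumption by exactly that entry", {
  plan <- tiny_plan()
  log <- new_intake_log() |>
    confirm_meal(plan, "monday", "dinner", "2022-03-07T20:00:00") |>
    log_extra_food(ft, "apple", 100, "2022-03-07T16:00:00")
  full <- daily_stats(log, plan, ft, "monday", "2022-03-07")$consumed
  without <- daily_stats(log[log$kind != "extra_food", ], plan, ft, "monday",
                         "2022-03-07")$consumed
  apple_vec <- nv_scale(ft[ft$food_id == "apple", ], 1)
  expect_equal(nv_add(without, apple_vec), full)
})

test_that("targets pass through, with temperature-adjusted water goals", {
  plan <- tiny_plan()
  empty <- daily_stats(new_intake_log(), plan, ft, "monday", "2022-03-07")
  expect_equal(empty$consumed, nv_zero())
  expect_equal(empty$water_target_ml, 2000)
  e_row <- empty$nutrients[empty$nutrients$nutrient == "energy_kcal", ]
  expect_equal(e_row$target, 2000)
  expect_equal(e_row$fraction_of_target, 0)

  hot <- daily_stats(new_intake_log(), plan, ft, "monday", "2022-03-07",
                     temperature_c = 32)
  expect_equal(hot$water_target_ml, 2800)

  # fraction is exactly 1 when consumed equals target, NA for zero targets
  ft1 <- tibble::tibble(food_id = "m", name = "m", energy_kcal = 290,
                        protein_g = 10, carbs_g = 40, lipids_g = 10,
                        fiber_g = 0, water_ml = 0, iron_mg = 0, calcium_mg = 0,
                        sodium_mg = 0, magnesium_mg = 0)
  p1 <- food_plan("p", "u",
                  tibble::tibble(variant = "monday", meal_type = "lunch",
                                 food_id = "m", quantity_g = 100),
                  plan_targets(290, 40 / 290, 160 / 290, 90 / 290),
                  food_table = ft1)
  s1 <- daily_stats(
    confirm_meal(new_intake_log(), p1, "monday", "lunch",
                 "2022-03-07T13:00:00"),
    p1, ft1, "monday", "2022-03-07")
  n <- s1$nutrients
  expect_equal(n$fraction_of_target[n$nutrient == "energy_kcal"], 1)
  expect_true(is.na(n$fraction_of_target[n$nutrient == "water_ml"]))
})

test_that("intake on event keys stays separate from the calendar day", {
  plan2 <- food_plan(
    "p2", "anon",
    dplyr::bind_rows(
      tiny_plan()$meals,
      tibble::tibble(variant = "train", meal_type = "event",
                     food_id = "e500", quantity_g = 80)),
    tiny_targets(), food_table = ft)
  log <- new_intake_log() |>
    confirm_meal(plan2, "train", "event", "2022-03-07T18:00:00", key = "train") |>
    confirm_meal(plan2, "monday", "dinner", "2022-03-07T20:00:00")
  ev <- daily_stats(log, plan2, ft, "train", "train")
  day <- daily_stats(log, plan2, ft, "monday", "2022-03-07")
  expect_equal(ev$consumed$energy_kcal, 400)
  expect_equal(day$consumed$energy_kcal, 260)
})
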