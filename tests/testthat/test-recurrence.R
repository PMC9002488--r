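test_that("occurrence days scan items by membership and meals by set equality", {
  s <- example_sequence()
  latte <- occurrence_days(s, "latte")
  expect_equal(latte$days, c(1:11, 13, 14))
  expect_equal(latte$frequency, 13L)
  lm <- occurrence_days(s, c("muffin", "latte"), type = "meal")
  expect_equal(lm$frequency, 7L)
  # choice never occurring -> valid empty occurrence set
  expect_equal(occurrence_days(s, "cereal")$frequency, 0L)
  one <- consumption_sequence("u", "o", as.Date("2020-01-01"), list("a"))
  expect_equal(occurrence_days(one, "a")$days, 1L)
})

test_that("relative frequency is occurrences per recorded day", {
  s <- example_sequence()
  occ <- structure(list(choice = "x", days = 1:5, frequency = 5L),
                   class = "occurrence_set")
  expect_equal(relative_frequency(occ, 28), 5 / 28)
  expect_equal(relative_frequency(occurrence_days(s, "latte"), s$n), 13 / 14)
  daily <- occurrence_days(
    consumption_sequence("u", "o", as.Date("2020-01-01") + 0:9,
                         rep(list("cereal"), 10)), "cereal")
  expect_equal(relative_frequency(daily, 10), 1)
  expect_error(relative_frequency(occ, 0), "undefined")
})

test_that("span is the normalized first-to-last occurrence difference", {
  occ <- structure(list(choice = "x", days = 1:5, frequency = 5L),
                   class = "occurrence_set")
  expect_equal(span(occ, 28), 4 / 28)
  single <- structure(list(choice = "x", days = 7L, frequency = 1L),
                      class = "occurrence_set")
  expect_equal(span(single, 28), 0)
  none <- structure(list(choice = "x", days = integer(0), frequency = 0L),
                    class = "occurrence_set")
  expect_error(span(none, 28), "undefined")
  # brute force on random sequences
  set.seed(4)
  for (i in 1:50) {
    s <- random_sequence()
    item <- sample(unique(unlist(s$meals)), 1)
    occ <- occurrence_days(s, item)
    days <- oracle_item_days(s$meals, item)
    expect_equal(relative_frequency(occ, s$n), length(days) / s$n)
    expect_equal(span(occ, s$n), (max(days) - min(days)) / s$n)
  }
})

test_that("the worked example yields its published recurrent sets and tuple", {
  s <- example_sequence()
  expect_identical(recurrent_items(s), c("latte", "muffin"))
  expect_same_meal_set(recurrent_meals(s),
                       list(c("latte", "muffin"), "latte"))
  strengths <- recurrence_strengths(s, recurrent_items(s), recurrent_meals(s))
  expect_equal(unname(strengths), c(1, 13 / 14, 12 / 14))
  # rounded presentation
  expect_equal(round(unname(strengths), 2), c(1, 0.93, 0.86))
  expect_equal(avg_items_per_meal(s), 23 / 14)
})

test_that("degenerate sequences behave as defined", {
  one <- consumption_sequence("u", "o", as.Date("2020-01-01"), list("a"))
  # single day: span 0 < 1/2 -> nothing recurrent
  expect_length(recurrent_items(one), 0L)
  expect_length(recurrent_meals(one), 0L)
  expect_equal(unname(recurrence_strengths(one, character(0), list())),
               c(0, 0, 0))
  # identical meals daily -> everything recurrent, tuple (1, 1, 1)
  same <- consumption_sequence("u", "o", as.Date("2020-01-01") + 0:13,
                               rep(list(c("a", "b")), 14))
  expect_identical(recurrent_items(same), c("a", "b"))
  expect_same_meal_set(recurrent_meals(same), list(c("a", "b")))
  p <- recurrence_profile(same)
  expect_equal(c(p$alpha, p$beta, p$gamma), c(1, 1, 1))
  expect_equal(avg_items_per_meal(same), 2)
})

test_that("strict thresholds use > and never enlarge the recurrent sets", {
  # frequency exactly 1/7 and span exactly 1/2 pass inclusively, fail strictly
  meals <- rep(list("filler"), 14)
  meals[[4]] <- c("filler", "edge")
  meals[[11]] <- c("filler", "edge")  # freq 2/14 = 1/7, span 7/14 = 1/2
  s <- consumption_sequence("u", "o", as.Date("2020-01-01") + 0:13, meals)
  expect_true("edge" %in% recurrent_items(s))
  expect_false("edge" %in%
                 recurrent_items(s, recurrence_thresholds(strict = TRUE)))
})

test_that("raising thresholds never enlarges sets or strengths", {
  set.seed(12)
  lo <- recurrence_thresholds(1 / 7, 1 / 2)
  hi <- recurrence_thresholds(2 / 7, 3 / 4)
  violations <- 0L
  for (i in 1:100) {
    s <- random_sequence()
    p_lo <- recurrence_profile(s, lo)
    p_hi <- recurrence_profile(s, hi)
    keys_lo <- vapply(p_lo$recurrent_meals, paste, character(1), collapse = "|")
    keys_hi <- vapply(p_hi$recurrent_meals, paste, character(1), collapse = "|")
    ok <- all(p_hi$recurrent_items %in% p_lo$recurrent_items) &&
      all(keys_hi %in% keys_lo) &&
      p_hi$alpha <= p_lo$alpha && p_hi$beta <= p_lo$beta &&
      p_hi$gamma <= p_lo$gamma
    if (!ok) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("per-day strengths equal the meal-library-weighted sums", {
  set.seed(13)
  mismatches <- 0L
  for (i in 1:100) {
    s <- random_sequence()
    p <- recurrence_profile(s)
    o <- oracle_profile(s)
    ok <- abs(p$alpha - o$alpha) < 1e-12 && abs(p$beta - o$beta) < 1e-12 &&
      abs(p$gamma - o$gamma) < 1e-12 &&
      abs(p$avg_items_per_meal - o$avg_items_per_meal) < 1e-12
    if (!ok) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("profiles are deterministic and respect containment invariants", {
  set.seed(14)
  violations <- 0L
  for (i in 1:50) {
    s <- random_sequence()
    p1 <- recurrence_profile(s)
    p2 <- recurrence_profile(s)
    lib_keys <- vapply(p1$meal_library, paste, character(1), collapse = "|")
    rec_keys <- vapply(p1$recurrent_meals, paste, character(1), collapse = "|")
    ok <- identical(p1, p2) &&
      all(p1$recurrent_items %in% p1$food_item_library) &&
      all(rec_keys %in% lib_keys) &&
      all(c(p1$alpha, p1$beta, p1$gamma) >= 0) &&
      all(c(p1$alpha, p1$beta, p1$gamma) <= 1)
    if (!ok) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})
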