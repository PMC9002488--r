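test_that("serving-size suffix splits at the last comma", {
  expect_equal(strip_serving_size("Latte, 12 oz"), "latte")
  expect_equal(strip_serving_size("muffin"), "muffin")
  expect_equal(strip_serving_size("Chicken, grilled, 3 oz"), "chicken, grilled")
  expect_equal(strip_serving_size("  Apple , 1 medium "), "apple")
  # empty after stripping flags the row invalid
  expect_true(is.na(strip_serving_size(", 2 cups")))
  expect_true(is.na(strip_serving_size("   ")))
})

test_that("zero-calorie entries are dropped within surviving meals", {
  d <- make_diary(list("u", "2020-01-01", "breakfast", "bread", 200),
                  list("u", "2020-01-01", "breakfast", "water", 0))
  out <- filter_entries(d)
  expect_equal(out$entries$item, "bread")
  expect_equal(out$audit[["zero_kcal_entry"]], 1L)
})

test_that("meals with calorie totals above the cap are removed whole", {
  d <- make_diary(list("u", "2020-01-01", "lunch", "feast a", 1700),
                  list("u", "2020-01-01", "lunch", "feast b", 1500),
                  list("u", "2020-01-02", "lunch", "salad", 300))
  out <- filter_entries(d)
  expect_equal(out$entries$item, "salad")
  expect_equal(out$audit[["high_kcal_meal"]], 2L)
  # exactly at the cap survives ("greater than" rule)
  d2 <- make_diary(list("u", "2020-01-01", "lunch", "big meal", 3000))
  expect_equal(nrow(filter_entries(d2)$entries), 1L)
})

test_that("placeholder meals are removed before the calorie rule sees them", {
  d <- make_diary(
    list("u", "2020-01-01", "lunch", "Quick Added Calories", 3500),
    list("u", "2020-01-01", "lunch", "soup", 200),
    list("u", "2020-01-02", "lunch", "salad", 300))
  out <- filter_entries(d)
  expect_equal(out$entries$item, "salad")
  expect_equal(out$audit[["placeholder_meal"]], 2L)
  expect_equal(out$audit[["high_kcal_meal"]], 0L)
})

test_that("audit counts partition the input rows", {
  d <- generate_diary(habit_spec(n_days = 30, novelty_rate = 2,
                                 zero_cal_rate = 0.3, high_cal_rate = 0.1,
                                 placeholder_rate = 0.1, seed = 5))
  a <- filter_entries(d$entries)$audit
  expect_equal(a[["rows_in"]],
               a[["rows_out"]] + a[["invalid_name"]] + a[["placeholder_meal"]] +
                 a[["high_kcal_meal"]] + a[["zero_kcal_entry"]])
})

test_that("individuals using custom occasion labels are dropped wholly", {
  d <- make_diary(list("a", "2020-01-01", "Breakfast", "latte", 150),
                  list("a", "2020-01-01", "LUNCH ", "salad", 300),
                  list("b", "2020-01-01", "breakfast", "toast", 120),
                  list("b", "2020-01-02", "brunch", "eggs", 250))
  d$item <- strip_serving_size(d$item_text)
  out <- retain_default_label_users(d)
  expect_setequal(unique(out$individual_id), "a")
  expect_setequal(unique(out$occasion), c("breakfast", "lunch"))
  # brute-force scan oracle over a mixed cohort
  set.seed(8)
  labels <- c("breakfast", "lunch", "dinner", "snacks", "brunch", "tea")
  big <- do.call(make_diary, unlist(lapply(1:30, function(i) {
    lapply(seq_len(sample(2:5, 1)), function(j) {
      list(paste0("u", i), "2020-01-01", sample(labels, 1), "food", 100)
    })
  }), recursive = FALSE))
  big$item <- strip_serving_size(big$item_text)
  keep <- retain_default_label_users(big)
  expected <- Filter(function(u) {
    all(big$occasion[big$individual_id == u] %in%
          c("breakfast", "lunch", "dinner", "snacks"))
  }, unique(big$individual_id))
  expect_setequal(unique(keep$individual_id), expected)
})

test_that("only complete days enter sequences and all occasions share them", {
  day <- function(u, date, occasions) {
    do.call(make_diary, lapply(occasions, function(o)
      list(u, date, o, paste0(o, " food"), 100)))
  }
  all4 <- c("breakfast", "lunch", "dinner", "snacks")
  d <- rbind(day("u", "2020-01-01", all4),
             day("u", "2020-01-02", setdiff(all4, "snacks")),
             day("u", "2020-01-03", all4))
  d$occasion <- tolower(d$occasion)
  d$item <- strip_serving_size(d$item_text)
  seqs <- build_sequences(d)
  expect_length(seqs, 4L)
  for (s in seqs) {
    expect_equal(s$n, 2L)
    expect_equal(format(s$dates), c("2020-01-01", "2020-01-03"))
  }
  # zero complete days -> no sequences
  seqs0 <- build_sequences(day("v", "2020-01-01", "breakfast")[
    , , drop = FALSE] |> transform(item = "x"))
  expect_length(seqs0, 0L)
})

test_that("duplicate items within a meal collapse to a set", {
  d <- make_diary(list("u", "2020-01-01", "breakfast", "latte", 150),
                  list("u", "2020-01-01", "breakfast", "Latte, 12 oz", 150),
                  list("u", "2020-01-01", "lunch", "a", 1),
                  list("u", "2020-01-01", "dinner", "b", 1),
                  list("u", "2020-01-01", "snacks", "c", 1))
  d$item <- strip_serving_size(d$item_text)
  seqs <- build_sequences(d)
  bf <- Filter(function(s) s$occasion == "breakfast", seqs)[[1]]
  expect_identical(bf$meals[[1]], "latte")
})

test_that("consistency filter applies the mean-gap and length rules", {
  mk <- function(dates, id = "u") {
    consumption_sequence(id, "breakfast", dates,
                         rep(list("x"), length(dates)))
  }
  cfg <- preprocess_config(min_sequence_length = 3)
  # dates d, d+2, d+8: gaps 1 and 5, mean 3 -> passes the gap rule
  expect_length(consistency_filter(list(mk(as.Date("2020-01-01") + c(0, 2, 8))),
                                   cfg), 1L)
  # mean gap above 3 -> dropped
  expect_length(consistency_filter(list(mk(as.Date("2020-01-01") + c(0, 2, 9))),
                                   cfg), 0L)
  # 27 contiguous days fails the default 28-day rule; 28 passes
  expect_length(consistency_filter(list(mk(as.Date("2020-01-01") + 0:26))), 0L)
  expect_length(consistency_filter(list(mk(as.Date("2020-01-01") + 0:27))), 1L)
  # brute-force oracle over random cohorts
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    dates <- as.Date("2020-01-01") + sort(sample(0:120, n))
    s <- mk(dates)
    kept <- length(consistency_filter(list(s), cfg)) == 1L
    want <- n >= 3 && mean(diff(as.numeric(dates)) - 1) <= 3
    expect_identical(kept, want)
  }
})

test_that("the filter chain is idempotent", {
  d <- generate_diary(habit_spec(n_days = 40, zero_cal_rate = 0.2,
                                 high_cal_rate = 0.1, placeholder_rate = 0.1,
                                 seed = 9))
  once <- filter_entries(d$entries)
  twice <- filter_entries(once$entries)
  expect_equal(twice$entries$item, once$entries$item)
  expect_equal(twice$audit[["rows_in"]], twice$audit[["rows_out"]])

  lab <- retain_default_label_users(once$entries)
  expect_equal(retain_default_label_users(lab), lab)

  cfg <- preprocess_config(min_sequence_length = 10)
  seqs <- consistency_filter(build_sequences(lab, cfg), cfg)
  expect_equal(length(consistency_filter(seqs, cfg)), length(seqs))
})

test_that("sequence length never exceeds the distinct logged dates", {
  d <- generate_diary(habit_spec(n_days = 30, missing_day_prob = 0.3, seed = 2))
  prep <- preprocess_diary(d$entries, preprocess_config(min_sequence_length = 1))
  n_dates <- length(unique(d$entries$date))
  for (s in prep$sequences) expect_lte(s$n, n_dates)
})
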