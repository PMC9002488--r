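# Independent brute-force oracle for the recurrence measures: naive scans
# over days, items and meals, with the meal-library-weighted strength sums.
# Deliberately structured nothing like the package implementation.

oracle_item_days <- function(meals, item) {
  days <- integer(0)
  for (t in seq_along(meals)) {
    if (item %in% meals[[t]]) days <- c(days, t)
  }
  days
}

oracle_meal_days <- function(meals, meal) {
  days <- integer(0)
  for (t in seq_along(meals)) {
    if (setequal(meals[[t]], meal)) days <- c(days, t)
  }
  days
}

oracle_distinct_meals <- function(meals) {
  out <- list()
  for (m in meals) {
    seen <- FALSE
    for (x in out) if (setequal(x, m)) { seen <- TRUE; break }
    if (!seen) out[[length(out) + 1L]] <- sort(unique(m))
  }
  out
}

oracle_is_recurrent <- function(days, n, fmin = 1 / 7, smin = 1 / 2,
                                strict = FALSE) {
  if (length(days) == 0L) return(FALSE)
  rf <- length(days) / n
  sp <- (max(days) - min(days)) / n
  if (strict) rf > fmin && sp > smin else rf >= fmin && sp >= smin
}

oracle_profile <- function(seq, fmin = 1 / 7, smin = 1 / 2, strict = FALSE) {
  meals <- seq$meals
  n <- length(meals)
  items <- sort(unique(unlist(meals)))
  rec_items <- character(0)
  for (d in items) {
    if (oracle_is_recurrent(oracle_item_days(meals, d), n, fmin, smin, strict)) {
      rec_items <- c(rec_items, d)
    }
  }
  lib <- oracle_distinct_meals(meals)
  rec_meals <- list()
  for (m in lib) {
    if (oracle_is_recurrent(oracle_meal_days(meals, m), n, fmin, smin, strict)) {
      rec_meals[[length(rec_meals) + 1L]] <- m
    }
  }
  # meal-library-weighted sums (grouping identical meals by frequency)
  alpha <- beta <- gamma <- 0
  items_total <- 0
  for (m in lib) {
    f <- length(oracle_meal_days(meals, m))
    overlap <- length(intersect(m, rec_items))
    alpha <- alpha + f / n * as.numeric(overlap >= 1)
    beta <- beta + f / n * overlap / length(m)
    in_rec <- FALSE
    for (rm in rec_meals) if (setequal(rm, m)) { in_rec <- TRUE; break }
    gamma <- gamma + f * as.numeric(in_rec) / n
    items_total <- items_total + length(m) * f
  }
  list(recurrent_items = sort(rec_items),
       recurrent_meals = rec_meals,
       alpha = alpha, beta = beta, gamma = gamma,
       avg_items_per_meal = items_total / n)
}

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (x in a) if (x %in% b) inter <- inter + 1
  u <- length(a) + length(b) - inter
  if (u == 0) 0 else 1 - inter / u
}

# sorted meal lists compared as sets of sets
expect_same_meal_set <- function(got, want) {
  expect_equal(length(got), length(want))
  for (m in want) {
    found <- any(vapply(got, function(g) setequal(g, m), logical(1)))
    expect_true(found, label = paste("meal {", paste(m, collapse = ","), "} present"))
  }
}
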