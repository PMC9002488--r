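#' Specification of a synthetic food diary with known habitual structure
#'
#' Describes a generative model for one individual's diary: each recorded
#' day and occasion, the meal is the union of habitual items, each included
#' independently with its own daily probability, and a Poisson number of
#' never-repeating novelty items drawn without replacement from a large
#' vocabulary. Days go unrecorded independently with probability
#' `missing_day_prob`, making the recorded days irregular as in real
#' app-collected diaries. Optional artifact rates inject the kinds of noise
#' the preprocessing filters exist for: zero-calorie entries, meals pushed
#' above 3000 kcal, and placeholder "quick added calories" meals.
#'
#' @param habitual_items Named numeric vector: names are habitual item
#'   names, values their daily inclusion probabilities in (0, 1].
#' @param novelty_vocab_size Size of the novelty vocabulary; must be much
#'   larger than `n_days` for novelty items to stay non-recurrent.
#' @param novelty_rate Expected novelty items per meal (Poisson mean).
#' @param n_days Calendar days in the observation window (>= 1).
#' @param missing_day_prob Probability a calendar day is unrecorded, in
#'   \[0, 1).
#' @param weekend_multiplier Factor applied to habitual inclusion
#'   probabilities on Saturdays/Sundays (capped at 1); values below 1 model
#'   the weaker weekend routine.
#' @param occasions Occasion labels to emit for every recorded day.
#' @param zero_cal_rate,high_cal_rate,placeholder_rate Per-meal probability
#'   of injecting, respectively, a zero-calorie entry, a >3000 kcal entry,
#'   and a placeholder meal entry.
#' @param start_date First calendar day.
#' @param seed Integer RNG seed; the diary is reproducible given the spec.
#' @return An object of class `habit_spec`.
#' @export
habit_spec <- function(habitual_items = c(latte = 0.8, muffin = 0.5),
                       novelty_vocab_size = 5000L, novelty_rate = 1,
                       n_days = 112L, missing_day_prob = 0,
                       weekend_multiplier = 1,
                       occasions = c("breakfast", "lunch", "dinner", "snacks"),
                       zero_cal_rate = 0, high_cal_rate = 0,
                       placeholder_rate = 0,
                       start_date = as.Date("2014-09-01"), seed = 1L) {
  p <- unname(habitual_items)
  if (length(habitual_items) > 0 &&
      (is.null(names(habitual_items)) || any(!nzchar(names(habitual_items))))) {
    stop("habitual_items must be a named vector of inclusion probabilities")
  }
  if (any(p <= 0 | p > 1)) stop("habitual inclusion probabilities must be in (0, 1]")
  if (novelty_rate < 0) stop("novelty_rate must be >= 0")
  if (novelty_rate > novelty_vocab_size) {
    stop("novelty_rate cannot exceed the novelty vocabulary size")
  }
  if (n_days < 1) stop("n_days must be >= 1")
  if (missing_day_prob < 0 || missing_day_prob >= 1) {
    stop("missing_day_prob must be in [0, 1)")
  }
  if (length(habitual_items) == 0 && novelty_rate == 0) {
    stop("spec cannot produce non-empty meals: no habitual items and no novelty")
  }
  for (r in c(zero_cal_rate, high_cal_rate, placeholder_rate)) {
    if (r < 0 || r > 1) stop("artifact rates must be probabilities")
  }
  if (weekend_multiplier < 0) stop("weekend_multiplier must be >= 0")
  structure(
    list(habitual_items = habitual_items,
         novelty_vocab_size = as.integer(novelty_vocab_size),
         novelty_rate = novelty_rate, n_days = as.integer(n_days),
         missing_day_prob = missing_day_prob,
         weekend_multiplier = weekend_multiplier,
         occasions = tolower(occasions),
         zero_cal_rate = zero_cal_rate, high_cal_rate = high_cal_rate,
         placeholder_rate = placeholder_rate,
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "habit_spec"
  )
}

#' Generate a synthetic food diary with ground truth
#'
#' Draws a diary according to a [habit_spec()]. Every meal is guaranteed
#' non-empty (empty draws are redrawn). Item text carries a comma-separated
#' serving-size suffix, and per-entry calories are log-normal, so the
#' generated diary exercises the same preprocessing path as real app
#' exports. The returned ground truth records the true habitual item set
#' and the exact per-(date, occasion) meal composition before artifact
#' injection, for parameter-recovery studies.
#'
#' @param spec A [habit_spec()].
#' @return List with `entries` (diary data.frame as from [read_diary()])
#'   and `truth`: list with `habitual_items` (named probability vector),
#'   `dates` (recorded calendar days) and `meals` (data.frame: `date`,
#'   `occasion`, `items` list-column of true item names).
#' @examples
#' d <- generate_diary(habit_spec(n_days = 14, occasions = "breakfast"))
#' head(d$entries)
#' @export
generate_diary <- function(spec) {
  stopifnot(inherits(spec, "habit_spec"))
  with_seed(spec$seed, {
    all_dates <- spec$start_date + 0:(spec$n_days - 1)
    recorded <- all_dates[stats::runif(spec$n_days) >= spec$missing_day_prob]
    if (length(recorded) == 0L) recorded <- all_dates[1]  # keep >= 1 day
    p_items <- spec$habitual_items
    n_meals <- length(recorded) * length(spec$occasions)
    truth_items <- vector("list", n_meals)
    truth_date <- rep(recorded[1], n_meals)
    truth_occ <- character(n_meals)
    e_text <- e_items <- vector("list", n_meals)
    e_cal <- vector("list", n_meals)
    e_len <- integer(n_meals)
    k_meal <- 0L
    for (d in seq_along(recorded)) {
      date <- recorded[d]
      p_day <- p_items
      if (is_weekend(date)) {
        p_day[] <- pmin(p_day * spec$weekend_multiplier, 1)
      }
      for (o in spec$occasions) {
        repeat {
          habitual <- names(p_day)[stats::runif(length(p_day)) < p_day]
          k <- min(stats::rpois(1, spec$novelty_rate), spec$novelty_vocab_size)
          novel <- if (k > 0) {
            paste0("novel food ",
                   sample.int(spec$novelty_vocab_size, k, replace = FALSE))
          } else character(0)
          items <- c(habitual, novel)
          if (length(items) > 0) break
        }
        k_meal <- k_meal + 1L
        truth_items[[k_meal]] <- sort(items)
        truth_date[k_meal] <- date
        truth_occ[k_meal] <- o
        cal <- stats::rlnorm(length(items), meanlog = log(150), sdlog = 0.5)
        item_text <- paste0(items, ", 1 serving")
        if (stats::runif(1) < spec$zero_cal_rate) {
          item_text <- c(item_text, "water, 1 cup")
          cal <- c(cal, 0)
        }
        if (stats::runif(1) < spec$high_cal_rate) {
          item_text <- c(item_text, "calorie bomb, 1 serving")
          cal <- c(cal, 3500)
        }
        if (stats::runif(1) < spec$placeholder_rate) {
          item_text <- c(item_text, "quick added calories")
          cal <- c(cal, 400)
        }
        e_text[[k_meal]] <- item_text
        e_cal[[k_meal]] <- round(cal, 1)
        e_len[k_meal] <- length(item_text)
      }
    }
    entries <- data.frame(
      individual_id = "sim",
      date = rep(truth_date, e_len),
      occasion = rep(truth_occ, e_len),
      item_text = unlist(e_text, use.names = FALSE),
      calories = unlist(e_cal, use.names = FALSE),
      stringsAsFactors = FALSE)
    truth <- data.frame(date = truth_date, occasion = truth_occ,
                        stringsAsFactors = FALSE)
    truth$items <- truth_items
    list(entries = entries,
         truth = list(habitual_items = spec$habitual_items,
                      dates = recorded, meals = truth))
  })
}

#' Sequences straight from a synthetic diary's ground truth
#'
#' Bypasses preprocessing (the truth has no artifacts and its item names are
#' already normalized) and builds one [consumption_sequence()] per occasion
#' directly from the generator's per-day composition. Useful for studies of
#' the recurrence measures themselves, where the preprocessing path is not
#' under test.
#'
#' @param diary A [generate_diary()] result.
#' @return List of [consumption_sequence()] objects, one per occasion.
#' @export
truth_sequences <- function(diary) {
  tr <- diary$truth$meals
  lapply(unique(tr$occasion), function(o) {
    sub <- tr[tr$occasion == o, , drop = FALSE]
    consumption_sequence("sim", o, sub$date, sub$items)
  })
}

#' Asymptotic expected food-item recurrence strength of a habit spec
#'
#' When every habitual item is detected as recurrent and novelty items are
#' not (vocabulary much larger than the observation window), the expected
#' fraction of days whose meal contains a habitual item is, with
#' `q = prod(1 - p_i)` the all-miss probability and `lambda` the novelty
#' rate,
#' \deqn{E[\alpha] = \frac{1 - q}{1 - q\,e^{-\lambda}}.}
#' The denominator accounts for the generator redrawing empty meals until
#' non-empty, which conditions every meal on being non-empty; when empty
#' draws are rare (`q e^{-lambda}` near 0) this reduces to the unconditional
#' `1 - prod(1 - p_i)`.
#'
#' @param spec A [habit_spec()].
#' @return Fraction in \[0, 1\].
#' @examples
#' # redraws never occur when some p_i = 1:
#' expected_alpha(habit_spec(habitual_items = c(a = 1)))  # 1
#' # ample novelty makes empty draws negligible:
#' expected_alpha(habit_spec(habitual_items = c(a = 0.5, b = 0.5),
#'                           novelty_rate = 12))  # ~0.75
#' @export
expected_alpha <- function(spec) {
  stopifnot(inherits(spec, "habit_spec"))
  q <- prod(1 - unname(spec$habitual_items))
  (1 - q) / (1 - q * exp(-spec$novelty_rate))
}
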