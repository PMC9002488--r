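#' Recurrence thresholds
#'
#' A food choice (item or meal) is recurrent when it is both repeated often
#' enough and spread across enough of the observation window. The frequency
#' threshold of 1/7 per recorded day reflects roughly weekly repetition
#' (groceries are typically bought weekly); the span threshold of 1/2
#' excludes choices repeated intensely within one stretch but absent from
#' the rest of the record.
#'
#' @param min_relative_frequency Minimum occurrences per recorded day
#'   (fraction in (0, 1]; default `1/7`).
#' @param min_span Minimum spread of first-to-last occurrence as a fraction
#'   of the sequence length (in (0, 1]; default `1/2`).
#' @param strict If `TRUE`, use strict (`>`) comparisons instead of the
#'   default inclusive (`>=`) ones.
#' @return An object of class `recurrence_thresholds`.
#' @export
recurrence_thresholds <- function(min_relative_frequency = 1 / 7,
                                  min_span = 1 / 2, strict = FALSE) {
  stopifnot(min_relative_frequency > 0, min_relative_frequency <= 1,
            min_span > 0, min_span <= 1, is.logical(strict))
  structure(list(min_relative_frequency = min_relative_frequency,
                 min_span = min_span, strict = strict),
            class = "recurrence_thresholds")
}

#' Occurrence days of a food-item or meal in a sequence
#'
#' For an item, the days whose meal contains it; for a meal, the days whose
#' meal equals it as a set.
#'
#' @param seq A [consumption_sequence()].
#' @param choice A single item name (`type = "item"`) or a character vector
#'   of item names treated as a meal (`type = "meal"`).
#' @param type `"item"` or `"meal"`.
#' @return An object of class `occurrence_set`: list with `choice`, `days`
#'   (integer vector of 1-based sequence indices) and `frequency`
#'   (`length(days)`; 0 when the choice never occurs).
#' @examples
#' s <- consumption_sequence("u", "breakfast", as.Date("2020-01-01") + 0:2,
#'                           list(c("latte", "muffin"), "latte", "latte"))
#' occurrence_days(s, "latte")$frequency
#' occurrence_days(s, c("latte", "muffin"), type = "meal")$days
#' @export
occurrence_days <- function(seq, choice, type = c("item", "meal")) {
  type <- match.arg(type)
  stopifnot(inherits(seq, "consumption_sequence"))
  if (type == "item") {
    stopifnot(length(choice) == 1L)
    days <- which(vapply(seq$meals, function(m) choice %in% m, logical(1)))
  } else {
    key <- meal_key(sort(unique(as.character(choice))))
    days <- which(meal_keys(seq$meals) == key)
  }
  structure(list(choice = choice, days = as.integer(days),
                 frequency = length(days)),
            class = "occurrence_set")
}

#' Relative frequency of a choice
#'
#' Occurrences divided by sequence length: a per-recorded-day consumption
#' rate in \[0, 1\]. An individual who eats cereal on every recorded day has
#' relative frequency 1 for cereal.
#'
#' @param occ An [occurrence_days()] result.
#' @param n_u Sequence length (must be >= 1).
#' @return Fraction in \[0, 1\].
#' @export
relative_frequency <- function(occ, n_u) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (n_u < 1) stop("relative frequency is undefined for n_u < 1")
  occ$frequency / n_u
}

#' Span of a choice
#'
#' Difference between the last and first occurrence day (sequence indices),
#' normalized by the sequence length: the fraction of the observation window
#' across which the choice was selected. A single occurrence has span 0.
#'
#' @inheritParams relative_frequency
#' @return Fraction in \[0, 1).
#' @export
span <- function(occ, n_u) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (occ$frequency < 1) stop("span is undefined for a choice that never occurs")
  if (n_u < 1) stop("span is undefined for n_u < 1")
  (max(occ$days) - min(occ$days)) / n_u
}

# frequency / first / last occurrence per distinct item and per distinct meal
occurrence_stats <- function(seq) {
  n <- seq$n
  day_idx <- rep.int(seq_len(n), lengths(seq$meals))
  item <- unlist(seq$meals, use.names = FALSE)
  i_freq <- tapply(day_idx, item, length)
  i_first <- tapply(day_idx, item, min)
  i_last <- tapply(day_idx, item, max)
  keys <- meal_keys(seq$meals)
  m_freq <- tapply(seq_len(n), keys, length)
  m_first <- tapply(seq_len(n), keys, min)
  m_last <- tapply(seq_len(n), keys, max)
  list(items = data.frame(item = names(i_freq),
                          frequency = as.integer(i_freq),
                          first = as.integer(i_first),
                          last = as.integer(i_last),
                          stringsAsFactors = FALSE),
       meals = data.frame(key = names(m_freq),
                          frequency = as.integer(m_freq),
                          first = as.integer(m_first),
                          last = as.integer(m_last),
                          stringsAsFactors = FALSE))
}

recurrent_of <- function(stats_df, n, thresholds) {
  rf <- stats_df$frequency / n
  sp <- (stats_df$last - stats_df$first) / n
  if (thresholds$strict) {
    rf > thresholds$min_relative_frequency & sp > thresholds$min_span
  } else {
    rf >= thresholds$min_relative_frequency & sp >= thresholds$min_span
  }
}

#' Recurrent food-item set of a sequence
#'
#' Items whose relative frequency and span both meet the thresholds.
#'
#' @param seq A [consumption_sequence()].
#' @param thresholds A [recurrence_thresholds()].
#' @return Sorted character vector of recurrent item names (possibly empty).
#' @export
recurrent_items <- function(seq, thresholds = recurrence_thresholds()) {
  stopifnot(inherits(seq, "consumption_sequence"))
  st <- occurrence_stats(seq)
  sort(st$items$item[recurrent_of(st$items, seq$n, thresholds)])
}

#' Recurrent meal set of a sequence
#'
#' Meals (as exact sets of item names) whose relative frequency and span both
#' meet the thresholds.
#'
#' @inheritParams recurrent_items
#' @return List of character vectors (sorted item names), possibly empty.
#' @export
recurrent_meals <- function(seq, thresholds = recurrence_thresholds()) {
  stopifnot(inherits(seq, "consumption_sequence"))
  st <- occurrence_stats(seq)
  keys <- sort(st$meals$key[recurrent_of(st$meals, seq$n, thresholds)])
  lapply(keys, function(k) strsplit(k, "\x1f", fixed = TRUE)[[1]])
}

#' Recurrence strength tuple (alpha, beta, gamma)
#'
#' Three levels of habitual consumption for one sequence, given its
#' recurrent sets:
#' * `alpha` — fraction of days whose meal contains at least one recurrent
#'   food-item;
#' * `beta` — mean over days of the fraction of the day's meal items that
#'   are recurrent;
#' * `gamma` — fraction of days whose whole meal is a recurrent meal.
#'
#' The per-day form computed here is equivalent to the meal-library-weighted
#' sums (grouping identical meals by their frequency).
#'
#' @param seq A [consumption_sequence()].
#' @param rec_items Recurrent item set, as from [recurrent_items()].
#' @param rec_meals Recurrent meal set, as from [recurrent_meals()].
#' @return Named numeric vector `c(alpha =, beta =, gamma =)`, each in
#'   \[0, 1\] with `gamma <= beta <= alpha`.
#' @export
recurrence_strengths <- function(seq, rec_items, rec_meals) {
  stopifnot(inherits(seq, "consumption_sequence"))
  if (seq$n < 1) stop("recurrence strengths are undefined for an empty sequence")
  n_rec <- vapply(seq$meals, function(m) sum(m %in% rec_items), numeric(1))
  sizes <- lengths(seq$meals)
  rec_meal_keys <- vapply(rec_meals, function(m) meal_key(sort(unique(m))),
                          character(1))
  is_rec_meal <- meal_keys(seq$meals) %in% rec_meal_keys
  c(alpha = mean(n_rec >= 1),
    beta = mean(n_rec / sizes),
    gamma = mean(is_rec_meal))
}

#' Average number of food-items per meal
#'
#' @param seq A [consumption_sequence()].
#' @return Mean meal size over the sequence (>= 1).
#' @export
avg_items_per_meal <- function(seq) {
  stopifnot(inherits(seq, "consumption_sequence"))
  if (seq$n < 1) stop("undefined for an empty sequence")
  mean(lengths(seq$meals))
}

#' Recurrence profile of a consumption sequence
#'
#' Computes the full habitual-behavior summary for one (individual,
#' occasion): the food-item and meal libraries, the recurrent item and meal
#' sets, the recurrence strength tuple and the average meal size.
#'
#' @inheritParams recurrent_items
#' @return An object of class `recurrence_profile`: list with
#'   `individual_id`, `occasion`, `n`, `food_item_library`, `meal_library`,
#'   `recurrent_items`, `recurrent_meals`, `alpha`, `beta`, `gamma`,
#'   `avg_items_per_meal`.
#' @examples
#' s <- consumption_sequence("u", "breakfast", as.Date("2020-01-01") + 0:13,
#'                           rep(list(c("latte", "muffin")), 14))
#' recurrence_profile(s)$gamma
#' @export
recurrence_profile <- function(seq, thresholds = recurrence_thresholds()) {
  stopifnot(inherits(seq, "consumption_sequence"))
  st <- occurrence_stats(seq)
  ritems <- sort(st$items$item[recurrent_of(st$items, seq$n, thresholds)])
  rkeys <- sort(st$meals$key[recurrent_of(st$meals, seq$n, thresholds)])
  rmeals <- lapply(rkeys, function(k) strsplit(k, "\x1f", fixed = TRUE)[[1]])
  strengths <- recurrence_strengths(seq, ritems, rmeals)
  structure(
    list(individual_id = seq$individual_id, occasion = seq$occasion,
         n = seq$n,
         food_item_library = sort(st$items$item),
         meal_library = lapply(sort(st$meals$key),
                               function(k) strsplit(k, "\x1f", fixed = TRUE)[[1]]),
         recurrent_items = ritems, recurrent_meals = rmeals,
         alpha = unname(strengths["alpha"]),
         beta = unname(strengths["beta"]),
         gamma = unname(strengths["gamma"]),
         avg_items_per_meal = avg_items_per_meal(seq)),
    class = "recurrence_profile"
  )
}

#' @export
print.recurrence_profile <- function(x, ...) {
  cat(sprintf(
    "<recurrence_profile> %s / %s (n = %d)\n  recurrent items: %s\n  recurrent meals: %d\n  (alpha, beta, gamma) = (%.2f, %.2f, %.2f)\n",
    x$individual_id, x$occasion, x$n,
    if (length(x$recurrent_items)) paste(x$recurrent_items, collapse = ", ")
    else "(none)",
    length(x$recurrent_meals), x$alpha, x$beta, x$gamma))
  invisible(x)
}
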