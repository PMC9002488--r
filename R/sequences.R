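#' Consumption sequence for one individual and meal occasion
#'
#' An ordered sequence of meals `[m_t], t = 1..n`, one per recorded day, for a
#' single (individual, occasion) pair. A meal is a set of distinct normalized
#' food-item names; `t` is the 1-based sequence index, not a calendar offset —
#' recorded days need not be consecutive, and all recurrence measures are
#' expressed in recorded-day units.
#'
#' @param individual_id Opaque individual identifier.
#' @param occasion Meal occasion label (e.g. `"breakfast"`).
#' @param dates Vector of calendar dates (`Date` or coercible), one per meal;
#'   must be distinct. Meals are reordered so dates are strictly increasing.
#' @param meals List of character vectors of food-item names; each meal must
#'   be non-empty. Duplicate items within a meal collapse (set semantics).
#'
#' @return An object of class `consumption_sequence`: a list with elements
#'   `individual_id`, `occasion`, `dates`, `meals`, and `n` (sequence length).
#' @examples
#' s <- consumption_sequence("u1", "breakfast",
#'                           as.Date("2020-01-01") + c(0, 2, 3),
#'                           list("latte", c("latte", "muffin"), "latte"))
#' s$n
#' @export
consumption_sequence <- function(individual_id, occasion, dates, meals) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("all dates must parse to valid calendar dates")
  if (length(dates) != length(meals)) {
    stop("`dates` and `meals` must have equal length")
  }
  if (length(meals) == 0L) stop("a consumption sequence must have >= 1 day")
  if (anyDuplicated(dates)) stop("dates must be distinct within a sequence")
  ord <- order(dates)
  dates <- dates[ord]
  meals <- lapply(meals[ord], function(m) sort(unique(as.character(m))))
  if (any(lengths(meals) == 0L)) stop("every meal must be non-empty")
  structure(
    list(individual_id = as.character(individual_id),
         occasion = as.character(occasion),
         dates = dates, meals = meals, n = length(meals)),
    class = "consumption_sequence"
  )
}

#' @export
print.consumption_sequence <- function(x, ...) {
  cat(sprintf("<consumption_sequence> individual %s, %s: %d day(s), %s .. %s\n",
              x$individual_id, x$occasion, x$n,
              format(x$dates[1]), format(x$dates[x$n])))
  invisible(x)
}

#' @export
length.consumption_sequence <- function(x) x$n

# canonical single-string key for a meal (items are sorted on construction)
meal_key <- function(meal) paste(meal, collapse = "\x1f")

meal_keys <- function(meals) vapply(meals, meal_key, character(1))
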