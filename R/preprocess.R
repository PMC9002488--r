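#' Preprocessing configuration
#'
#' Bundles the quality-filter settings used to turn raw diary entries into
#' clean consumption sequences.
#'
#' @param max_meal_kcal Meals whose summed calories exceed this are removed
#'   as logging errors (kcal; default 3000).
#' @param default_occasions Canonical occasion labels; individuals using any
#'   other label are excluded so that occasions can be compared within
#'   individuals.
#' @param max_mean_gap_days Consistency rule: an individual is kept only if
#'   the mean number of missing days between consecutive complete days is at
#'   most this (default 3, less than half a week).
#' @param min_sequence_length Minimum number of complete days required for a
#'   reliable recurrence measurement (default 28).
#' @param placeholder_token Normalized item name marking non-descriptive
#'   placeholder entries; meals containing one are removed entirely.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_meal_kcal = 3000,
                              default_occasions = c("breakfast", "lunch",
                                                    "dinner", "snacks"),
                              max_mean_gap_days = 3,
                              min_sequence_length = 28L,
                              placeholder_token = "quick added calories") {
  stopifnot(max_meal_kcal > 0, min_sequence_length >= 1,
            max_mean_gap_days >= 0, length(default_occasions) >= 1)
  structure(
    list(max_meal_kcal = max_meal_kcal,
         default_occasions = tolower(trimws(default_occasions)),
         max_mean_gap_days = max_mean_gap_days,
         min_sequence_length = as.integer(min_sequence_length),
         placeholder_token = placeholder_token),
    class = "preprocess_config"
  )
}

#' Strip the serving-size suffix from a food-item description
#'
#' App exports append the serving size to the item name, separated by a
#' comma (`"Latte, 12 oz"`). The text after the final comma is removed —
#' the serving size is a suffix, so names that themselves contain commas
#' keep their prefix commas — and the result is trimmed and lower-cased.
#' A string with no comma is returned whole (normalized). An entry that is
#' empty after stripping yields `NA`, flagging the row as invalid.
#'
#' @param item_text Character vector of raw item descriptions.
#' @return Character vector of normalized food-item names (`NA` where the
#'   name is empty after stripping).
#' @examples
#' strip_serving_size(c("Latte, 12 oz", "muffin", "Chicken, grilled, 3 oz"))
#' @export
strip_serving_size <- function(item_text) {
  out <- sub(",[^,]*$", "", as.character(item_text))
  out <- tolower(trimws(out))
  out[!nzchar(out)] <- NA_character_
  out
}

#' Apply entry-level quality filters to diary entries
#'
#' Three rules, applied in this order so that calorie-based meal removal sees
#' the original meal composition (a meal is the group of entries sharing one
#' (individual, date, occasion)):
#'
#' 1. meals containing a placeholder entry ("quick added calories") are
#'    removed entirely — they carry no food-item information;
#' 2. meals whose summed calories exceed `max_meal_kcal` are removed entirely
#'    as presumed logging errors;
#' 3. within surviving meals, zero-calorie entries (water, medications,
#'    supplements) are removed.
#'
#' Entries whose name is empty after serving-size stripping are dropped
#' first as invalid. Audit counts partition the input rows exactly.
#'
#' @param entries Data.frame of diary entries from [read_diary()].
#' @param cfg A [preprocess_config()].
#' @return List with `entries` (surviving rows plus a normalized `item`
#'   column) and `audit` (named integer vector of per-rule removal counts).
#' @export
filter_entries <- function(entries, cfg = preprocess_config()) {
  n_in <- nrow(entries)
  entries$item <- strip_serving_size(entries$item_text)
  audit <- c(rows_in = n_in, invalid_name = 0L, placeholder_meal = 0L,
             high_kcal_meal = 0L, zero_kcal_entry = 0L, rows_out = 0L)

  bad_name <- is.na(entries$item)
  audit[["invalid_name"]] <- sum(bad_name)
  entries <- entries[!bad_name, , drop = FALSE]

  grp <- paste(entries$individual_id, format(entries$date), entries$occasion,
               sep = "\x1f")
  # normalized whole-entry name equal to the placeholder marks the meal
  has_placeholder <- entries$item == cfg$placeholder_token
  bad_grp <- unique(grp[has_placeholder])
  drop <- grp %in% bad_grp
  audit[["placeholder_meal"]] <- sum(drop)
  entries <- entries[!drop, , drop = FALSE]
  grp <- grp[!drop]

  if (nrow(entries) > 0L) {
    totals <- tapply(entries$calories, grp, sum)
    bad_grp <- names(totals)[totals > cfg$max_meal_kcal]
    drop <- grp %in% bad_grp
  } else {
    drop <- logical(0)
  }
  audit[["high_kcal_meal"]] <- sum(drop)
  entries <- entries[!drop, , drop = FALSE]

  drop <- entries$calories == 0
  audit[["zero_kcal_entry"]] <- sum(drop)
  entries <- entries[!drop, , drop = FALSE]

  audit[["rows_out"]] <- nrow(entries)
  rownames(entries) <- NULL
  list(entries = entries, audit = audit)
}

#' Restrict to individuals who use only the default occasion labels
#'
#' Occasion comparisons require a common label set, so individuals who used
#' any custom meal-occasion label are excluded wholly. Matching is
#' case-insensitive after trimming; labels are normalized to lower case in
#' the result.
#'
#' @inheritParams filter_entries
#' @return The entries of conforming individuals, with `occasion` normalized.
#' @export
retain_default_label_users <- function(entries, cfg = preprocess_config()) {
  entries$occasion <- tolower(trimws(entries$occasion))
  bad <- !(entries$occasion %in% cfg$default_occasions)
  bad_users <- unique(entries$individual_id[bad])
  out <- entries[!(entries$individual_id %in% bad_users), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-(individual, occasion) consumption sequences
#'
#' Only complete days — days on which every default occasion has at least one
#' surviving entry — are kept, so the four sequences of an individual share
#' the same days and have equal length. Each kept day contributes one meal
#' per occasion: the set of distinct normalized item names logged under it.
#' Missing meals are never imputed; incomplete days are simply excluded.
#'
#' @param entries Filtered, label-restricted entries (must carry the `item`
#'   column added by [filter_entries()]).
#' @inheritParams filter_entries
#' @return List of [consumption_sequence()] objects, one per retained
#'   (individual, occasion); individuals with zero complete days contribute
#'   none.
#' @export
build_sequences <- function(entries, cfg = preprocess_config()) {
  if (is.null(entries$item)) {
    stop("entries must carry the normalized `item` column; run filter_entries() first")
  }
  occasions <- cfg$default_occasions
  out <- list()
  for (u in unique(entries$individual_id)) {
    e <- entries[entries$individual_id == u, , drop = FALSE]
    day_occ <- unique(data.frame(date = e$date, occasion = e$occasion))
    occ_per_day <- tapply(day_occ$occasion, format(day_occ$date),
                          function(o) length(unique(o)))
    complete <- as.Date(names(occ_per_day)[occ_per_day == length(occasions)])
    if (length(complete) == 0L) next
    complete <- sort(complete)
    e <- e[e$date %in% complete, , drop = FALSE]
    for (o in occasions) {
      eo <- e[e$occasion == o, , drop = FALSE]
      meals <- lapply(complete, function(d) unique(eo$item[eo$date == d]))
      out[[length(out) + 1L]] <-
        consumption_sequence(u, o, complete, meals)
    }
  }
  out
}

#' Retain individuals with long, consistently recorded sequences
#'
#' An individual is kept iff (i) the mean number of missing days between
#' consecutive complete days — calendar gap minus one — is at most
#' `max_mean_gap_days`, and (ii) the sequence length satisfies
#' `n >= min_sequence_length`. An individual with a single complete day has
#' an undefined mean gap and is excluded by the length rule.
#'
#' @param sequences List of [consumption_sequence()] objects (all occasions
#'   of one individual share the same days).
#' @inheritParams filter_entries
#' @return The retained subset of `sequences`.
#' @export
consistency_filter <- function(sequences, cfg = preprocess_config()) {
  if (length(sequences) == 0L) return(sequences)
  ids <- vapply(sequences, function(s) s$individual_id, character(1))
  keep_user <- vapply(unique(ids), function(u) {
    s <- sequences[[match(u, ids)]]
    if (s$n < cfg$min_sequence_length) return(FALSE)
    gaps <- as.numeric(diff(s$dates)) - 1
    if (length(gaps) == 0L) return(TRUE)  # single day: no gap defined
    mean(gaps) <= cfg$max_mean_gap_days
  }, logical(1))
  sequences[ids %in% unique(ids)[keep_user]]
}

#' Full diary preprocessing chain
#'
#' Runs [filter_entries()], [retain_default_label_users()],
#' [build_sequences()] and [consistency_filter()] in order and collects a
#' cohort funnel: entry-level audit counts plus the number of individuals
#' surviving each stage.
#'
#' @inheritParams filter_entries
#' @return List with `sequences` (retained [consumption_sequence()]s),
#'   `entries` (filtered, label-restricted entries — the pre-completeness
#'   rows used for recorded-day counts) and `funnel` (named counts).
#' @export
preprocess_diary <- function(entries, cfg = preprocess_config()) {
  filt <- filter_entries(entries, cfg)
  lab <- retain_default_label_users(filt$entries, cfg)
  seqs <- build_sequences(lab, cfg)
  kept <- consistency_filter(seqs, cfg)
  funnel <- c(
    filt$audit,
    individuals_in = length(unique(entries$individual_id)),
    individuals_default_labels = length(unique(lab$individual_id)),
    individuals_with_complete_days =
      length(unique(vapply(seqs, function(s) s$individual_id, character(1)))),
    individuals_retained =
      length(unique(vapply(kept, function(s) s$individual_id, character(1))))
  )
  list(sequences = kept, entries = lab, funnel = funnel)
}
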