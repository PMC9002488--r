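#' Read a food-diary log
#'
#' Reads raw diary entries from delimited text. Each row is one logged food
#' entry: who logged it, on what date, at which meal occasion, the free-text
#' item description (food name plus an optional comma-separated serving-size
#' suffix), and its calorie value. No filtering happens here: rows come back
#' in file order, one entry per row, so preprocessing filters can report
#' exact audit counts.
#'
#' @param path Path to the input file.
#' @param dialect `"csv"` (header `individual_id,date,occasion,item_text,calories`)
#'   or `"jsonl"` (one JSON object per line with the same keys).
#' @return A data.frame with columns `individual_id` (character), `date`
#'   (`Date`), `occasion` (character), `item_text` (character) and `calories`
#'   (numeric, kcal). Extra input columns are dropped with a warning.
#' @seealso [write_diary()], [preprocess_diary()]
#' @export
read_diary <- function(path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  required <- c("individual_id", "date", "occasion", "item_text", "calories")
  if (dialect == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, strip.white = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      raw <- data.frame(individual_id = character(), date = character(),
                        occasion = character(), item_text = character(),
                        calories = character())
    } else {
      recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
      cols <- unique(unlist(lapply(recs, names)))
      raw <- as.data.frame(
        lapply(stats::setNames(cols, cols), function(k)
          vapply(recs, function(r) {
            v <- r[[k]]
            if (is.null(v)) NA_character_ else as.character(v)
          }, character(1))),
        stringsAsFactors = FALSE
      )
    }
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("diary input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0L) {
    warning("ignoring extra diary column(s): ", paste(extra, collapse = ", "))
  }
  n <- nrow(raw)
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date) & n > 0)
  if (length(bad_date) > 0L) {
    stop("unparseable date in diary row(s): ",
         paste(utils::head(bad_date, 5L), collapse = ", "))
  }
  calories <- suppressWarnings(as.numeric(raw$calories))
  bad_cal <- which(is.na(calories))
  if (length(bad_cal) > 0L) {
    stop("unparseable calories in diary row(s): ",
         paste(utils::head(bad_cal, 5L), collapse = ", "))
  }
  if (any(calories < 0)) {
    stop("negative calories in diary row(s): ",
         paste(utils::head(which(calories < 0), 5L), collapse = ", "))
  }
  data.frame(individual_id = raw$individual_id, date = date,
             occasion = raw$occasion, item_text = raw$item_text,
             calories = calories, stringsAsFactors = FALSE)
}

#' Write a food-diary log
#'
#' Inverse of [read_diary()]: serializes entries so that a read-back
#' reproduces them. Dates are written ISO-8601; occasion labels verbatim.
#'
#' @param entries Data.frame of diary entries as returned by [read_diary()].
#' @param path Output path.
#' @inheritParams read_diary
#' @return `path`, invisibly.
#' @export
write_diary <- function(entries, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  out <- data.frame(individual_id = as.character(entries$individual_id),
                    date = format(as.Date(entries$date), "%Y-%m-%d"),
                    occasion = as.character(entries$occasion),
                    item_text = as.character(entries$item_text),
                    calories = entries$calories,
                    stringsAsFactors = FALSE)
  if (dialect == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write recurrence profiles as JSON-lines
#'
#' One JSON record per (individual, occasion) profile, holding the food-item
#' and meal libraries, the recurrent sets, the recurrence strength tuple and
#' the average number of items per meal. Strengths are stored at full
#' precision so that [read_profiles()] reproduces them exactly.
#'
#' @param profiles List of [recurrence_profile()] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  lines <- vapply(profiles, function(p) {
    jsonlite::toJSON(list(
      individual_id = p$individual_id, occasion = p$occasion, n = p$n,
      alpha = p$alpha, beta = p$beta, gamma = p$gamma,
      avg_items_per_meal = p$avg_items_per_meal,
      food_item_library = as.list(p$food_item_library),
      meal_library = lapply(p$meal_library, as.list),
      recurrent_items = as.list(p$recurrent_items),
      recurrent_meals = lapply(p$recurrent_meals, as.list)
    ), auto_unbox = TRUE, digits = I(17))  # 17 sig. digits: doubles round-trip
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read recurrence profiles written by [write_profiles()]
#'
#' @param path Path to a JSON-lines profile file.
#' @return List of `recurrence_profile` objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    as_chr_sets <- function(x) lapply(x, function(m) sort(unlist(m, use.names = FALSE)))
    structure(
      list(individual_id = r$individual_id, occasion = r$occasion,
           n = as.integer(r$n),
           food_item_library = sort(unlist(r$food_item_library, use.names = FALSE)),
           meal_library = as_chr_sets(r$meal_library),
           recurrent_items = sort(as.character(unlist(r$recurrent_items, use.names = FALSE))),
           recurrent_meals = as_chr_sets(r$recurrent_meals),
           alpha = as.numeric(r$alpha), beta = as.numeric(r$beta),
           gamma = as.numeric(r$gamma),
           avg_items_per_meal = as.numeric(r$avg_items_per_meal)),
      class = "recurrence_profile")
  })
}

#' Write consumption sequences as JSON-lines
#'
#' @param sequences List of [consumption_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  lines <- vapply(sequences, function(s) {
    jsonlite::toJSON(list(
      individual_id = s$individual_id, occasion = s$occasion,
      dates = format(s$dates, "%Y-%m-%d"),
      meals = lapply(s$meals, as.list)
    ), auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read consumption sequences written by [write_sequences()]
#'
#' @param path Path to a JSON-lines sequence file.
#' @return List of `consumption_sequence` objects.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("sequence file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    consumption_sequence(
      r$individual_id, r$occasion,
      as.Date(unlist(r$dates, use.names = FALSE)),
      lapply(r$meals, function(m) unlist(m, use.names = FALSE)))
  })
}
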