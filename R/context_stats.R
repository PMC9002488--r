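#' Cohort table of recurrence measures
#'
#' One row per (individual, occasion) with the recurrence strength tuple,
#' the average meal size, the sequence length, the number of recorded days
#' (days with at least one occasion entry, before the complete-day filter —
#' a proxy for logging engagement) and the number of weekend days in the
#' sequence.
#'
#' @param sequences List of [consumption_sequence()] objects.
#' @param thresholds A [recurrence_thresholds()].
#' @param entries Optional pre-completeness entries (as returned in
#'   `preprocess_diary()$entries`) used to count recorded days; when absent,
#'   `recorded_days` falls back to the sequence length.
#' @return Data.frame with columns `individual_id`, `occasion`, `alpha`,
#'   `beta`, `gamma`, `avg_items_per_meal`, `n`, `recorded_days`,
#'   `weekend_days`.
#' @export
cohort_table <- function(sequences, thresholds = recurrence_thresholds(),
                         entries = NULL) {
  if (length(sequences) == 0L) {
    return(data.frame(individual_id = character(), occasion = character(),
                      alpha = numeric(), beta = numeric(), gamma = numeric(),
                      avg_items_per_meal = numeric(), n = integer(),
                      recorded_days = integer(), weekend_days = integer()))
  }
  recorded <- NULL
  if (!is.null(entries)) {
    recorded <- tapply(format(entries$date), entries$individual_id,
                       function(d) length(unique(d)))
  }
  rows <- lapply(sequences, function(s) {
    p <- recurrence_profile(s, thresholds)
    rd <- if (is.null(recorded)) s$n else
      as.integer(recorded[[s$individual_id]])
    data.frame(individual_id = s$individual_id, occasion = s$occasion,
               alpha = p$alpha, beta = p$beta, gamma = p$gamma,
               avg_items_per_meal = p$avg_items_per_meal, n = s$n,
               recorded_days = rd,
               weekend_days = sum(is_weekend(s$dates)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Empirical cumulative distribution points
#'
#' Right-continuous ECDF evaluated at the sorted distinct values; the
#' cumulative fraction at the maximum is 1.
#'
#' @param values Numeric vector (length >= 1).
#' @return Data.frame with columns `value` and `fraction`.
#' @export
ecdf_points <- function(values) {
  if (length(values) == 0L) stop("ecdf of an empty sample is undefined")
  v <- sort(unique(values))
  data.frame(value = v, fraction = stats::ecdf(values)(v))
}

#' Pearson correlation with significance
#'
#' Product-moment correlation and its two-sided p-value. A zero-variance
#' input has no defined correlation and is reported as `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p_value` (both `NA` when undefined).
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Compare a recurrence strength across meal occasions
#'
#' Within-individual comparison of one strength measure across the four
#' occasions: a Friedman omnibus test on the individuals x occasions matrix,
#' Wilcoxon signed-rank tests for all pairwise post-hoc contrasts (raw
#' p-values by default, matching common reporting practice; `adjust =
#' "holm"` is available), and per-occasion mean/SD summaries. Individuals
#' missing any occasion are excluded with a warning.
#'
#' @param cohort A [cohort_table()].
#' @param measure One of `"alpha"`, `"beta"`, `"gamma"`.
#' @param adjust P-value adjustment for the pairwise tests (a method of
#'   [stats::p.adjust()]; default `"none"`).
#' @return An object of class `occasion_contrast`: list with `measure`,
#'   `n` (complete individuals), `omnibus` (statistic, df, p_value),
#'   `pairwise` (data.frame: `occasion_a`, `occasion_b`, `p_value`) and
#'   `summary` (data.frame: `occasion`, `mean`, `sd`).
#' @export
occasion_contrast <- function(cohort, measure = c("alpha", "beta", "gamma"),
                              adjust = "none") {
  measure <- match.arg(measure)
  occasions <- sort(unique(cohort$occasion))
  wide <- stats::reshape(
    cohort[, c("individual_id", "occasion", measure)],
    idvar = "individual_id", timevar = "occasion", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub(paste0("^", measure, "\\."), "", colnames(mat))
  mat <- mat[, occasions, drop = FALSE]
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    warning(sum(!complete), " individual(s) missing an occasion excluded")
    mat <- mat[complete, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("need >= 2 complete individuals")
  fr <- stats::friedman.test(mat)
  fr_stat <- unname(fr$statistic)
  fr_p <- fr$p.value
  if (!is.finite(fr_stat) || !is.finite(fr_p)) {
    # complete ties (e.g. identical columns) carry no evidence of a difference
    fr_stat <- 0
    fr_p <- 1
  }
  pairs <- utils::combn(occasions, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(mat[, pr[1]], mat[, pr[2]],
                                        paired = TRUE, exact = FALSE)$p.value)
  })
  pairwise <- data.frame(occasion_a = pairs[1, ], occasion_b = pairs[2, ],
                         p_value = stats::p.adjust(p_raw, method = adjust),
                         stringsAsFactors = FALSE)
  structure(
    list(measure = measure, n = nrow(mat),
         omnibus = list(statistic = fr_stat,
                        df = unname(fr$parameter), p_value = fr_p),
         pairwise = pairwise,
         summary = data.frame(occasion = occasions,
                              mean = apply(mat, 2, mean),
                              sd = apply(mat, 2, stats::sd),
                              row.names = NULL)),
    class = "occasion_contrast")
}

#' @export
print.occasion_contrast <- function(x, ...) {
  cat(sprintf("<occasion_contrast> %s across occasions (n = %d)\n",
              x$measure, x$n))
  cat(sprintf("  Friedman chi-squared = %.3f, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

is_weekend <- function(dates) format(as.Date(dates), "%u") %in% c("6", "7")

#' Split a consumption sequence into weekday and weekend parts
#'
#' Weekend days are Saturday and Sunday. Each part is re-indexed from its
#' own days (t = 1.. within the part), so recurrence profiles computed on a
#' part describe that context alone.
#'
#' @param seq A [consumption_sequence()].
#' @return List with elements `weekday` and `weekend`, each a
#'   [consumption_sequence()] or `NULL` when the part is empty.
#' @export
split_weekday_weekend <- function(seq) {
  stopifnot(inherits(seq, "consumption_sequence"))
  we <- is_weekend(seq$dates)
  part <- function(keep) {
    if (!any(keep)) return(NULL)
    consumption_sequence(seq$individual_id, seq$occasion,
                         seq$dates[keep], seq$meals[keep])
  }
  list(weekday = part(!we), weekend = part(we))
}

#' Restrict a cohort to individuals with enough weekend days
#'
#' Weekend logging is sparser than weekday logging, so weekend estimates
#' from individuals with few weekend days are noisy; they are excluded.
#'
#' @param cohort A [cohort_table()].
#' @param min_weekend_days Minimum weekend days required (default 14).
#' @return The qualifying rows of `cohort`.
#' @export
weekend_eligible <- function(cohort, min_weekend_days = 14L) {
  cohort[cohort$weekend_days >= min_weekend_days, , drop = FALSE]
}

#' Association between recurrence strength and logging engagement
#'
#' Pearson correlation, per occasion, between a strength measure and the
#' number of recorded days. An absence of association suggests the act of
#' logging does not itself drive recurrent consumption.
#'
#' @inheritParams occasion_contrast
#' @return Data.frame with columns `occasion`, `rho`, `p_value` (`NA` where
#'   the correlation is undefined).
#' @export
recorded_days_association <- function(cohort,
                                      measure = c("alpha", "beta", "gamma")) {
  measure <- match.arg(measure)
  occasions <- sort(unique(cohort$occasion))
  rows <- lapply(occasions, function(o) {
    sub <- cohort[cohort$occasion == o, , drop = FALSE]
    res <- tryCatch(
      suppressWarnings(pearson_cor(sub[[measure]], sub$recorded_days)),
      error = function(e) list(rho = NA_real_, p_value = NA_real_))
    data.frame(occasion = o, rho = res$rho, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Most frequent tokens in a set of food-item names
#'
#' Lower-cases the names, splits on whitespace, strips punctuation at token
#' boundaries and ranks tokens by how many names contain them (a name
#' contributes each of its tokens once per occurrence in the input). Ties
#' break alphabetically for determinism.
#'
#' @param item_names Character vector of food-item names, e.g. the union of
#'   recurrent item sets across individuals for one occasion.
#' @param k Number of top tokens to return (the full ranking when `k`
#'   exceeds the vocabulary).
#' @return Data.frame with columns `token` and `count`, at most `k` rows.
#' @export
top_tokens <- function(item_names, k = 50L) {
  if (length(item_names) == 0L) {
    return(data.frame(token = character(), count = integer()))
  }
  toks <- unlist(strsplit(tolower(item_names), "[[:space:]]+"))
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    return(data.frame(token = character(), count = integer()))
  }
  tab <- table(toks)
  df <- data.frame(token = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$token), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}
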