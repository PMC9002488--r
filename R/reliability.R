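#' Jaccard distance between two sets
#'
#' `1 - |A ∩ B| / |A ∪ B|`. Two empty sets are identical, so their distance
#' is 0. Meal sets (lists of character vectors) are compared by exact set
#' equality of their elements.
#'
#' @param a,b Sets: character vectors of items, or lists of character
#'   vectors (sets of meals).
#' @return Fraction in \[0, 1\].
#' @examples
#' jaccard_distance(c("a", "b"), c("b", "c"))  # 2/3
#' @export
jaccard_distance <- function(a, b) {
  as_keys <- function(x) {
    if (is.list(x)) {
      unique(vapply(x, function(m) meal_key(sort(unique(as.character(m)))),
                    character(1)))
    } else {
      unique(as.character(x))
    }
  }
  a <- as_keys(a)
  b <- as_keys(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

#' Truncate a consumption sequence to its first days
#'
#' Keeps the earliest `n_hat` recorded days, emulating a shorter observation
#' window that precedes the full record.
#'
#' @param seq A [consumption_sequence()].
#' @param n_hat Number of leading days to keep, `1 <= n_hat <= seq$n`.
#' @return A [consumption_sequence()] of length `n_hat`.
#' @export
truncate_sequence <- function(seq, n_hat) {
  stopifnot(inherits(seq, "consumption_sequence"))
  if (n_hat < 1 || n_hat > seq$n) {
    stop("n_hat must be between 1 and the sequence length (", seq$n, ")")
  }
  idx <- seq_len(n_hat)
  consumption_sequence(seq$individual_id, seq$occasion,
                       seq$dates[idx], seq$meals[idx])
}

#' Estimation error of a truncated-sequence profile against a baseline
#'
#' Combined error in the five recurrence measures, averaged over the three
#' strength levels. Each part multiplies a set-detection error (Jaccard
#' distance between the short-window and baseline recurrent sets) by the
#' absolute error in the corresponding strength:
#' \deqn{e = \frac{1}{3}\left[J_D\,|\Delta\alpha| + J_D\,|\Delta\beta|
#'       + J_M\,|\Delta\gamma|\right]}
#' where \eqn{J_D} is the Jaccard distance between recurrent item sets and
#' \eqn{J_M} between recurrent meal sets. Both factors of each part lie in
#' \[0, 1\], so the error does too; identical profiles give 0. Note the
#' multiplicative coupling makes a strength error invisible when the
#' recurrent sets agree exactly; `additive = TRUE` gives an alternative
#' `(J_D + |da| + |db| + J_M + |dg|)/5` form without that property (not the
#' published definition).
#'
#' @param profile_short [recurrence_profile()] from the truncated sequence.
#' @param profile_base [recurrence_profile()] from the baseline (longer)
#'   sequence; must be the same individual and occasion.
#' @param additive Use the additive variant (default `FALSE`).
#' @return Error in \[0, 1\].
#' @export
estimation_error <- function(profile_short, profile_base, additive = FALSE) {
  stopifnot(inherits(profile_short, "recurrence_profile"),
            inherits(profile_base, "recurrence_profile"))
  if (profile_short$individual_id != profile_base$individual_id ||
      profile_short$occasion != profile_base$occasion) {
    stop("profiles must belong to the same individual and occasion")
  }
  j_d <- jaccard_distance(profile_short$recurrent_items,
                          profile_base$recurrent_items)
  j_m <- jaccard_distance(profile_short$recurrent_meals,
                          profile_base$recurrent_meals)
  da <- abs(profile_short$alpha - profile_base$alpha)
  db <- abs(profile_short$beta - profile_base$beta)
  dg <- abs(profile_short$gamma - profile_base$gamma)
  if (additive) {
    (j_d + da + db + j_m + dg) / 5
  } else {
    (j_d * da + j_d * db + j_m * dg) / 3
  }
}

#' Estimation-error curves over truncated sequence lengths
#'
#' For every individual with a sequence of at least `baseline_length` days,
#' the recurrence profile of the first `baseline_length` days is taken as
#' the baseline estimate, profiles are recomputed on each truncated length
#' of the grid, and [estimation_error()] is evaluated against the baseline.
#' The cohort mean per grid point summarizes how reliability grows with the
#' number of recorded days.
#'
#' @param sequences List of [consumption_sequence()] objects.
#' @param baseline_length Days defining the baseline estimate (default 112).
#' @param grid Truncated lengths to evaluate (default `seq(14, 98, by = 14)`;
#'   `baseline_length` is always appended, where the error is 0 by
#'   construction).
#' @param thresholds A [recurrence_thresholds()].
#' @return List with `curves` (data.frame: `individual_id`, `occasion`,
#'   `n_hat`, `error`) and `summary` (data.frame: `n_hat`, `mean_error`,
#'   `n_profiles`). Both empty, with a warning, when no sequence is long
#'   enough.
#' @export
error_curve_cohort <- function(sequences, baseline_length = 112L,
                               grid = seq(14L, 98L, by = 14L),
                               thresholds = recurrence_thresholds()) {
  eligible <- Filter(function(s) s$n >= baseline_length, sequences)
  grid <- sort(unique(c(as.integer(grid), as.integer(baseline_length))))
  if (length(eligible) == 0L) {
    warning("no sequence reaches the baseline length of ", baseline_length,
            " days")
    empty <- data.frame(individual_id = character(), occasion = character(),
                        n_hat = integer(), error = numeric())
    return(list(curves = empty,
                summary = data.frame(n_hat = integer(), mean_error = numeric(),
                                     n_profiles = integer())))
  }
  curves <- do.call(rbind, lapply(eligible, function(s) {
    base <- recurrence_profile(truncate_sequence(s, baseline_length),
                               thresholds)
    errs <- vapply(grid, function(nh) {
      estimation_error(recurrence_profile(truncate_sequence(s, nh),
                                          thresholds), base)
    }, numeric(1))
    data.frame(individual_id = s$individual_id, occasion = s$occasion,
               n_hat = grid, error = errs, stringsAsFactors = FALSE)
  }))
  rownames(curves) <- NULL
  summary <- data.frame(
    n_hat = grid,
    mean_error = as.numeric(tapply(curves$error, curves$n_hat, mean)[as.character(grid)]),
    n_profiles = as.integer(tapply(curves$error, curves$n_hat, length)[as.character(grid)])
  )
  list(curves = curves, summary = summary)
}

#' Kaplan-Meier survival of consumption-sequence lengths
#'
#' Product-limit estimate of the fraction of individuals whose sequence
#' length exceeds each value. Lengths are fully observed (no censoring), so
#' the estimate equals one minus the empirical CDF; the Kaplan-Meier form is
#' used for comparability with standard survival summaries.
#'
#' @param lengths Integer vector of sequence lengths (each >= 1).
#' @return Data.frame with columns `length` (event times) and `survival`
#'   (surviving fraction just after each length).
#' @export
km_survival <- function(lengths) {
  if (length(lengths) == 0L) stop("no sequence lengths supplied")
  stopifnot(all(lengths >= 1))
  fit <- survival::survfit(survival::Surv(lengths, rep(1L, length(lengths))) ~ 1)
  data.frame(length = fit$time, survival = fit$surv)
}
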