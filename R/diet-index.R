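#' Energy-weighted Nutri-Score dietary index
#'
#' Computes, for every participant-visit, the individual dietary index:
#' the mean of the Nutri-Score of all consumed foods and beverages
#' weighted by their energy contribution,
#' \deqn{DI = \sum_i NS_i E_i / \sum_i E_i,}
#' where \eqn{E_i} is the daily energy intake (kcal/day) from item
#' \eqn{i}.  Higher values indicate poorer overall diet quality.  The
#' index is computed on raw (not energy-residual-adjusted) intakes: the
#' energy weighting is intrinsic to the definition, while the residual
#' method applies to nutrient and food covariates.
#'
#' @param intake_items Per-item intake rows (`$items` from
#'   [compute_daily_intakes()]): `participant_id`, `visit_time`,
#'   `item_id`, `energy_kcal_day`.
#' @param scores Item scores: either a data frame with `item_id` and
#'   `score` (e.g. from [score_foods()]) or a named numeric vector.
#' @return Data frame with one row per participant-visit:
#'   `participant_id`, `visit_time`, `di`, `total_energy_kcal`.
#' @examples
#' it <- data.frame(participant_id = 1, visit_time = 0,
#'                  item_id = c("a", "b"), energy_kcal_day = c(300, 100))
#' sc <- data.frame(item_id = c("a", "b"), score = c(2, 6))
#' compute_di(it, sc)$di  # 3
#' @export
compute_di <- function(intake_items, scores) {
  if (is.data.frame(scores)) {
    sc <- scores$score
    names(sc) <- scores$item_id
  } else sc <- scores
  s <- sc[as.character(intake_items$item_id)]
  consumed <- intake_items$energy_kcal_day > 0
  if (anyNA(s[consumed])) {
    bad <- unique(intake_items$item_id[consumed & is.na(s)])
    stop("no score for consumed item(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  s[is.na(s)] <- 0  # zero-energy items contribute nothing anyway
  key <- interaction(intake_items$participant_id,
                     intake_items$visit_time, drop = TRUE)
  e_tot <- rowsum(intake_items$energy_kcal_day, key, reorder = TRUE)[, 1]
  se_tot <- rowsum(intake_items$energy_kcal_day * s, key,
                   reorder = TRUE)[, 1]
  first <- !duplicated(key)
  ord <- order(as.integer(key[first]))
  out <- data.frame(
    participant_id = intake_items$participant_id[first][ord],
    visit_time = intake_items$visit_time[first][ord],
    di = se_tot / e_tot,
    total_energy_kcal = e_tot)
  rownames(out) <- NULL
  if (any(e_tot <= 0)) {
    bad <- out$participant_id[e_tot <= 0]
    stop("zero total energy for participant(s): ",
         paste(utils::head(unique(bad), 10), collapse = ", "),
         "; such participants should have been excluded")
  }
  out
}

#' Cumulative-average exposure series
#'
#' For each participant, replaces the per-visit dietary index by the
#' cumulative average of all values from baseline up to and including
#' each visit, damping within-person measurement noise; this is the
#' long-term exposure carried into the survival models.  A wholly missing
#' FFQ at a follow-up visit simply contributes no row, so the cumulative
#' average is carried forward unchanged.
#'
#' @param di_table Output of [compute_di()] (or any data frame with
#'   `participant_id`, `visit_time`, `di`).
#' @return The input with a `cum_avg_di` column appended, ordered by
#'   participant and visit time.
#' @export
exposure_series <- function(di_table) {
  ord <- order(di_table$participant_id, di_table$visit_time)
  x <- di_table[ord, , drop = FALSE]
  if (anyDuplicated(x[, c("participant_id", "visit_time")]))
    stop("duplicate participant-visit rows in the dietary index table")
  grp <- cumsum(!duplicated(x$participant_id))
  k <- stats::ave(x$di, grp, FUN = seq_along)
  x$cum_avg_di <- stats::ave(x$di, grp, FUN = cumsum) / k
  rownames(x) <- NULL
  x
}

#' Cumulative average of one participant's index series as of a time
#'
#' @param times Visit times (years since baseline), strictly increasing.
#' @param values Dietary index values at those times.
#' @param t As-of time; values with `visit_time <= t` enter the mean.
#' @return The cumulative-average exposure at time `t`.
#' @examples
#' cumulative_average(c(0, 1), c(2, 4), t = 1)    # 3
#' cumulative_average(c(0, 1), c(2, 4), t = 0.5)  # 2 (no lookahead)
#' @export
cumulative_average <- function(times, values, t) {
  if (length(times) != length(values) || !length(times))
    stop("times and values must be non-empty and aligned")
  if (is.unsorted(times, strictly = TRUE))
    stop("visit times must be strictly increasing")
  if (t < times[1])
    stop("as-of time ", t, " precedes the baseline visit at ", times[1])
  mean(values[times <= t])
}

#' Quintile assignment of a cohort exposure distribution
#'
#' Cut points are the 20/40/60/80th percentiles computed by linear
#' interpolation between order statistics (so they are reproducible
#' bit-for-bit); values exactly at a cut point go to the lower quintile.
#' The observed median exposure of each quintile is reported for use as
#' the pseudo-continuous trend variable.
#'
#' @param values Finite numeric exposure vector, `n >= 5` with at least 5
#'   distinct values.
#' @return A list of class `quintile_assignment`: `quintile` (integer
#'   1..5 per value), `cuts` (4 cut points), `medians` (5 observed
#'   medians) and `counts`.
#' @examples
#' q <- assign_quintiles(1:100)
#' q$medians  # 10.5 30.5 50.5 70.5 90.5
#' @export
assign_quintiles <- function(values) {
  if (any(!is.finite(values)))
    stop("exposure values must be finite")
  if (length(values) < 5 || length(unique(values)) < 5)
    stop("need at least 5 observations with 5 distinct values ",
         "to form quintiles")
  cuts <- stats::quantile(values, probs = c(0.2, 0.4, 0.6, 0.8),
                          type = 7, names = FALSE)
  q <- findInterval(values, cuts, left.open = TRUE) + 1L
  medians <- vapply(1:5, function(k) stats::median(values[q == k]),
                    numeric(1))
  structure(list(quintile = q, cuts = cuts, medians = medians,
                 counts = tabulate(q, 5)),
            class = "quintile_assignment")
}

#' @export
print.quintile_assignment <- function(x, ...) {
  cat("Quintile assignment\n  cuts:   ",
      paste(signif(x$cuts, 4), collapse = ", "),
      "\n  medians:", paste(signif(x$medians, 4), collapse = ", "),
      "\n  n:      ", paste(x$counts, collapse = ", "), "\n")
  invisible(x)
}
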