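# Servings/day assigned to the nine ordinal FFQ frequency levels
# ("never or almost never" ... "more than six times per day").  The
# instrument prints only the scale endpoints; the interior constants are
# the standard FFQ conventions, fixed here as configuration.
FFQ_FREQ_LEVELS <- c(never = 0, per_month_1_3 = 2 / 30, per_week_1 = 1 / 7,
                     per_week_2_4 = 3 / 7, per_week_5_6 = 5.5 / 7,
                     per_day_1 = 1, per_day_2_3 = 2.5, per_day_4_6 = 5,
                     per_day_gt6 = 7)

#' Convert an FFQ frequency level to servings per day
#'
#' The nine-level ordinal scale runs from "never or almost never"
#' (level 1, 0 servings/day) to "more than six times per day" (level 9).
#' The mapping is strictly increasing in the level.
#'
#' @param level Integer vector with values in 1..9.
#' @param mapping Servings/day for each level; defaults to the package's
#'   fixed constants.
#' @return Numeric servings per day.
#' @examples
#' frequency_to_daily(c(1, 6, 9))
#' @export
frequency_to_daily <- function(level, mapping = FFQ_FREQ_LEVELS) {
  if (any(is.na(level)) || any(level != as.integer(level)) ||
      any(level < 1 | level > length(mapping)))
    stop("frequency level must be an integer in 1..", length(mapping))
  unname(mapping[as.integer(level)])
}

#' Compute daily intakes from FFQ responses
#'
#' Converts long-format FFQ responses (participant x visit x item x
#' frequency level) into daily gram and nutrient intakes: grams/day =
#' servings/day x portion size, and each nutrient is grams/day x content
#' per 100 g / 100.  Items absent from a participant's responses count as
#' "never" (zero intake).
#'
#' @param responses Data frame with columns `participant_id`,
#'   `visit_time`, `item_id`, `freq_level`.
#' @param items Food/item table with `item_id`, `portion_g`,
#'   `energy_kcal`, `protein_g`, `totalfat_g`, `carb_g`, `fibre_g`,
#'   `alcohol_g` (contents per 100 g).
#' @return A list with `items`: per-row intakes (`grams_day`,
#'   `energy_kcal_day`), and `totals`: one row per participant-visit with
#'   total energy (kcal/day), protein, carbohydrate, fat, fibre and
#'   alcohol (g/day).
#' @examples
#' items <- data.frame(item_id = "x", portion_g = 100, energy_kcal = 200,
#'                     protein_g = 5, totalfat_g = 2, carb_g = 40,
#'                     fibre_g = 3, alcohol_g = 0)
#' resp <- data.frame(participant_id = 1, visit_time = 0, item_id = "x",
#'                    freq_level = 6)
#' compute_daily_intakes(resp, items)$totals
#' @export
compute_daily_intakes <- function(responses, items) {
  need <- c("participant_id", "visit_time", "item_id", "freq_level")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses are missing columns: ", paste(miss, collapse = ", "))
  idx <- match(responses$item_id, items$item_id)
  if (anyNA(idx)) {
    bad <- unique(responses$item_id[is.na(idx)])
    stop("unknown item_id(s) in responses: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  servings <- frequency_to_daily(responses$freq_level)
  grams <- servings * items$portion_g[idx]
  per_item <- data.frame(
    participant_id = responses$participant_id,
    visit_time = responses$visit_time,
    item_id = responses$item_id,
    grams_day = grams,
    energy_kcal_day = grams * items$energy_kcal[idx] / 100,
    stringsAsFactors = FALSE)
  key <- interaction(per_item$participant_id, per_item$visit_time,
                     drop = TRUE)
  sum_by <- function(x) rowsum(x, key, reorder = TRUE)[, 1]
  totals <- data.frame(
    energy_kcal = sum_by(per_item$energy_kcal_day),
    protein_g = sum_by(grams * items$protein_g[idx] / 100),
    carb_g = sum_by(grams * items$carb_g[idx] / 100),
    fat_g = sum_by(grams * items$totalfat_g[idx] / 100),
    fibre_g = sum_by(grams * items$fibre_g[idx] / 100),
    alcohol_g = sum_by(grams * items$alcohol_g[idx] / 100))
  first <- !duplicated(key)
  ord <- order(as.integer(key[first]))
  totals <- cbind(data.frame(
    participant_id = per_item$participant_id[first][ord],
    visit_time = per_item$visit_time[first][ord]), totals)
  rownames(totals) <- NULL
  list(items = per_item, totals = totals)
}

#' Apply the cohort exclusion filters
#'
#' Removes participants, in the documented order: (1) missing baseline
#' dietary data; (2) implausible energy intakes -- below 500 or at/above
#' 3500 kcal/day for women, below 800 or at/above 4000 kcal/day for men
#' (strict "<" on the low side, ">=" on the high side); (3) participants
#' without any follow-up.  Each participant is counted under the first
#' reason that applies.
#'
#' @param cohort Data frame with `participant_id`, `sex`
#'   (`"male"`/`"female"`) and `futime` (follow-up years).
#' @param baseline_totals Baseline intake totals (from
#'   [compute_daily_intakes()]) with `participant_id` and `energy_kcal`;
#'   participants absent from it count as missing dietary data.
#' @param limits Energy plausibility bounds per sex (kcal/day).
#' @return A list with `cohort` (retained rows) and `report`, a data frame
#'   of counts per reason plus the retained n.
#' @export
apply_exclusions <- function(cohort, baseline_totals,
                             limits = list(female = c(500, 3500),
                                           male = c(800, 4000))) {
  if (!all(cohort$sex %in% names(limits)))
    stop("sex must be one of: ", paste(names(limits), collapse = ", "))
  energy <- baseline_totals$energy_kcal[
    match(cohort$participant_id, baseline_totals$participant_id)]
  missing_diet <- is.na(energy)
  lo <- vapply(limits, `[`, numeric(1), 1)[cohort$sex]
  hi <- vapply(limits, `[`, numeric(1), 2)[cohort$sex]
  implausible <- !missing_diet & (energy < lo | energy >= hi)
  no_followup <- !missing_diet & !implausible &
    (is.na(cohort$futime) | cohort$futime <= 0)
  keep <- !missing_diet & !implausible & !no_followup
  report <- data.frame(
    reason = c("missing_dietary_data", "implausible_energy",
               "no_followup", "retained"),
    n = c(sum(missing_diet), sum(implausible), sum(no_followup), sum(keep)))
  list(cohort = cohort[keep, , drop = FALSE], report = report)
}

#' Energy adjustment by the residual method
#'
#' Regresses a nutrient or food amount on total energy intake by ordinary
#' least squares and returns the residual plus the predicted value at the
#' sample-mean energy.  The adjusted values keep the sample mean of the
#' input and are uncorrelated with energy.
#'
#' @param values Numeric vector of intakes (one per participant).
#' @param energy Total energy intake, kcal/day, aligned with `values`.
#' @return Numeric vector of energy-adjusted values.
#' @examples
#' e <- c(1800, 2000, 2200, 2500, 3000)
#' v <- 0.01 * e + c(1, -2, 0, 3, -1)
#' adj <- residual_energy_adjust(v, e)
#' cor(adj, e)  # ~ 0
#' @export
residual_energy_adjust <- function(values, energy) {
  if (length(values) != length(energy))
    stop("values and energy must have the same length")
  if (length(values) < 3)
    stop("need at least 3 observations for the residual method")
  if (stats::sd(energy) == 0)
    stop("energy is constant; the residual regression is undefined")
  fit <- stats::lm(values ~ energy)
  unname(stats::residuals(fit) +
           sum(stats::coef(fit) * c(1, mean(energy))))
}

#' @rdname read_write_tables
#' @name read_write_tables
#' @title CSV readers and writers for pipeline tables
#' @description Thin wrappers around [utils::read.csv()] /
#'   [utils::write.csv()] used by the command-line interface: the item
#'   (food-composition) table, long-format FFQ responses and the cohort
#'   covariate/outcome table.
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_*` return data frames; `write_table_csv` returns `path`
#'   invisibly.
NULL

#' @rdname read_write_tables
#' @export
read_food_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_write_tables
#' @export
read_ffq_responses <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "visit_time", "item_id", "freq_level")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("FFQ response file is missing columns: ",
         paste(miss, collapse = ", "))
  out
}

#' @rdname read_write_tables
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
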