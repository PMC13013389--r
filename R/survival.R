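OUTCOME_CAUSES <- c(all_cause = "any", cvd = "cvd_death",
                    cancer = "cancer_death", other = "other_death")
EVENT_LEVELS <- c("none", "cvd_death", "cancer_death", "other_death")

# covariate sets of the two model specifications
MINIMAL_COVARIATES <- c("age", "sex")
FULL_COVARIATES <- c(MINIMAL_COVARIATES, "energy_kcal", "group",
                     "education", "smoking", "activity", "bmi_class",
                     "alcohol_g", "fam_cancer", "diabetes",
                     "hypertension", "hypercholesterolemia")

.model_covariates <- function(model = c("minimal", "full")) {
  switch(match.arg(model), minimal = MINIMAL_COVARIATES,
         full = FULL_COVARIATES)
}

.event_status <- function(event, outcome) {
  outcome <- match.arg(outcome, names(OUTCOME_CAUSES))
  if (outcome == "all_cause") as.integer(event != "none")
  else as.integer(event == OUTCOME_CAUSES[[outcome]])
}

.prepare_covariates <- function(d) {
  if (!"bmi_class" %in% names(d) && "bmi" %in% names(d))
    d$bmi_class <- factor(ifelse(d$bmi >= 25, "overweight_obese",
                                 "under_normal"),
                          levels = c("under_normal", "overweight_obese"))
  for (nm in c("sex", "group", "education", "smoking"))
    if (nm %in% names(d) && !is.factor(d[[nm]])) d[[nm]] <- factor(d[[nm]])
  d
}

#' Build start-stop survival intervals with time-varying exposure
#'
#' Splits each participant's follow-up at their FFQ visit times: one
#' half-open interval `[start, stop)` per inter-FFQ period, carrying the
#' cumulative-average dietary index (and optionally its quintile against
#' fixed cohort cut points) observed at the interval start.  The event is
#' placed on the final interval; exposure is updated exactly at visit
#' times, with no interpolation between visits.
#'
#' @param outcomes Cohort table: `participant_id`, `cluster_id`, `futime`
#'   (years), `event` (one of `none`, `cvd_death`, `cancer_death`,
#'   `other_death`) and covariate columns.
#' @param exposure Exposure series (from [exposure_series()]):
#'   `participant_id`, `visit_time`, `cum_avg_di`.
#' @param cuts Optional fixed quintile cut points (from
#'   [assign_quintiles()]`$cuts`); if given, a `quintile` column is added.
#' @return Data frame of intervals with `start`, `stop`, `event` (at
#'   stop), `cum_avg_di`, optional `quintile`, and the outcome covariates.
#' @export
build_intervals <- function(outcomes, exposure, cuts = NULL) {
  if (!all(outcomes$futime > 0))
    stop("follow-up time must be positive for every participant")
  if (!all(outcomes$event %in% EVENT_LEVELS))
    stop("event must be one of: ", paste(EVENT_LEVELS, collapse = ", "))
  base_ok <- outcomes$participant_id %in%
    exposure$participant_id[exposure$visit_time == 0]
  if (!all(base_ok))
    stop("no baseline exposure for participant(s): ",
         paste(utils::head(outcomes$participant_id[!base_ok], 10),
               collapse = ", "))
  e <- exposure[, c("participant_id", "visit_time", "cum_avg_di")]
  e <- merge(e, outcomes[, c("participant_id", "futime", "event")],
             by = "participant_id")
  e <- e[e$visit_time < e$futime, , drop = FALSE]
  e <- e[order(e$participant_id, e$visit_time), , drop = FALSE]
  nxt <- c(e$visit_time[-1], NA)
  last <- c(e$participant_id[-1] != e$participant_id[-nrow(e)], TRUE)
  e$start <- e$visit_time
  e$stop <- ifelse(last, e$futime, nxt)
  e$event <- ifelse(last, e$event, "none")
  e$visit_time <- e$futime <- NULL
  covars <- outcomes[, setdiff(names(outcomes), c("futime", "event")),
                     drop = FALSE]
  out <- merge(e, covars, by = "participant_id", sort = FALSE)
  out <- out[order(out$participant_id, out$start), , drop = FALSE]
  if (!is.null(cuts))
    out$quintile <- findInterval(out$cum_avg_di, cuts,
                                 left.open = TRUE) + 1L
  rownames(out) <- NULL
  .prepare_covariates(out)
}

#' Standard deviation of the exposure at cohort entry
#'
#' The SD used to put the dietary index on a per-1-SD scale: computed on
#' the analysis distribution at cohort entry (each participant's first
#' interval, i.e. the baseline cumulative average, which equals the
#' baseline dietary index).
#'
#' @param intervals Interval data from [build_intervals()].
#' @return The baseline exposure SD (positive scalar).
#' @export
exposure_sd <- function(intervals) {
  base <- intervals[!duplicated(intervals$participant_id), , drop = FALSE]
  s <- stats::sd(base$cum_avg_di)
  if (!is.finite(s) || s == 0)
    stop("exposure has zero variance; per-SD model is undefined")
  s
}

.cox_fit <- function(intervals, rhs, outcome, cluster = TRUE,
                     weights = NULL) {
  d <- intervals
  d$.status <- .event_status(d$event, outcome)
  if (sum(d$.status) < 2)
    stop("fewer than 2 events for outcome '", outcome, "'")
  terms <- rhs
  if (cluster) terms <- c(terms, "cluster(cluster_id)")
  f <- stats::as.formula(paste("survival::Surv(start, stop, .status) ~",
                               paste(terms, collapse = " + ")))
  if (is.null(weights)) {
    survival::coxph(f, data = d, ties = "efron")
  } else {
    d$.w <- weights
    survival::coxph(f, data = d, ties = "efron", weights = .w)
  }
}

.coef_row <- function(fit, pattern) {
  s <- summary(fit)$coefficients
  rows <- grep(pattern, rownames(s), value = TRUE)
  se_col <- if ("robust se" %in% colnames(s)) "robust se" else "se(coef)"
  data.frame(term = rows, coef = s[rows, "coef"], se = s[rows, se_col],
             hr = exp(s[rows, "coef"]),
             ci_low = exp(s[rows, "coef"] - 1.96 * s[rows, se_col]),
             ci_high = exp(s[rows, "coef"] + 1.96 * s[rows, se_col]),
             p = 2 * stats::pnorm(-abs(s[rows, "coef"] / s[rows, se_col])),
             row.names = NULL)
}

#' Time-dependent Cox model across exposure quintiles
#'
#' Fits the partial-likelihood Cox model on start-stop interval data with
#' quintile indicator variables (lowest quintile as reference), Efron tie
#' handling, and cluster-robust (sandwich) standard errors to account for
#' intra-cluster correlation.  For cause-specific outcomes, competing
#' deaths are censored at the time of death.
#'
#' @param intervals Interval data from [build_intervals()] (must carry a
#'   `quintile` column).
#' @param model `"minimal"` (age + sex) or `"full"` (the 12-covariate
#'   specification).
#' @param outcome `"all_cause"`, `"cvd"`, `"cancer"` or `"other"`.
#' @param cluster Use cluster-robust variance by `cluster_id`
#'   (default TRUE).
#' @return An object of class `ns_cox`: the `coxph` fit plus a tidy
#'   per-quintile coefficient table (`$table`).
#' @export
fit_cox <- function(intervals, model = c("minimal", "full"),
                    outcome = "all_cause", cluster = TRUE) {
  model <- match.arg(model)
  if (!"quintile" %in% names(intervals))
    stop("intervals carry no 'quintile' column; pass cuts to ",
         "build_intervals()")
  d <- intervals
  d$quintile <- factor(d$quintile, levels = 1:5)
  ev_by_q <- tapply(.event_status(d$event, outcome), d$quintile, sum)
  unstable <- names(ev_by_q)[is.na(ev_by_q) | ev_by_q == 0]
  if (length(unstable))
    warning("quintile(s) with zero events (estimates unstable): ",
            paste(unstable, collapse = ", "))
  fit <- .cox_fit(d, c("quintile", .model_covariates(model)), outcome,
                  cluster)
  tab <- .coef_row(fit, "^quintile")
  tab$quintile <- 2:5
  structure(list(fit = fit, table = tab, model = model, outcome = outcome),
            class = "ns_cox")
}

#' @export
print.ns_cox <- function(x, ...) {
  cat(sprintf("Cox model (%s, %s-adjusted)\n", x$outcome, x$model))
  print(x$table, digits = 3)
  invisible(x)
}

#' Linear trend test across exposure quintiles
#'
#' Models the observed median exposure of each quintile as a continuous
#' variable in the same adjusted Cox model and returns the Wald p-value
#' of its coefficient.
#'
#' @param intervals Interval data with a `quintile` column.
#' @param medians Observed per-quintile medians (from
#'   [assign_quintiles()]`$medians`).
#' @inheritParams fit_cox
#' @return List with `p`, `coef` and `se` of the trend variable.
#' @export
trend_test <- function(intervals, medians, model = c("minimal", "full"),
                       outcome = "all_cause", cluster = TRUE) {
  model <- match.arg(model)
  q <- intervals$quintile
  if (length(unique(q)) < 2)
    stop("fewer than two quintile groups; trend test is undefined")
  d <- intervals
  d$.trend <- medians[q]
  fit <- .cox_fit(d, c(".trend", .model_covariates(model)), outcome,
                  cluster)
  row <- .coef_row(fit, "^\\.trend$")
  list(p = row$p, coef = row$coef, se = row$se)
}

#' Cox model per 1-SD increment of the exposure
#'
#' Fits the adjusted Cox model with the exposure standardised to unit
#' standard deviation; the SD is computed on the baseline exposure
#' distribution of the analysis set unless supplied.
#'
#' @inheritParams fit_cox
#' @param sd_ref Exposure SD used for scaling; defaults to the SD of the
#'   baseline cumulative-average exposure.
#' @return List with `hr`, `ci_low`, `ci_high`, `p`, `coef`, `se`, `sd`.
#' @export
continuous_sd_model <- function(intervals, model = c("minimal", "full"),
                                outcome = "all_cause", sd_ref = NULL,
                                cluster = TRUE) {
  model <- match.arg(model)
  if (is.null(sd_ref)) sd_ref <- exposure_sd(intervals)
  if (!is.finite(sd_ref) || sd_ref <= 0)
    stop("exposure SD must be positive")
  d <- intervals
  d$.z <- d$cum_avg_di / sd_ref
  fit <- .cox_fit(d, c(".z", .model_covariates(model)), outcome, cluster)
  row <- .coef_row(fit, "^\\.z$")
  list(hr = row$hr, ci_low = row$ci_low, ci_high = row$ci_high,
       p = row$p, coef = row$coef, se = row$se, sd = sd_ref)
}

#' Mortality rates per 1000 person-years
#'
#' @param cases Number of events per stratum.
#' @param person_years Person-years at risk per stratum (must be > 0).
#' @return `cases / person_years * 1000`.
#' @examples
#' mortality_rates(65, 8819.5)  # 7.37
#' @export
mortality_rates <- function(cases, person_years) {
  if (any(person_years <= 0))
    stop("person-years must be positive")
  cases / person_years * 1000
}

#' Per-quintile hazard-ratio table for one outcome
#'
#' Assembles the standard presentation of a quintile analysis: cases,
#' person-time and mortality rate per 1000 person-years per quintile,
#' adjusted hazard ratios with 95% CIs against the lowest quintile, the
#' median-based trend p-value, and the continuous per-1-SD estimate.
#'
#' @inheritParams fit_cox
#' @param medians Per-quintile observed medians for the trend variable.
#' @param sd_ref Optional exposure SD for the per-SD model.
#' @return An object of class `hr_table` with elements `quintiles` (data
#'   frame, reference hazard ratio fixed at 1), `p_trend`, `per_sd`,
#'   `outcome` and `model`.
#' @export
hr_table <- function(intervals, medians, model = c("minimal", "full"),
                     outcome = "all_cause", sd_ref = NULL,
                     cluster = TRUE) {
  model <- match.arg(model)
  status <- .event_status(intervals$event, outcome)
  py <- tapply(intervals$stop - intervals$start, intervals$quintile, sum)
  cases <- tapply(status, intervals$quintile, sum)
  fit <- fit_cox(intervals, model, outcome, cluster)
  tr <- trend_test(intervals, medians, model, outcome, cluster)
  sd_row <- continuous_sd_model(intervals, model, outcome, sd_ref, cluster)
  qtab <- data.frame(quintile = 1:5,
                     cases = as.integer(cases[as.character(1:5)]),
                     person_years = as.numeric(py[as.character(1:5)]))
  qtab$rate_per_1000 <- mortality_rates(qtab$cases, qtab$person_years)
  qtab$hr <- c(1, fit$table$hr)
  qtab$ci_low <- c(NA, fit$table$ci_low)
  qtab$ci_high <- c(NA, fit$table$ci_high)
  qtab$p <- c(NA, fit$table$p)
  structure(list(quintiles = qtab, p_trend = tr$p, per_sd = sd_row,
                 outcome = outcome, model = model),
            class = "hr_table")
}

#' @export
print.hr_table <- function(x, digits = 3, ...) {
  cat(sprintf("%s mortality, %s-adjusted model\n", x$outcome, x$model))
  q <- x$quintiles
  q$rate_per_1000 <- round(q$rate_per_1000, 2)
  q$hr <- round(q$hr, digits)
  q$ci <- ifelse(is.na(q$ci_low), "(ref.)",
                 sprintf("(%.2f to %.2f)", q$ci_low, q$ci_high))
  print(q[, c("quintile", "cases", "person_years", "rate_per_1000",
              "hr", "ci")], row.names = FALSE)
  cat(sprintf("p-trend = %.3g; per 1-SD HR = %.2f (%.2f to %.2f), p = %.3g\n",
              x$p_trend, x$per_sd$hr, x$per_sd$ci_low, x$per_sd$ci_high,
              x$per_sd$p))
  invisible(x)
}

#' @export
as.data.frame.hr_table <- function(x, ...) {
  q <- x$quintiles
  q$outcome <- x$outcome
  q$model <- x$model
  q$p_trend <- x$p_trend
  q[, c("outcome", "model", "quintile", "cases", "person_years",
        "rate_per_1000", "hr", "ci_low", "ci_high", "p", "p_trend")]
}

#' Interaction (effect-modification) test with subgroup estimates
#'
#' Likelihood-ratio test comparing the adjusted Cox model with and
#' without exposure-by-modifier product terms, the exposure entering per
#' 1-SD increment.  Continuous modifiers (age, MEDAS adherence score,
#' ultra-processed food intake) are dichotomised at the analysis median.
#' Plain (non-robust) fits are used for the likelihood ratio; subgroup
#' hazard ratios are refitted per stratum with cluster-robust variance.
#'
#' @inheritParams continuous_sd_model
#' @param modifier One of `"sex"`, `"education"`, `"bmi_class"`,
#'   `"age"`, `"medas"`, `"upf"` (the latter three split at the median).
#' @return List with `p_lrt` and `subgroups` (per-level per-SD HR rows).
#' @export
interaction_test <- function(intervals, modifier, model = "full",
                             outcome = "all_cause", sd_ref = NULL) {
  allowed <- c("sex", "education", "bmi_class", "age", "medas", "upf")
  modifier <- match.arg(modifier, allowed)
  col <- switch(modifier, age = "age", medas = "medas", upf = "upf_g",
                modifier)
  if (!col %in% names(intervals))
    stop("modifier column '", col, "' not present in the interval data")
  d <- intervals
  if (modifier %in% c("age", "medas", "upf")) {
    base <- d[!duplicated(d$participant_id), col]
    med <- stats::median(base)
    d$.mod <- factor(ifelse(d[[col]] < med, paste0("lt_", med),
                            paste0("ge_", med)))
  } else {
    d$.mod <- factor(d[[col]])
  }
  lv <- table(d$.mod[!duplicated(d$participant_id)])
  if (length(lv) < 2)
    stop("modifier '", modifier, "' is constant; interaction undefined")
  if (any(lv == 0))
    stop("empty subgroup for modifier '", modifier, "': ",
         names(lv)[lv == 0])
  if (is.null(sd_ref)) sd_ref <- exposure_sd(intervals)
  d$.z <- d$cum_avg_di / sd_ref
  covs <- setdiff(.model_covariates(model), col)
  fit0 <- .cox_fit(d, c(".z", ".mod", covs), outcome, cluster = FALSE)
  fit1 <- .cox_fit(d, c(".z", ".mod", ".z:.mod", covs), outcome,
                   cluster = FALSE)
  lrt <- 2 * (fit1$loglik[2] - fit0$loglik[2])
  df <- length(stats::coef(fit1)) - length(stats::coef(fit0))
  p <- stats::pchisq(lrt, df, lower.tail = FALSE)
  subgroups <- lapply(levels(d$.mod), function(l) {
    sub <- d[d$.mod == l, , drop = FALSE]
    fit <- .cox_fit(sub, c(".z", covs), outcome, cluster = TRUE)
    row <- .coef_row(fit, "^\\.z$")
    data.frame(modifier = modifier, level = l, hr = row$hr,
               ci_low = row$ci_low, ci_high = row$ci_high, p = row$p)
  })
  list(p_lrt = p, lrt = lrt, df = df,
       subgroups = do.call(rbind, subgroups))
}

#' Sensitivity analysis excluding early deaths
#'
#' Drops participants whose death occurred within the first one or two
#' years of follow-up (guarding against reverse causality) and refits the
#' quintile analysis for each requested outcome with the main-analysis
#' quintile cut points held fixed.
#'
#' @param outcomes Cohort outcome table.
#' @param exposure Exposure series.
#' @param window Exclusion window in years (1 or 2 in the standard
#'   analysis; any positive value accepted).
#' @param cuts,medians Main-analysis quintile cuts and medians.
#' @inheritParams fit_cox
#' @param outcomes_to_fit Outcomes to refit.
#' @return List with `n_removed` and `tables` (one [hr_table()] per
#'   outcome).
#' @export
sensitivity_exclude_early <- function(outcomes, exposure, window = 1,
                                      cuts, medians, model = "full",
                                      outcomes_to_fit = names(OUTCOME_CAUSES)) {
  if (window <= 0) stop("window must be positive")
  early <- outcomes$event != "none" & outcomes$futime <= window
  kept <- outcomes[!early, , drop = FALSE]
  iv <- build_intervals(kept,
                        exposure[exposure$participant_id %in%
                                   kept$participant_id, , drop = FALSE],
                        cuts = cuts)
  tables <- lapply(outcomes_to_fit, function(oc)
    hr_table(iv, medians, model = model, outcome = oc))
  names(tables) <- outcomes_to_fit
  list(n_removed = sum(early), tables = tables)
}

#' Fine-Gray competing-risks model
#'
#' Fits the subdistribution hazard model for one cause of death, treating
#' deaths from other causes as competing events, via weighted risk-set
#' estimation ([survival::finegray()] expansion followed by a weighted
#' Cox fit).  Start-stop intervals with time-varying exposure are
#' supported through the participant id.
#'
#' @param intervals Interval data with a `quintile` column.
#' @param cause `"cvd"`, `"cancer"` or `"other"`.
#' @inheritParams fit_cox
#' @return An `ns_cox`-like list with the per-quintile subdistribution
#'   hazard ratios (`$table`).
#' @export
fine_gray <- function(intervals, cause = c("cvd", "cancer", "other"),
                      model = c("minimal", "full")) {
  cause <- match.arg(cause)
  model <- match.arg(model)
  d <- intervals
  d$.etype <- factor(ifelse(d$event == "none", "censor", d$event),
                     levels = c("censor", EVENT_LEVELS[-1]))
  if (sum(d$.etype == OUTCOME_CAUSES[[cause]]) < 2)
    stop("fewer than 2 events of cause '", cause, "'")
  d$quintile <- factor(d$quintile, levels = 1:5)
  fg <- survival::finegray(
    survival::Surv(start, stop, .etype) ~ ., data = d,
    etype = OUTCOME_CAUSES[[cause]], id = participant_id)
  f <- stats::as.formula(paste(
    "survival::Surv(fgstart, fgstop, fgstatus) ~",
    paste(c("quintile", .model_covariates(model),
            "cluster(cluster_id)"), collapse = " + ")))
  fit <- survival::coxph(f, data = fg, weights = fgwt, ties = "efron")
  tab <- .coef_row(fit, "^quintile")
  tab$quintile <- 2:5
  structure(list(fit = fit, table = tab, model = model,
                 outcome = paste0(cause, " (subdistribution)")),
            class = "ns_cox")
}

#' Time-fixed baseline-exposure models
#'
#' Refits the per-1-SD Cox model with the baseline dietary index as a
#' time-fixed exposure in place of the cumulative average (one interval
#' per participant), with the SD taken from the baseline distribution.
#'
#' @param outcomes Cohort outcome table.
#' @param baseline_di Data frame with `participant_id` and `di` at
#'   baseline.
#' @inheritParams fit_cox
#' @return List as returned by [continuous_sd_model()].
#' @export
baseline_di_models <- function(outcomes, baseline_di,
                               model = c("minimal", "full"),
                               outcome = "all_cause", cluster = TRUE) {
  model <- match.arg(model)
  di <- baseline_di$di[match(outcomes$participant_id,
                             baseline_di$participant_id)]
  if (anyNA(di))
    stop("missing baseline dietary index for ", sum(is.na(di)),
         " participant(s)")
  exposure <- data.frame(participant_id = outcomes$participant_id,
                         visit_time = 0, cum_avg_di = di)
  iv <- build_intervals(outcomes, exposure)
  continuous_sd_model(iv, model = model, outcome = outcome,
                      cluster = cluster)
}
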