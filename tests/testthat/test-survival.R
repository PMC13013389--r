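# small helper: a cohort whose exposure is drawn directly (no FFQ stage),
# survival simulated by the package generator
direct_cohort <- function(n, seed, betas = c(cvd = 0, cancer = 0, other = 0),
                          visits = 1, di_mean = 3.6, di_sd = 1.6, ...) {
  cfg <- cohort_config(n = n, n_visits = visits, seed = seed,
                       betas = betas, ...)
  covars <- generate_covariates(cfg)
  set.seed(seed + 17)
  truth <- do.call(rbind, lapply(seq_len(visits) - 1, function(v)
    data.frame(participant_id = seq_len(n), visit_time = v,
               di = rnorm(n, di_mean, di_sd))))
  truth <- exposure_series(truth)
  outcomes <- generate_survival(cfg, truth, covars)
  list(outcomes = outcomes, exposure = truth, covars = covars, cfg = cfg)
}

test_that("interval construction by hand and person-time conservation", {
  outc <- data.frame(participant_id = c(1, 2), cluster_id = c(1, 2),
                     futime = c(3, 2.5),
                     event = c("cvd_death", "none"),
                     age = 67, sex = c("male", "female"))
  expo <- data.frame(participant_id = c(1, 2, 2, 2, 2),
                     visit_time = c(0, 0, 1, 2, 2.6),
                     cum_avg_di = c(4, 2, 2.5, 3, 3.1))
  iv <- build_intervals(outc, expo)
  # one FFQ, death at year 3 -> single interval [0, 3) with the event
  iv1 <- iv[iv$participant_id == 1, ]
  expect_equal(iv1$start, 0)
  expect_equal(iv1$stop, 3)
  expect_identical(iv1$event, "cvd_death")
  # FFQs at 0,1,2 (the 2.6 visit falls after censoring), censor at 2.5
  iv2 <- iv[iv$participant_id == 2, ]
  expect_equal(iv2$start, c(0, 1, 2))
  expect_equal(iv2$stop, c(1, 2, 2.5))
  expect_identical(iv2$event, c("none", "none", "none"))
  expect_equal(iv2$cum_avg_di, c(2, 2.5, 3))
  # conservation
  expect_equal(sum(iv$stop - iv$start), sum(outc$futime))
  # quintile assignment against fixed cuts, ties to the lower bin
  ivq <- build_intervals(outc, expo, cuts = c(2, 2.5, 3, 3.5))
  expect_identical(ivq$quintile[ivq$participant_id == 2], c(1L, 2L, 3L))
  expect_error(build_intervals(outc, expo[expo$participant_id == 1, ]),
               "no baseline exposure")
})

test_that("conservation and case-count partition on a generated cohort", {
  d <- direct_cohort(400, seed = 31, visits = 3)
  iv <- build_intervals(d$outcomes, d$exposure)
  expect_equal(sum(iv$stop - iv$start), sum(d$outcomes$futime))
  # cause-specific cases partition the all-cause count
  causes <- c("cvd", "cancer", "other")
  n_by_cause <- vapply(causes, function(oc)
    sum(iv$event == paste0(oc, "_death")), numeric(1))
  expect_equal(sum(n_by_cause), sum(d$outcomes$event != "none"))
})

test_that("mortality rates: arithmetic, pooling bounds, errors", {
  expect_equal(round(mortality_rates(65, 8819.5), 2), 7.37)
  expect_equal(mortality_rates(0, 100), 0)
  r1 <- mortality_rates(10, 900)
  r2 <- mortality_rates(40, 1100)
  pooled <- mortality_rates(50, 2000)
  expect_gte(pooled, min(r1, r2))
  expect_lte(pooled, max(r1, r2))
  expect_error(mortality_rates(3, 0), "positive")
})

test_that("Cox fit recovers a two-group exponential rate ratio", {
  set.seed(202)
  n <- 1500
  grp <- rep(0:1, each = n)
  # closed-form oracle: rate ratio 2 -> log-HR log(2)
  t_ev <- c(rexp(n, 0.1), rexp(n, 0.2))
  d <- data.frame(participant_id = seq_len(2 * n), cluster_id = seq_len(2 * n),
                  start = 0, stop = t_ev, event = "cvd_death",
                  x = grp)
  fit <- survival::coxph(survival::Surv(start, stop, rep(1, 2 * n)) ~ x,
                         data = d, ties = "efron")
  est <- unname(coef(fit)); se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(est - log(2)), 3 * se)
})

test_that("quintile model emits reference HR 1 and a full table", {
  d <- direct_cohort(3000, seed = 57,
                     betas = c(cvd = log(1.6), cancer = 0, other = 0),
                     visits = 2)
  base <- d$exposure$cum_avg_di[d$exposure$visit_time == 0]
  q <- assign_quintiles(base)
  iv <- build_intervals(d$outcomes, d$exposure, cuts = q$cuts)
  tab <- hr_table(iv, q$medians, model = "minimal", outcome = "all_cause")
  expect_identical(tab$quintiles$hr[1], 1)
  expect_identical(nrow(tab$quintiles), 5L)
  expect_true(all(tab$quintiles$ci_low[-1] <= tab$quintiles$hr[-1]))
  expect_true(all(tab$quintiles$ci_high[-1] >= tab$quintiles$hr[-1]))
  expect_equal(tab$quintiles$rate_per_1000,
               tab$quintiles$cases / tab$quintiles$person_years * 1000)
  expect_true(tab$p_trend >= 0 && tab$p_trend <= 1)
  # per-SD scale invariance: doubling the exposure leaves the HR alone
  iv2 <- iv; iv2$cum_avg_di <- 2 * iv$cum_avg_di
  m1 <- continuous_sd_model(iv, model = "minimal", outcome = "cvd")
  m2 <- continuous_sd_model(iv2, model = "minimal", outcome = "cvd")
  expect_equal(m1$hr, m2$hr, tolerance = 1e-8)
  # tidy export mirrors the table layout
  td <- as.data.frame(tab)
  expect_identical(names(td)[1:3], c("outcome", "model", "quintile"))
})

test_that("early-death sensitivity drops the right participants", {
  d <- direct_cohort(2500, seed = 73,
                     betas = c(cvd = log(1.4), cancer = 0, other = 0))
  base <- d$exposure$cum_avg_di[d$exposure$visit_time == 0]
  q <- assign_quintiles(base)
  n_early1 <- sum(d$outcomes$event != "none" & d$outcomes$futime <= 1)
  n_early2 <- sum(d$outcomes$event != "none" & d$outcomes$futime <= 2)
  s1 <- sensitivity_exclude_early(d$outcomes, d$exposure, window = 1,
                                  cuts = q$cuts, medians = q$medians,
                                  model = "minimal",
                                  outcomes_to_fit = "all_cause")
  s2 <- sensitivity_exclude_early(d$outcomes, d$exposure, window = 2,
                                  cuts = q$cuts, medians = q$medians,
                                  model = "minimal",
                                  outcomes_to_fit = "all_cause")
  expect_identical(s1$n_removed, n_early1)
  expect_identical(s2$n_removed, n_early2)
  expect_gte(s2$n_removed, s1$n_removed)
  expect_error(sensitivity_exclude_early(d$outcomes, d$exposure, 0,
                                         q$cuts, q$medians), "positive")
  # no deaths inside the window -> estimates identical to main analysis
  shifted <- d$outcomes
  shifted$futime <- shifted$futime + 1.5
  expo_s <- d$exposure
  iv_main <- build_intervals(shifted, expo_s, cuts = q$cuts)
  main_fit <- fit_cox(iv_main, "minimal", "all_cause")
  s0 <- sensitivity_exclude_early(shifted, expo_s, window = 1,
                                  cuts = q$cuts, medians = q$medians,
                                  model = "minimal",
                                  outcomes_to_fit = "all_cause")
  expect_identical(s0$n_removed, 0L)
  expect_equal(s0$tables$all_cause$quintiles$hr[-1], main_fit$table$hr,
               tolerance = 1e-10)
})

test_that("interaction test: LRT validity, subgroups, degenerate input", {
  d <- direct_cohort(3000, seed = 91,
                     betas = c(cvd = 0, cancer = 0, other = 0))
  base <- d$exposure$cum_avg_di[d$exposure$visit_time == 0]
  q <- assign_quintiles(base)
  iv <- build_intervals(d$outcomes, d$exposure, cuts = q$cuts)
  res <- interaction_test(iv, "sex", model = "minimal",
                          outcome = "all_cause")
  expect_true(res$p_lrt > 0 && res$p_lrt <= 1)
  expect_identical(res$df, 1L)
  expect_identical(nrow(res$subgroups), 2L)
  res_age <- interaction_test(iv, "age", model = "minimal",
                              outcome = "all_cause")
  expect_identical(nrow(res_age$subgroups), 2L)
  iv_const <- iv; iv_const$sex <- factor("female")
  expect_error(interaction_test(iv_const, "sex", model = "minimal"),
               "constant")
  expect_error(interaction_test(iv, "upf", model = "minimal"),
               "not present")
})

test_that("cluster-robust standard errors exceed naive ones under shared frailty", {
  # household members share both a frailty and a diet: the exposure is
  # cluster-correlated, which is what the sandwich correction must absorb
  cfg <- cohort_config(n = 2500, n_visits = 1, seed = 133,
                       betas = c(cvd = log(1.3), cancer = 0, other = 0),
                       frailty_var = 1.0, cluster_frac = 0.9)
  covars <- generate_covariates(cfg)
  set.seed(150)
  cl_di <- rnorm(max(covars$cluster_id), 3.6, 1.4)
  truth <- exposure_series(data.frame(
    participant_id = seq_len(cfg$n), visit_time = 0,
    di = cl_di[covars$cluster_id] + rnorm(cfg$n, 0, 0.6)))
  d <- list(outcomes = generate_survival(cfg, truth, covars),
            exposure = truth)
  iv <- build_intervals(d$outcomes, d$exposure)
  iv$.z <- iv$cum_avg_di / exposure_sd(iv)
  iv$.status <- as.integer(iv$event != "none")
  fit <- survival::coxph(
    survival::Surv(start, stop, .status) ~ .z + age + sex +
      cluster(cluster_id), data = iv, ties = "efron")
  robust <- sqrt(diag(fit$var))[1]
  naive <- sqrt(diag(fit$naive.var))[1]
  expect_gte(robust, naive)
})

test_that("Fine-Gray reduces to the cause-specific model without competition", {
  # competing causes made vanishingly rare
  d <- direct_cohort(3000, seed = 77,
                     betas = c(cvd = log(1.5), cancer = 0, other = 0),
                     base_rates = c(cvd = 0.008, cancer = 1e-7,
                                    other = 1e-7))
  base <- d$exposure$cum_avg_di[d$exposure$visit_time == 0]
  q <- assign_quintiles(base)
  iv <- build_intervals(d$outcomes, d$exposure, cuts = q$cuts)
  cs <- fit_cox(iv, "minimal", "cvd")
  fg <- fine_gray(iv, "cvd", "minimal")
  expect_equal(fg$table$coef, cs$table$coef, tolerance = 0.02)
  expect_error(fine_gray(iv, "cancer", "minimal"), "fewer than 2")
})

test_that("subdistribution HR attenuates under heavy upper-quintile competition", {
  # competing (other-cause) mortality loaded onto high quintiles removes
  # high-exposure subjects from the cvd risk set, so the Fine-Gray sHR
  # sits below the cause-specific HR
  d <- direct_cohort(4000, seed = 88,
                     betas = c(cvd = log(1.6), cancer = 0,
                               other = log(3.5)),
                     base_rates = c(cvd = 0.004, cancer = 1e-7,
                                    other = 0.02))
  iv <- build_intervals(d$outcomes, d$exposure)
  sdv <- exposure_sd(iv)
  iv$quintile <- assign_quintiles(
    d$exposure$cum_avg_di[d$exposure$visit_time == 0])$quintile[
      match(iv$participant_id,
            d$exposure$participant_id[d$exposure$visit_time == 0])]
  cs <- continuous_sd_model(iv, "minimal", "cvd", sd_ref = sdv)
  fg <- fine_gray(iv, "cvd", "minimal")
  cs_q <- fit_cox(iv, "minimal", "cvd")
  expect_lt(mean(fg$table$coef), mean(cs_q$table$coef))
})

test_that("baseline-exposure model equals the cumulative model with one FFQ", {
  d <- direct_cohort(2000, seed = 55,
                     betas = c(cvd = log(1.4), cancer = 0, other = 0),
                     visits = 1)
  iv <- build_intervals(d$outcomes, d$exposure)
  cum_fit <- continuous_sd_model(iv, "minimal", "cvd")
  base_di <- data.frame(
    participant_id = d$exposure$participant_id[d$exposure$visit_time == 0],
    di = d$exposure$di[d$exposure$visit_time == 0])
  base_fit <- baseline_di_models(d$outcomes, base_di, "minimal", "cvd")
  expect_equal(base_fit$coef, cum_fit$coef, tolerance = 1e-10)
  expect_equal(base_fit$se, cum_fit$se, tolerance = 1e-10)
})
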