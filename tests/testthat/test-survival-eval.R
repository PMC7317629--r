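registry_row <- function(death = NA, hosp = NA, icu = NA, censor = "2013-12-31",
                         start = "2006-01-01", age = 70L, sex = "F",
                         id = "S1") {
  as_d <- function(x) as.Date(if (length(x) == 1 && is.na(x)) NA_character_ else x)
  tibble::tibble(subject_id = id, age_at_baseline = age, sex = sex,
                 followup_start = as.Date(start), death_date = as_d(death),
                 first_unplanned_hosp_date = as_d(hosp),
                 first_icu_date = as_d(icu), admin_censor_date = as.Date(censor))
}

month_day <- function(m) format(as.Date("2006-01-01") + round(m * 30.4375))

test_that("build_outcome applies horizons and censoring at death", {
  # death at ~month 30, mortality over 8 years -> event at 30
  s <- registry_row(death = month_day(30))
  oe <- build_outcome(s, outcome_spec("all_cause_mortality", 8))
  expect_equal(oe$time, 30, tolerance = 0.02)
  expect_equal(oe$event, 1L)

  # same death, hospitalization outcome with no hospitalization -> censored at death
  oh <- build_outcome(s, outcome_spec("unplanned_hospitalization", 8))
  expect_equal(oh$time, 30, tolerance = 0.02)
  expect_equal(oh$event, 0L)

  # death at month 70 truncated by the 5-year horizon -> censored at 60
  s70 <- registry_row(death = month_day(70))
  o5 <- build_outcome(s70, outcome_spec("all_cause_mortality", 5))
  expect_equal(o5$time, 60)
  expect_equal(o5$event, 0L)

  # hospitalization before death is the event
  s2 <- registry_row(death = month_day(30), hosp = month_day(12))
  oh2 <- build_outcome(s2, outcome_spec("unplanned_hospitalization", 8))
  expect_equal(oh2$event, 1L)
  expect_equal(oh2$time, 12, tolerance = 0.02)

  expect_error(build_outcome(registry_row(death = "2005-06-01"),
                             outcome_spec("all_cause_mortality", 8)),
               "data error")
  expect_true(outcome_spec("unplanned_hospitalization", 5)$censor_at_death)
  expect_false(outcome_spec("all_cause_mortality", 1)$censor_at_death)
})

test_that("event counts are monotone in the horizon and partition by sex", {
  co <- simulate_cohort(sim_config(n_subjects = 500, seed = 14))
  ev <- vapply(c(1, 5, 8), function(h) {
    sum(build_outcome(co$subjects, outcome_spec("all_cause_mortality", h))$event)
  }, numeric(1))
  expect_true(all(diff(ev) >= 0))

  oe <- build_outcome(co$subjects, outcome_spec("icu_admission", 8))
  male <- co$subjects$sex == "M"
  expect_equal(sum(oe$event[male]) + sum(oe$event[!male]), sum(oe$event))
})

test_that("km_estimate reproduces the hand product-limit example", {
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 0))
  expect_equal(km$surv[km$time == 1], 0.8)
  expect_equal(km$surv[km$time == 3], 0.8 * (2 / 3))
  expect_equal(attr(km, "n_events"), 2)

  all_censored <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(all_censored$surv == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("km_estimate matches the brute-force oracle to 1e-12", {
  co <- simulate_cohort(sim_config(n_subjects = 200, seed = 31))
  oe <- build_outcome(co$subjects, outcome_spec("all_cause_mortality", 8))
  km <- km_estimate(oe$time, oe$event)
  want <- oracle_km(oe$time, oe$event)
  got <- km$surv[km$n_event > 0]
  expect_equal(got, want$surv, tolerance = 1e-12)
  # survival is non-increasing, bounded by its confidence limits
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$lower <= km$surv + 1e-12 & km$surv <= km$upper + 1e-12))
  expect_true(all(diff(km$n_risk) <= 0))
})

test_that("log-rank equals the hypergeometric sum and handles k groups", {
  time <- c(2, 4, 5, 7, 8, 9, 11, 12, 1, 3)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), each = 5)
  got <- logrank_test(time, event, group)
  want <- oracle_logrank(time, event, group)
  expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
  expect_equal(got$df, 1)

  # identical groups: statistic near zero, p near one
  t2 <- rep(c(1, 2, 3, 4, 5), 2)
  e2 <- rep(c(1, 0, 1, 1, 0), 2)
  g2 <- rep(c("x", "y"), each = 5)
  same <- logrank_test(t2, e2, g2)
  expect_lt(same$chisq, 1e-8)
  expect_gt(same$p, 0.999)

  g4 <- rep(c("a", "b", "c", "d"), length.out = 20)
  r4 <- logrank_test(rep(time, 2), rep(event, 2), g4)
  expect_equal(r4$df, 3)
  expect_error(logrank_test(time, event, rep("a", 10)), "2 groups")
})

test_that("cox_hr matches grid-search partial-likelihood maximization", {
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  grp <- factor(ifelse(x == 1, "mild", "fit"), levels = c("fit", "mild"))
  got <- cox_hr(time, event, grp)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time,
               event = event, x = x)
  beta_hat <- grid[which.max(ll)]
  expect_equal(log(got$hr), beta_hat, tolerance = 1e-3)

  # without ties Efron and Breslow coincide
  fit_e <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  fit_b <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  expect_equal(coef(fit_e), coef(fit_b), tolerance = 1e-10)
})

test_that("groups with zero events are flagged non-estimable", {
  set.seed(41)
  time <- c(rexp(30, 0.2), rexp(30, 0.2))
  event <- c(rbinom(30, 1, 0.6), rep(0, 30))
  grp <- factor(rep(c("fit", "mild"), each = 30), levels = c("fit", "mild"))
  hr <- suppressWarnings(cox_hr(time, event, grp))
  expect_false(hr$estimable[hr$group == "mild"])
  expect_true(is.na(hr$hr[hr$group == "mild"]))
})

test_that("hazard-ratio table covers outcomes x horizons x adjustment", {
  co <- simulate_cohort(sim_config(n_subjects = 400, seed = 17,
                                   informative_log_hr = log(3)))
  dm <- ascertain_deficits(co$claims, co$catalog, ascertain_window(co),
                           co$subjects)
  sc <- compute_fi(dm, colnames(dm$values))
  grp <- assign_groups(sc, cut_points(0.034, 0.1, 0.2))
  tab <- hazard_ratio_table(co$subjects, grp,
                            outcomes = c("all_cause_mortality", "icu_admission"),
                            horizons = c(5, 8))
  expect_equal(nrow(tab), 2 * 2 * 2 * 3)  # outcomes x horizons x adj x groups
  est <- tab[tab$estimable, ]
  expect_true(all(est$ci_low <= est$hr & est$hr <= est$ci_high))
})

test_that("concordance handles ties, perfect ranking, and matches the oracle", {
  expect_equal(concordance_index(c(1, 2, 3, 4), c(1, 1, 1, 1), rep(2, 4)), 0.5)
  expect_equal(concordance_index(1:6, rep(1, 6), 6:1), 1)

  co <- simulate_cohort(sim_config(n_subjects = 50, seed = 23,
                                   informative_log_hr = log(3)))
  oe <- build_outcome(co$subjects, outcome_spec("all_cause_mortality", 8))
  risk <- co$truth$subjects$latent_frailty
  got <- concordance_index(oe$time, oe$event, risk)
  expect_equal(got, oracle_concordance(oe$time, oe$event, risk),
               tolerance = 1e-10)
})
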