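# Survival evaluation: outcome construction with censoring at death,
# Kaplan-Meier estimation with Greenwood variance and log-minus-log CIs,
# log-rank tests, Cox hazard ratios (Efron ties) and Harrell's C.
#
# Time is measured in months from follow-up start, converting exact day
# counts at 30.4375 days per month. Horizons (1/5/8 years) are applied as
# administrative censoring at 12/60/96 months, with a separate fit per
# horizon.

DAYS_PER_MONTH <- 30.4375

#' Outcome specification
#'
#' @param outcome One of `"all_cause_mortality"`,
#'   `"unplanned_hospitalization"`, `"icu_admission"`.
#' @param horizon_years Follow-up horizon in years (typically 1, 5 or 8).
#' @return A list of class `outcome_spec`. `censor_at_death` is `TRUE`
#'   exactly when the outcome is non-fatal: for hospitalization and ICU
#'   admission, death ends follow-up without counting as the event.
#' @export
outcome_spec <- function(outcome = c("all_cause_mortality",
                                     "unplanned_hospitalization",
                                     "icu_admission"),
                         horizon_years = 8) {
  outcome <- match.arg(outcome)
  stopifnot(is.numeric(horizon_years), horizon_years > 0)
  structure(list(outcome = outcome,
                 horizon_years = horizon_years,
                 censor_at_death = outcome != "all_cause_mortality"),
            class = "outcome_spec")
}

#' Build (time, event) pairs for an outcome
#'
#' Follow-up runs from `followup_start` to the earliest of the outcome's
#' event date, death (for non-fatal outcomes), the administrative censoring
#' date, and the horizon. The event indicator is 1 only when the outcome's
#' own event date achieves that minimum.
#'
#' @param subjects Registry tibble (see [read_registry()]).
#' @param spec An [outcome_spec()].
#' @return A tibble with `subject_id`, `time` (months) and `event` (0/1).
#' @export
build_outcome <- function(subjects, spec) {
  stopifnot(inherits(spec, "outcome_spec"))
  event_col <- switch(spec$outcome,
                      all_cause_mortality = "death_date",
                      unplanned_hospitalization = "first_unplanned_hosp_date",
                      icu_admission = "first_icu_date")
  months_from_start <- function(d) {
    as.numeric(d - subjects$followup_start) / DAYS_PER_MONTH
  }
  ev <- months_from_start(subjects[[event_col]])
  if (any(ev < 0, na.rm = TRUE))
    stop("data error: event date before followup_start for subject(s) ",
         paste(utils::head(subjects$subject_id[which(ev < 0)], 5), collapse = ", "),
         call. = FALSE)
  cens <- pmin(months_from_start(subjects$admin_censor_date),
               spec$horizon_years * 12)
  if (spec$censor_at_death) {
    dm <- months_from_start(subjects$death_date)
    cens <- pmin(cens, dm, na.rm = TRUE)
  }
  ev_inf <- ifelse(is.na(ev), Inf, ev)
  tibble::tibble(subject_id = subjects$subject_id,
                 time = pmin(ev_inf, cens),
                 event = as.integer(ev_inf <= cens))
}

#' Kaplan-Meier curve with Greenwood variance
#'
#' Product-limit estimate with Greenwood variance and two-sided
#' log-minus-log confidence intervals (bounds stay inside \[0, 1\]).
#'
#' @param time Non-negative follow-up times.
#' @param event Binary event indicators.
#' @param conf_level Confidence level, default 0.95.
#' @return A `km_curve`: tibble of `time`, `n_risk`, `n_event`, `surv`,
#'   `var` (Greenwood variance of S), `lower`, `upper`, plus attributes
#'   `n` and `n_events`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(time) == length(event), all(time >= 0), all(event %in% 0:1))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  curve <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv,
    var = (fit$surv * fit$std.err)^2,
    lower = ifelse(is.na(fit$lower), fit$surv, fit$lower),
    upper = ifelse(is.na(fit$upper), fit$surv, fit$upper)
  )
  structure(curve, class = c("km_curve", class(curve)),
            n = length(time), n_events = sum(event))
}

# Evaluate a stratified survfit on a common grid; returns matrices
# groups x times. NA bounds (S = 1 before the first event, or S = 0) are
# collapsed onto the estimate itself.
km_curveset <- function(time, event, group, grid_times, conf_level = 0.95) {
  group <- droplevels(as.factor(group))
  g <- levels(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           conf.type = "log-log", conf.int = conf_level)
  sm <- summary(fit, times = grid_times, extend = TRUE)
  strat <- sub("^group=", "", as.character(sm$strata))
  shape <- function(x) {
    m <- matrix(NA_real_, length(g), length(grid_times),
                dimnames = list(g, NULL))
    for (gg in g) m[gg, ] <- x[strat == gg]
    m
  }
  surv <- shape(sm$surv)
  lower <- shape(sm$lower); upper <- shape(sm$upper)
  lower[is.na(lower)] <- surv[is.na(lower)]
  upper[is.na(upper)] <- surv[is.na(upper)]
  structure(list(times = grid_times, groups = g, surv = surv,
                 lower = lower, upper = upper,
                 n_risk = shape(sm$n.risk),
                 group_sizes = table(group)),
            class = "survival_curveset")
}

#' Kaplan-Meier curves for frailty groups on a common time grid
#'
#' @param time,event Follow-up months and event indicators.
#' @param group Frailty group labels (factor ordered fit to severe).
#' @param grid_times Common evaluation grid in months, default monthly
#'   months 0-96.
#' @param conf_level Confidence level for the Greenwood log-minus-log CIs.
#' @return A `survival_curveset` holding S(t), CI bounds and at-risk
#'   counts as groups-by-times matrices.
#' @export
curveset_by_group <- function(time, event, group, grid_times = 0:96,
                              conf_level = 0.95) {
  km_curveset(time, event, group, grid_times, conf_level)
}

#' @export
print.survival_curveset <- function(x, ...) {
  cat("Survival curve set:", length(x$groups), "groups (",
      paste(x$groups, collapse = " > "), ") on",
      length(x$times), "grid times\n")
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Group labels (2 or more groups).
#' @return A list with `chisq`, `df` (groups - 1) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratios by frailty group
#'
#' Fits a Cox model (Efron tie handling) of the outcome on the frailty
#' group with `fit` as the reference; the adjusted model adds age (years)
#' and sex. Groups with zero events are flagged non-estimable rather than
#' reported with a spurious hazard ratio.
#'
#' @param time,event Follow-up months and event indicators.
#' @param group Frailty group factor; first level is the reference.
#' @param age,sex Optional covariates (required when `adjusted = TRUE`).
#' @param adjusted Add age and sex to the model?
#' @param conf_level Confidence level for the Wald intervals.
#' @return A tibble with one row per non-reference group: `group`,
#'   `adjusted`, `hr`, `ci_low`, `ci_high`, `n_group`, `n_events`,
#'   `estimable`.
#' @export
cox_hr <- function(time, event, group, age = NULL, sex = NULL,
                   adjusted = FALSE, conf_level = 0.95) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    stop("hazard ratios need at least 2 groups", call. = FALSE)
  dat <- data.frame(time = time, event = event, group = group)
  fml <- survival::Surv(time, event) ~ group
  if (adjusted) {
    if (is.null(age) || is.null(sex))
      stop("adjusted model requires age and sex", call. = FALSE)
    dat$age <- age
    dat$sex <- droplevels(as.factor(sex))
    # in a sex-specific analysis the sex covariate is constant: adjust for
    # age alone
    fml <- if (nlevels(dat$sex) >= 2)
      survival::Surv(time, event) ~ group + age + sex
    else survival::Surv(time, event) ~ group + age
  }
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lv <- levels(group)[-1]
  coefs <- stats::coef(fit)[paste0("group", lv)]
  ses <- sqrt(diag(fit$var))[seq_along(lv)]
  ev_by_group <- vapply(split(dat$event, dat$group), sum, numeric(1))
  estimable <- unname(ev_by_group[lv] > 0 & is.finite(coefs) & ses < 50)
  tibble::tibble(
    group = lv,
    adjusted = adjusted,
    hr = ifelse(estimable, unname(exp(coefs)), NA_real_),
    ci_low = ifelse(estimable, unname(exp(coefs - z * ses)), NA_real_),
    ci_high = ifelse(estimable, unname(exp(coefs + z * ses)), NA_real_),
    n_group = as.integer(table(dat$group)[lv]),
    n_events = as.integer(ev_by_group[lv]),
    estimable = unname(estimable)
  )
}

#' Hazard-ratio table across outcomes, horizons and adjustment
#'
#' Builds the outcome per [build_outcome()] and fits a separate Cox model
#' per outcome x horizon x adjustment cell, mirroring the conventional
#' claims-cohort reporting layout (reference group: fit).
#'
#' @param subjects Registry tibble.
#' @param group Frailty group factor aligned with `subjects` rows.
#' @param outcomes Outcome names (see [outcome_spec()]).
#' @param horizons Horizons in years.
#' @param adjusted Logical vector; fit unadjusted and/or age-sex-adjusted
#'   models.
#' @return A tibble with columns `outcome`, `horizon_years`, and the
#'   [cox_hr()] columns.
#' @export
hazard_ratio_table <- function(subjects, group,
                               outcomes = c("all_cause_mortality",
                                            "unplanned_hospitalization",
                                            "icu_admission"),
                               horizons = c(1, 5, 8),
                               adjusted = c(FALSE, TRUE)) {
  rows <- list()
  for (oc in outcomes) {
    for (h in horizons) {
      oe <- build_outcome(subjects, outcome_spec(oc, h))
      for (adj in adjusted) {
        hr <- cox_hr(oe$time, oe$event, group,
                     age = subjects$age_at_baseline, sex = subjects$sex,
                     adjusted = adj)
        hr$outcome <- oc
        hr$horizon_years <- h
        rows[[length(rows) + 1]] <- hr
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "outcome", "horizon_years", dplyr::everything())
}

#' Harrell's concordance index
#'
#' Probability that, among pairs comparable under censoring, the subject
#' with the higher risk score fails first; tied scores contribute 1/2.
#'
#' @param time,event Follow-up times and event indicators.
#' @param risk Risk score per subject (higher = riskier).
#' @return The concordance index in \[0, 1\].
#' @export
concordance_index <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  n_pairs <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no comparable pairs under censoring", call. = FALSE)
  unname(cf$concordance)
}
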