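# Synthetic claims-cohort generator.
#
# The generative model: a latent frailty (standard normal plus a linear age
# term) raises condition prevalence on the log-odds scale; a small subset of
# "informative" conditions carries a log-linear effect on the death,
# hospitalization and ICU hazards, together with age and sex terms. Event
# times are exponential given the linear predictor; censoring at death is
# applied downstream by the analysis layer, not here.

#' Simulation configuration for a synthetic claims cohort
#'
#' Bundles and validates every parameter of the generative model. Defaults
#' describe a desk-scale cohort of community-dwelling older adults (65-100
#' years) observed for one baseline ascertainment year of claims followed by
#' eight years of follow-up for death, unplanned hospitalization and ICU
#' admission.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param n_conditions Number of chronic conditions in the catalog.
#' @param n_informative Number of conditions carrying a true hazard effect
#'   (must not exceed `n_conditions`).
#' @param informative_log_hr Per-condition log hazard ratio on each outcome
#'   for the informative conditions.
#' @param prevalence_base Baseline condition probability in (0,1); scalar or
#'   vector of length `n_conditions`.
#' @param prevalence_frailty_slope Log-odds increase in condition prevalence
#'   per unit latent frailty.
#' @param age_range Two-element integer vector, inclusive age band at
#'   baseline (years).
#' @param female_fraction Proportion of women.
#' @param baseline_hazard_death,baseline_hazard_hosp,baseline_hazard_icu
#'   Baseline event rates in events per person-year (at age 75, female, no
#'   informative conditions).
#' @param followup_years Follow-up duration after the baseline year.
#' @param claim_count_model List with `outpatient_mean` (mean of the
#'   zero-truncated Poisson outpatient claim count given condition presence;
#'   keep >= 3 so the ascertainment rule passes most true cases) and
#'   `inpatient_prob` (Bernoulli probability of one inpatient claim).
#' @param admin_censor_prob Probability of administrative loss to follow-up
#'   before the window end (loss time uniform over follow-up).
#' @param frailty_age_slope Increase in mean latent frailty per year of age
#'   above 65.
#' @param age_log_hr Log hazard ratio per year of age (centred at 75).
#' @param male_log_hr Log hazard ratio for men versus women.
#' @param baseline_start Calendar date opening the one-year ascertainment
#'   window; follow-up starts the day after the window closes.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 200, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort$subjects)
sim_config <- function(n_subjects = 2000,
                       seed = 1L,
                       n_conditions = 30,
                       n_informative = 5,
                       informative_log_hr = log(2),
                       prevalence_base = 0.10,
                       prevalence_frailty_slope = 0.8,
                       age_range = c(65L, 100L),
                       female_fraction = 0.5,
                       baseline_hazard_death = 0.04,
                       baseline_hazard_hosp = 0.15,
                       baseline_hazard_icu = 0.04,
                       followup_years = 8,
                       claim_count_model = list(outpatient_mean = 4,
                                                inpatient_prob = 0.15),
                       admin_censor_prob = 0.05,
                       frailty_age_slope = 0.04,
                       age_log_hr = 0.07,
                       male_log_hr = 0.35,
                       baseline_start = as.Date("2005-01-01")) {
  cfg <- list(
    n_subjects = n_subjects, seed = seed, n_conditions = n_conditions,
    n_informative = n_informative, informative_log_hr = informative_log_hr,
    prevalence_base = prevalence_base,
    prevalence_frailty_slope = prevalence_frailty_slope,
    age_range = age_range, female_fraction = female_fraction,
    baseline_hazard_death = baseline_hazard_death,
    baseline_hazard_hosp = baseline_hazard_hosp,
    baseline_hazard_icu = baseline_hazard_icu,
    followup_years = followup_years,
    claim_count_model = claim_count_model,
    admin_censor_prob = admin_censor_prob,
    frailty_age_slope = frailty_age_slope,
    age_log_hr = age_log_hr, male_log_hr = male_log_hr,
    baseline_start = as.Date(baseline_start)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid simulation config field `", field, "`: ", why, call. = FALSE)
  }
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
      bad(field, paste0("must be a single integer >= ", min))
  }
  chk_prob <- function(field, open = TRUE) {
    x <- cfg[[field]]
    ok <- is.numeric(x) && all(!is.na(x)) &&
      if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
    if (!ok) bad(field, if (open) "must lie in (0, 1)" else "must lie in [0, 1]")
  }
  chk_pos <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      bad(field, "must be a single positive number")
  }
  chk_count("n_subjects"); chk_count("n_conditions")
  chk_count("n_informative", min = 0)
  if (cfg$n_informative > cfg$n_conditions)
    bad("n_informative", "must not exceed n_conditions")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    bad("seed", "must be a single integer")
  if (!is.numeric(cfg$informative_log_hr) || anyNA(cfg$informative_log_hr))
    bad("informative_log_hr", "must be numeric")
  if (!(length(cfg$prevalence_base) %in% c(1L, cfg$n_conditions)))
    bad("prevalence_base", "must be scalar or length n_conditions")
  chk_prob("prevalence_base")
  chk_prob("female_fraction", open = FALSE)
  chk_prob("admin_censor_prob", open = FALSE)
  chk_pos("baseline_hazard_death"); chk_pos("baseline_hazard_hosp")
  chk_pos("baseline_hazard_icu"); chk_pos("followup_years")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2] ||
      cfg$age_range[1] < 0)
    bad("age_range", "must be an ordered pair of non-negative ages")
  ccm <- cfg$claim_count_model
  if (!is.list(ccm) || is.null(ccm$outpatient_mean) || is.null(ccm$inpatient_prob) ||
      ccm$outpatient_mean <= 0 || ccm$inpatient_prob < 0 || ccm$inpatient_prob > 1)
    bad("claim_count_model",
        "needs outpatient_mean > 0 and inpatient_prob in [0, 1]")
  if (is.na(cfg$baseline_start)) bad("baseline_start", "must be a valid date")
  invisible(cfg)
}

# Zero-truncated Poisson via inverse-cdf restricted to u > P(X = 0).
rztpois <- function(n, lambda) {
  u <- stats::runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic claims cohort
#'
#' Draws a subject registry, a claims table for the one-year baseline
#' ascertainment window, a condition catalog, and a ground-truth ledger
#' (latent frailty per subject, informative condition set) for
#' parameter-recovery tests.
#'
#' Draw order under the single root seed: ages, sex, latent frailty,
#' informative condition ids, condition presence, claims (counts, then dates,
#' then inpatient flags), event times (death, hospitalization, ICU), and
#' administrative censoring. Event dates falling after the administrative
#' censoring time or window end are recorded as missing (censored).
#'
#' @param config A [sim_config()].
#' @return A list of class `claims_cohort` with elements `subjects`,
#'   `claims`, `catalog`, `truth` (list with `subjects` and `conditions`
#'   tibbles), and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$n_conditions
  subject_id <- sprintf("S%05d", seq_len(n))
  condition_id <- sprintf("C%02d", seq_len(p))
  # Non-nested 3-digit ICD-9 families, three apart so no prefix contains
  # another.
  icd9_family <- sprintf("%03d", seq(110L, by = 3L, length.out = p))

  # Age pyramid thins with age, as in an insured 65+ population.
  ages_avail <- seq(config$age_range[1], config$age_range[2])
  age <- sample(ages_avail, n, replace = TRUE,
                prob = exp(-0.07 * (ages_avail - ages_avail[1])))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  frailty <- stats::rnorm(n) + config$frailty_age_slope * (age - 65)

  informative <- if (config$n_informative > 0)
    sort(sample.int(p, config$n_informative)) else integer(0)

  base <- rep(config$prevalence_base, length.out = p)
  eta <- outer(config$prevalence_frailty_slope * frailty, stats::qlogis(base), "+")
  present <- matrix(stats::runif(n * p) < stats::plogis(eta), n, p,
                    dimnames = list(subject_id, condition_id))

  window_start <- config$baseline_start
  window_days <- as.integer(seq(window_start, by = "day", length.out = 366)[366] -
                              window_start)  # 365 or 366 in leap years
  followup_start <- window_start + window_days

  claims <- simulate_claims(present, icd9_family, window_start, window_days,
                            config$claim_count_model)

  lp <- (present[, informative, drop = FALSE] %*%
           rep(config$informative_log_hr, length.out = length(informative)))[, 1] +
    config$age_log_hr * (age - 75) + config$male_log_hr * (sex == "M")
  t_death <- stats::rexp(n) / (config$baseline_hazard_death * exp(lp))
  t_hosp  <- stats::rexp(n) / (config$baseline_hazard_hosp  * exp(lp))
  t_icu   <- stats::rexp(n) / (config$baseline_hazard_icu   * exp(lp))

  lost <- stats::runif(n) < config$admin_censor_prob
  cens_years <- ifelse(lost, stats::runif(n) * config$followup_years,
                       config$followup_years)
  to_date <- function(t_years) {
    d <- followup_start + round(t_years * 365.25)
    d[t_years > cens_years] <- NA
    d
  }
  subjects <- tibble::tibble(
    subject_id = subject_id,
    age_at_baseline = as.integer(age),
    sex = sex,
    followup_start = followup_start,
    death_date = to_date(t_death),
    first_unplanned_hosp_date = to_date(t_hosp),
    first_icu_date = to_date(t_icu),
    admin_censor_date = followup_start + round(cens_years * 365.25)
  )
  catalog <- tibble::tibble(
    condition_id = condition_id,
    icd9_prefixes = icd9_family,
    label = paste0("condition ", condition_id, " (ICD-9 ", icd9_family, ")")
  )
  truth <- list(
    subjects = tibble::tibble(subject_id = subject_id, latent_frailty = frailty),
    conditions = tibble::tibble(
      condition_id = condition_id[informative],
      log_hr = rep(config$informative_log_hr, length.out = length(informative))
    )
  )
  structure(list(subjects = subjects, claims = claims, catalog = catalog,
                 truth = truth, config = config),
            class = "claims_cohort")
}

simulate_claims <- function(present, icd9_family, window_start, window_days,
                            ccm) {
  idx <- which(present, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(subject_id = character(), service_date = as.Date(character()),
                          setting = character(), icd9 = character()))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m <- nrow(idx)
  n_out <- rztpois(m, ccm$outpatient_mean)
  n_out <- pmin(n_out, window_days)
  # Distinct visit days per subject-condition pair, so the >=3 outpatient
  # rule counts genuine separate encounters.
  out_days <- lapply(n_out, function(k) sort(sample.int(window_days, k)) - 1L)
  inpatient <- stats::runif(m) < ccm$inpatient_prob
  in_days <- sample.int(window_days, m, replace = TRUE) - 1L
  sub_ids <- rownames(present)[idx[, 1]]
  fam <- icd9_family[idx[, 2]]
  # Claims carry full-precision codes under the condition's 3-digit family.
  code_of <- function(family, nn) {
    suffix <- sample(0:9, nn, replace = TRUE)
    paste0(family, ".", suffix)
  }
  out_tbl <- tibble::tibble(
    subject_id = rep(sub_ids, n_out),
    service_date = window_start + unlist(out_days),
    setting = "outpatient",
    icd9 = code_of(rep(fam, n_out), sum(n_out))
  )
  in_tbl <- tibble::tibble(
    subject_id = sub_ids[inpatient],
    service_date = window_start + in_days[inpatient],
    setting = "inpatient",
    icd9 = code_of(fam[inpatient], sum(inpatient))
  )
  claims <- dplyr::bind_rows(out_tbl, in_tbl)
  dplyr::arrange(claims, .data$subject_id, .data$service_date, .data$setting,
                 .data$icd9)
}

#' Write a cohort to plain-text files
#'
#' Serializes the claims table, subject registry, condition catalog and
#' ground-truth ledger as CSV in the documented dialect (ISO-8601 dates,
#' settings upper-cased). Files round-trip losslessly through
#' [read_claims()] / [read_registry()] / [read_catalog()].
#'
#' @param cohort A `claims_cohort` from [simulate_cohort()], or a list with
#'   at least `subjects` and `claims`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- c(claims = file.path(dir, "claims.csv"),
             registry = file.path(dir, "registry.csv"))
  claims_out <- dplyr::mutate(cohort$claims, setting = toupper(.data$setting))
  readr::write_csv(claims_out, paths[["claims"]], na = "")
  readr::write_csv(cohort$subjects, paths[["registry"]], na = "")
  if (!is.null(cohort$catalog)) {
    paths[["catalog"]] <- file.path(dir, "catalog.csv")
    readr::write_csv(cohort$catalog, paths[["catalog"]], na = "")
  }
  if (!is.null(cohort$truth)) {
    paths[["truth_subjects"]] <- file.path(dir, "truth_subjects.csv")
    paths[["truth_conditions"]] <- file.path(dir, "truth_conditions.csv")
    readr::write_csv(cohort$truth$subjects, paths[["truth_subjects"]], na = "")
    readr::write_csv(cohort$truth$conditions, paths[["truth_conditions"]], na = "")
  }
  invisible(paths)
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat("Synthetic claims cohort:", nrow(x$subjects), "subjects,",
      nrow(x$claims), "claim rows,", nrow(x$catalog), "conditions\n")
  cat("Baseline window starts", format(x$config$baseline_start),
      "| follow-up", x$config$followup_years, "years\n")
  invisible(x)
}
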