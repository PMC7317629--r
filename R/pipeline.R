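# End-to-end orchestration: simulate (or load) -> filter -> ascertain ->
# select -> score -> stratify -> evaluate, with per-stage artifacts and a
# manifest so each stage is independently inspectable and reruns with the
# same config and seed are byte-identical.

#' Pipeline configuration
#'
#' Exactly one data source must be active: a simulation block
#' ([sim_config()]) or external file paths (claims, registry, catalog).
#'
#' @param simulation A [sim_config()], or `NULL` when reading external
#'   files.
#' @param paths Named list with `claims`, `registry`, `catalog` CSV paths,
#'   or `NULL` when simulating.
#' @param output_dir Directory for stage artifacts.
#' @param ascertainment_window Two dates (closed interval); derived from
#'   the simulation config when simulating.
#' @param age_min,age_max Cohort filter bounds (years).
#' @param rf [rf_settings()] for condition ranking and k selection; its
#'   seed is derived from `seed` when left `NULL`.
#' @param k_grid Candidate k values; `NULL` means the full grid `1..p` for
#'   small catalogs (p <= 25) and a strided grid for larger ones.
#' @param target_outcome Outcome the selection forest predicts:
#'   `"death_followup"` (death during the full follow-up, the default) or
#'   `"death_1y"`.
#' @param reference_conditions Optional character vector of condition ids
#'   for the expert-list comparator index.
#' @param strat_grid_times Monthly evaluation grid for the cut-point
#'   search (months after follow-up start).
#' @param min_group_size Minimum subjects per frailty group in the search;
#'   `NULL` means `max(30, 0.5% of n)`.
#' @param outcomes,horizons Outcomes and horizons (years) for the
#'   hazard-ratio table.
#' @param seed Root seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            output_dir = tempfile("mlfrailty_run_"),
                            ascertainment_window = NULL,
                            age_min = 65, age_max = 100,
                            rf = NULL, k_grid = NULL,
                            target_outcome = c("death_followup", "death_1y"),
                            reference_conditions = NULL,
                            strat_grid_times = 12:96,
                            min_group_size = NULL,
                            outcomes = c("all_cause_mortality",
                                         "unplanned_hospitalization",
                                         "icu_admission"),
                            horizons = c(1, 5, 8),
                            seed = 1L) {
  target_outcome <- match.arg(target_outcome)
  if (is.null(simulation) == is.null(paths))
    stop("validation error: exactly one of `simulation` and `paths` must be set",
         call. = FALSE)
  if (!is.null(paths)) {
    need <- c("claims", "registry", "catalog")
    if (!all(need %in% names(paths)))
      stop("validation error: `paths` needs claims, registry and catalog",
           call. = FALSE)
    if (is.null(ascertainment_window))
      stop("validation error: `ascertainment_window` is required with external files",
           call. = FALSE)
  }
  if (is.null(rf)) rf <- rf_settings(seed = seed + 1L)
  structure(list(simulation = simulation, paths = paths,
                 output_dir = output_dir,
                 ascertainment_window = ascertainment_window,
                 age_min = age_min, age_max = age_max,
                 rf = rf, k_grid = k_grid, target_outcome = target_outcome,
                 reference_conditions = reference_conditions,
                 strat_grid_times = strat_grid_times,
                 min_group_size = min_group_size,
                 outcomes = outcomes, horizons = horizons,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulation`
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  if (!is.null(y$ascertainment_window))
    y$ascertainment_window <- as.Date(unlist(y$ascertainment_window))
  if (!is.null(y$rf)) y$rf <- do.call(rf_settings, y$rf)
  do.call(pipeline_config, y)
}

default_k_grid <- function(p) {
  if (p <= 25) seq_len(p) else unique(c(1:15, seq(20, p, by = 5), p))
}

#' Run the full frailty-index pipeline
#'
#' Stages, in order: acquire data (simulate or read), filter the cohort to
#' the configured age band, ascertain deficits, build the selection
#' outcome, rank conditions and select k by out-of-bag accuracy, compute
#' frailty scores, search stratification cut points on all-cause
#' mortality, and evaluate survival (descriptives, log-rank, hazard-ratio
#' table, concordance). Every stage persists its artifact under
#' `output_dir` and appends to `MANIFEST`; a failing stage aborts with its
#' name. If the cut-point search is infeasible the best-scoring candidate
#' is still used for downstream evaluation, flagged in the report.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: descriptives, frailty-index model,
#'   stratification result, group assignments, hazard-ratio table,
#'   log-rank tests, concordance indices and provenance.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$output_dir, "MANIFEST")
  writeLines(paste0("run started; config hash ", rlang::hash(unclass(config))),
             manifest_path)
  note <- function(stage, detail = "") {
    cat(paste0(stage, ": done ", detail, "\n"), file = manifest_path,
        append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      cat(paste0(stage, ": FAILED (", conditionMessage(e), ")\n"),
          file = manifest_path, append = TRUE)
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- run_stage("acquire", acquire_data(config))
  note("acquire", paste0("(", nrow(dat$subjects), " subjects, ",
                         nrow(dat$claims), " claim rows)"))

  subjects <- run_stage("filter_cohort",
                        suppressMessages(filter_cohort(dat$subjects,
                                                       config$age_min,
                                                       config$age_max)))
  note("filter_cohort", paste0("(", nrow(subjects), " retained)"))

  dm <- run_stage("ascertain", ascertain_deficits(dat$claims, dat$catalog,
                                                  dat$window, subjects))
  write_deficit_matrix(dm, file.path(config$output_dir, "deficit_matrix.csv"),
                       file.path(config$output_dir, "deficit_matrix_triplets.csv"))
  note("ascertain")

  followup_years <- if (!is.null(config$simulation))
    config$simulation$followup_years else 8
  sel_horizon <- if (config$target_outcome == "death_1y") 1 else followup_years
  sel_outcome <- run_stage("selection_outcome", {
    oe <- build_outcome(subjects, outcome_spec("all_cause_mortality", sel_horizon))
    if (length(unique(oe$event)) < 2)
      stop("selection outcome has a single class")
    oe
  })

  model <- run_stage("select_conditions", {
    ranking <- rank_importance(dm, sel_outcome$event, config$rf)
    k_grid <- if (is.null(config$k_grid)) default_k_grid(ncol(dm$values)) else
      config$k_grid
    select_k(dm, sel_outcome$event, ranking, k_grid, config$rf,
             target_outcome = config$target_outcome)
  })
  write_fi_model(model, file.path(config$output_dir, "fi_model.json"))
  note("select_conditions", paste0("(k = ", model$selected_k, ")"))

  scores <- run_stage("score", {
    sc <- compute_fi(dm, model$selected_conditions)
    if (!is.null(config$reference_conditions))
      sc <- dplyr::bind_rows(sc, compute_reference_fi(dm, config$reference_conditions))
    sc
  })
  readr::write_csv(scores, file.path(config$output_dir, "scores.csv"))
  note("score")

  mort <- build_outcome(subjects, outcome_spec("all_cause_mortality",
                                               followup_years))
  ml_scores <- dplyr::filter(scores, .data$index_kind == "ml_mfi")
  strat <- run_stage("stratify",
                     search_cutpoints(ml_scores, mort$time, mort$event,
                                      grid_times = config$strat_grid_times,
                                      min_group_size = config$min_group_size))
  write_stratification(strat, file.path(config$output_dir, "stratification.json"))
  note("stratify", if (strat$feasible) "(feasible)" else
    paste0("(INFEASIBLE: ", strat$failed_constraint, ")"))

  if (!is.null(strat$cutpoints)) {
    groups <- run_stage("assign_groups", assign_groups(ml_scores, strat$cutpoints))
    readr::write_csv(tibble::tibble(subject_id = ml_scores$subject_id,
                                    group = as.character(groups)),
                     file.path(config$output_dir, "groups.csv"))
    note("assign_groups")
  } else {
    # no candidate even met the group-size constraint (scores too coarse
    # for four groups at this n); group-level evaluation is skipped
    groups <- NULL
    cat("assign_groups: skipped (no size-feasible cut points)\n",
        file = manifest_path, append = TRUE)
  }

  descriptives <- run_stage("describe", describe_cohort(scores, subjects))
  readr::write_csv(descriptives, file.path(config$output_dir, "descriptives.csv"))
  note("describe")

  evalr <- run_stage("survival_eval", {
    hr <- if (!is.null(groups))
      hazard_ratio_table(subjects, groups, config$outcomes, config$horizons)
    lr <- if (!is.null(groups))
      lapply(stats::setNames(config$outcomes, config$outcomes), function(oc) {
        oe <- build_outcome(subjects, outcome_spec(oc, followup_years))
        logrank_test(oe$time, oe$event, groups)
      })
    cidx <- lapply(stats::setNames(config$outcomes, config$outcomes), function(oc) {
      oe <- build_outcome(subjects, outcome_spec(oc, followup_years))
      concordance_index(oe$time, oe$event, ml_scores$value)
    })
    list(hr_table = hr, logrank = lr, concordance = cidx)
  })
  if (!is.null(evalr$hr_table))
    readr::write_csv(evalr$hr_table, file.path(config$output_dir, "hr_table.csv"))
  note("survival_eval")

  report <- structure(list(
    descriptives = descriptives,
    model = model,
    stratification = strat,
    groups = groups,
    scores = scores,
    hr_table = evalr$hr_table,
    logrank = evalr$logrank,
    concordance = evalr$concordance,
    n_subjects = nrow(subjects),
    provenance = list(config_hash = rlang::hash(unclass(config)),
                      seed = config$seed,
                      package_version = as.character(utils::packageVersion("mlfrailty")))
  ), class = "run_report")
  jsonlite::write_json(report_summary(report),
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  note("report")
  report
}

acquire_data <- function(config) {
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    window <- c(cohort$config$baseline_start,
                cohort$subjects$followup_start[1] - 1)
    list(subjects = cohort$subjects, claims = cohort$claims,
         catalog = cohort$catalog, window = window, truth = cohort$truth)
  } else {
    list(subjects = read_registry(config$paths$registry),
         claims = read_claims(config$paths$claims),
         catalog = read_catalog(config$paths$catalog),
         window = as.Date(config$ascertainment_window), truth = NULL)
  }
}

report_summary <- function(report) {
  strat <- report$stratification
  list(
    n_subjects = report$n_subjects,
    selected_k = report$model$selected_k,
    oob_accuracy = report$model$accuracy_trace$accuracy[
      report$model$accuracy_trace$k == report$model$selected_k],
    cutpoints = if (!is.null(strat$cutpoints))
      list(c1 = strat$cutpoints$c1, c2 = strat$cutpoints$c2,
           c3 = strat$cutpoints$c3) else NULL,
    stratification_feasible = strat$feasible,
    group_sizes = as.list(strat$group_sizes),
    concordance = report$concordance,
    logrank_p = lapply(report$logrank, function(x) x$p),
    provenance = report$provenance
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("mlfrailty run report:", x$n_subjects, "subjects\n")
  print(x$model)
  print(x$stratification)
  cat("C-index (ML-mFI):",
      paste(names(x$concordance), signif(unlist(x$concordance), 3),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Table-1-style cohort descriptives
#'
#' Mean (SD) of each frailty index by 5-year age band (65-69, 70-74,
#' 75-79, 80-84, 85+) and sex, plus all-subject rows. Empty bands appear
#' with count 0 and missing statistics.
#'
#' @param scores Score tibble (`subject_id`, `value`, `index_kind`).
#' @param subjects Registry tibble aligned by `subject_id`.
#' @return A tibble with `age_band`, `sex` (`"all"`, `"M"`, `"F"`),
#'   `index_kind`, `n`, `mean`, `sd`.
#' @export
describe_cohort <- function(scores, subjects) {
  bands <- c("65-69", "70-74", "75-79", "80-84", "85+")
  band_of <- function(age) {
    cut(age, breaks = c(65, 70, 75, 80, 85, Inf), right = FALSE,
        labels = bands)
  }
  dat <- dplyr::inner_join(scores, subjects[, c("subject_id", "age_at_baseline", "sex")],
                           by = "subject_id")
  dat$age_band <- band_of(dat$age_at_baseline)
  one <- function(d, sex_label) {
    agg <- dplyr::summarise(
      dplyr::group_by(d, .data$age_band, .data$index_kind, .drop = FALSE),
      n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop")
    agg$sex <- sex_label
    agg
  }
  out <- dplyr::bind_rows(
    one(dat, "all"),
    one(dat[dat$sex == "M", ], "M"),
    one(dat[dat$sex == "F", ], "F")
  )
  out$mean[out$n == 0] <- NA_real_
  dplyr::select(dplyr::arrange(out, .data$index_kind, .data$sex, .data$age_band),
                "age_band", "sex", "index_kind", "n", "mean", "sd")
}

#' Rerun the pipeline per stratum
#'
#' Repeats the whole pipeline — including condition selection and the
#' cut-point search — inside each stratum, so every stratum acquires its
#' own selected k and cut points (sex strata, or the age sub-cohorts
#' 65-75, 76-85, 86+).
#'
#' @param config A [pipeline_config()].
#' @param strata `"sex"` or `"age"`.
#' @param min_stratum_n Strata smaller than this are skipped with a
#'   warning.
#' @return Named list of `run_report`s (skipped strata are absent).
#' @export
run_stratified <- function(config, strata = c("sex", "age"),
                           min_stratum_n = 100) {
  strata <- match.arg(strata)
  dat <- acquire_data(config)
  defs <- if (strata == "sex") {
    list(M = function(s) s$sex == "M", F = function(s) s$sex == "F")
  } else {
    list("65-75" = function(s) s$age_at_baseline >= 65 & s$age_at_baseline <= 75,
         "76-85" = function(s) s$age_at_baseline >= 76 & s$age_at_baseline <= 85,
         "86+"  = function(s) s$age_at_baseline >= 86)
  }
  reports <- list()
  for (nm in names(defs)) {
    keep <- defs[[nm]](dat$subjects)
    if (sum(keep) < min_stratum_n) {
      warning("stratum `", nm, "` has ", sum(keep), " subjects (< ",
              min_stratum_n, "); skipped", call. = FALSE)
      next
    }
    sub_dir <- file.path(config$output_dir, paste0("stratum_", gsub("[^A-Za-z0-9]", "_", nm)))
    sub_cfg <- config
    sub_cfg$output_dir <- sub_dir
    sub_subjects <- dat$subjects[keep, ]
    sub_claims <- dat$claims[dat$claims$subject_id %in% sub_subjects$subject_id, ]
    reports[[nm]] <- run_pipeline_on(sub_cfg, sub_subjects, sub_claims,
                                     dat$catalog, dat$window)
  }
  reports
}

# Run the pipeline on in-memory data (used by run_stratified so the cohort
# is simulated or read once and then partitioned).
run_pipeline_on <- function(config, subjects, claims, catalog, window) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- file.path(config$output_dir, "input")
  write_cohort(list(subjects = subjects, claims = claims, catalog = catalog),
               tmp)
  cfg <- pipeline_config(
    paths = list(claims = file.path(tmp, "claims.csv"),
                 registry = file.path(tmp, "registry.csv"),
                 catalog = file.path(tmp, "catalog.csv")),
    output_dir = config$output_dir,
    ascertainment_window = window,
    age_min = config$age_min, age_max = config$age_max,
    rf = config$rf, k_grid = config$k_grid,
    target_outcome = config$target_outcome,
    reference_conditions = config$reference_conditions,
    strat_grid_times = config$strat_grid_times,
    min_group_size = config$min_group_size,
    outcomes = config$outcomes, horizons = config$horizons,
    seed = config$seed)
  run_pipeline(cfg)
}
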