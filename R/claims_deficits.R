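# Claims readers, cohort filter, and the deficit-ascertainment rule.
#
# A diagnosis counts as a deficit only when the subject has at least three
# outpatient claim records or at least one inpatient claim record for that
# condition inside the baseline ascertainment window — the standard
# claims-validation convention for administrative data.

#' Read a claims file
#'
#' Expects CSV columns `subject_id`, `service_date` (ISO-8601), `setting`
#' (OUTPATIENT or INPATIENT, case-insensitive) and `icd9`. Malformed rows
#' are reported with their line numbers and abort the run.
#'
#' @param path Path to the claims CSV.
#' @return A tibble of claim records with `setting` normalized to lower
#'   case and `service_date` as `Date`.
#' @export
read_claims <- function(path) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("subject_id", "service_date", "setting", "icd9")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("claims file schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  setting <- tolower(raw$setting)
  bad_setting <- which(!setting %in% c("outpatient", "inpatient"))
  date <- as.Date(raw$service_date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date) & !is.na(raw$service_date) & raw$service_date != "")
  bad_na_date <- which(is.na(raw$service_date) | raw$service_date == "")
  errs <- character(0)
  if (length(bad_setting) > 0)
    errs <- c(errs, paste0("line ", bad_setting + 1L, ": invalid setting \"",
                           raw$setting[bad_setting], "\""))
  for (i in union(bad_date, bad_na_date))
    errs <- c(errs, paste0("line ", i + 1L, ": unparseable service_date \"",
                           raw$service_date[i], "\""))
  if (length(errs) > 0)
    stop("claims file ", path, " has ", length(errs), " malformed row(s):\n  ",
         paste(utils::head(sort(errs), 20), collapse = "\n  "), call. = FALSE)
  tibble::tibble(subject_id = raw$subject_id, service_date = date,
                 setting = setting, icd9 = raw$icd9)
}

#' Read a subject registry file
#'
#' Expects CSV columns `subject_id`, `age_at_baseline`, `sex` (M/F),
#' `followup_start`, `death_date`, `first_unplanned_hosp_date`,
#' `first_icu_date`, `admin_censor_date`; empty date fields mean the event
#' was not observed.
#'
#' @param path Path to the registry CSV.
#' @return A tibble of subject records.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  date_cols <- c("followup_start", "death_date", "first_unplanned_hosp_date",
                 "first_icu_date", "admin_censor_date")
  reg <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    age_at_baseline = readr::col_integer(),
    sex = readr::col_character(),
    .default = readr::col_date(format = "%Y-%m-%d")
  ), progress = FALSE)
  need <- c("subject_id", "age_at_baseline", "sex", date_cols)
  missing_cols <- setdiff(need, names(reg))
  if (length(missing_cols) > 0)
    stop("registry file schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_sex <- which(!reg$sex %in% c("M", "F"))
  if (length(bad_sex) > 0)
    stop("registry file has invalid sex value(s) at line(s) ",
         paste(utils::head(bad_sex + 1L, 10), collapse = ", "), call. = FALSE)
  reg[, need]
}

#' Read a condition catalog
#'
#' CSV with columns `condition_id`, `icd9_prefixes` (semicolon-separated
#' ICD-9-CM code prefixes) and `label`.
#'
#' @param path Path to the catalog CSV.
#' @return A tibble catalog.
#' @export
read_catalog <- function(path) {
  cat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("condition_id", "icd9_prefixes", "label")
  missing_cols <- setdiff(need, names(cat))
  if (length(missing_cols) > 0)
    stop("catalog schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(cat$condition_id))
    stop("catalog has duplicated condition_id values", call. = FALSE)
  if (any(is.na(cat$icd9_prefixes) | cat$icd9_prefixes == ""))
    stop("catalog has empty icd9_prefixes", call. = FALSE)
  cat[, need]
}

#' Filter a subject registry to an age band
#'
#' Retains subjects with `age_min <= age_at_baseline <= age_max`
#' (boundaries inclusive, e.g. 65 to 100 keeps both 65 and 100).
#'
#' @param subjects Registry tibble.
#' @param age_min,age_max Inclusive age bounds in years.
#' @return The filtered registry; the retention count is reported as a
#'   message.
#' @export
filter_cohort <- function(subjects, age_min = 65, age_max = 100) {
  if (age_min > age_max)
    stop("configuration error: age_min (", age_min, ") exceeds age_max (",
         age_max, ")", call. = FALSE)
  kept <- dplyr::filter(subjects, .data$age_at_baseline >= age_min,
                        .data$age_at_baseline <= age_max)
  message("cohort filter [", age_min, ", ", age_max, "]: retained ",
          nrow(kept), " of ", nrow(subjects), " subjects")
  kept
}

# ICD-9-CM normalization: strip dots and spaces, upper-case (V/E codes).
normalize_icd9 <- function(code) {
  toupper(gsub("[. ]", "", code))
}

# A claim code matches a prefix when its normalized form starts with the
# normalized prefix; bare 3-digit families therefore capture every subcode
# of the family ("250" matches "250", "250.01" and "2500" = "250.0").
icd9_prefix_match <- function(codes, prefixes) {
  ncode <- normalize_icd9(codes)
  hit <- rep(FALSE, length(ncode))
  for (pref in normalize_icd9(prefixes)) {
    hit <- hit | startsWith(ncode, pref)
  }
  hit
}

#' Ascertain binary deficits from claims
#'
#' Marks condition `c` present for subject `s` when, inside the
#' ascertainment window, `s` has at least 3 outpatient claim records or at
#' least 1 inpatient claim record whose ICD-9 code matches one of `c`'s
#' prefixes. Claim rows are first deduplicated on (subject, date, setting,
#' code) to guard against file artifacts, so claim records are distinct
#' encounters. Rows are produced for every registry subject (all-zero for
#' subjects without qualifying claims); claims for subjects absent from the
#' registry raise a warning and are dropped.
#'
#' @param claims Claims tibble (see [read_claims()]).
#' @param catalog Condition catalog tibble (see [read_catalog()]).
#' @param window Two dates, the closed ascertainment interval.
#' @param subjects Optional registry tibble fixing the row universe; when
#'   omitted the subjects observed in `claims` are used.
#' @return A `deficit_matrix`: list with `values` (binary integer matrix,
#'   subjects x conditions), and `window`.
#' @export
ascertain_deficits <- function(claims, catalog, window, subjects = NULL) {
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  window <- as.Date(window)
  if (length(window) != 2 || anyNA(window) || window[2] < window[1])
    stop("window must be a closed [start, end] date interval", call. = FALSE)
  subj_ids <- if (!is.null(subjects)) subjects$subject_id else
    sort(unique(claims$subject_id))
  if (anyDuplicated(subj_ids))
    stop("duplicated subject ids in registry", call. = FALSE)

  cl <- dplyr::distinct(claims, .data$subject_id, .data$service_date,
                        .data$setting, .data$icd9)
  cl <- dplyr::filter(cl, .data$service_date >= window[1],
                      .data$service_date <= window[2])
  orphan <- setdiff(unique(cl$subject_id), subj_ids)
  if (length(orphan) > 0) {
    warning(length(orphan), " subject(s) present in claims but absent from ",
            "the registry; their claims are ignored", call. = FALSE)
    cl <- dplyr::filter(cl, .data$subject_id %in% subj_ids)
  }

  values <- matrix(0L, length(subj_ids), nrow(catalog),
                   dimnames = list(subj_ids, catalog$condition_id))
  if (nrow(cl) > 0) {
    for (k in seq_len(nrow(catalog))) {
      prefixes <- strsplit(catalog$icd9_prefixes[k], ";", fixed = TRUE)[[1]]
      sub <- cl[icd9_prefix_match(cl$icd9, prefixes), ]
      if (nrow(sub) == 0) next
      tal <- dplyr::summarise(
        dplyr::group_by(sub, .data$subject_id),
        n_out = sum(.data$setting == "outpatient"),
        n_in = sum(.data$setting == "inpatient"),
        .groups = "drop")
      hit <- tal$subject_id[tal$n_out >= 3 | tal$n_in >= 1]
      values[hit, k] <- 1L
    }
  }
  structure(list(values = values, window = window), class = "deficit_matrix")
}

#' @export
print.deficit_matrix <- function(x, ...) {
  cat("Deficit matrix:", nrow(x$values), "subjects x", ncol(x$values),
      "conditions; window", format(x$window[1]), "to", format(x$window[2]), "\n")
  cat("Overall deficit prevalence:",
      signif(mean(x$values), 3), "\n")
  invisible(x)
}

#' Write a deficit matrix
#'
#' Writes the wide form (subject_id plus one 0/1 column per condition) and,
#' optionally, a sparse triplet form (`subject_id`, `condition_id`,
#' `value`) listing only the ones.
#'
#' @param dm A `deficit_matrix`.
#' @param path Output CSV path for the wide form.
#' @param triplet_path Optional output path for the sparse triplet form.
#' @return Invisibly, the path(s) written.
#' @export
write_deficit_matrix <- function(dm, path, triplet_path = NULL) {
  wide <- tibble::as_tibble(dm$values)
  wide <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(dm$values)), wide)
  readr::write_csv(wide, path)
  out <- path
  if (!is.null(triplet_path)) {
    idx <- which(dm$values == 1L, arr.ind = TRUE)
    trip <- tibble::tibble(subject_id = rownames(dm$values)[idx[, 1]],
                           condition_id = colnames(dm$values)[idx[, 2]],
                           value = 1L)
    trip <- dplyr::arrange(trip, .data$subject_id, .data$condition_id)
    readr::write_csv(trip, triplet_path)
    out <- c(out, triplet_path)
  }
  invisible(out)
}
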