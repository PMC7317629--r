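claims_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "claims.csv")
  writeLines(c("subject_id,service_date,setting,icd9", lines), path)
  path
}

test_that("read_claims parses well-formed files and rejects bad rows", {
  p <- claims_file(c("S1,2005-01-02,OUTPATIENT,250.01",
                     "S1,2005-02-03,outpatient,250.11",
                     "S2,2005-03-04,INPATIENT,374"))
  cl <- read_claims(p)
  expect_equal(nrow(cl), 3)
  expect_setequal(unique(cl$setting), c("outpatient", "inpatient"))
  expect_s3_class(cl$service_date, "Date")

  expect_error(read_claims(claims_file("S1,2005-01-02,ER,250")), "ER")
  expect_error(read_claims(claims_file("S1,01/02/2005,OUTPATIENT,250")),
               "line 2.*service_date")

  empty <- claims_file(character(0))
  expect_equal(nrow(read_claims(empty)), 0)

  dir <- withr::local_tempdir()
  nocol <- file.path(dir, "bad.csv")
  writeLines(c("subject_id,service_date,setting", "S1,2005-01-02,OUTPATIENT"), nocol)
  expect_error(read_claims(nocol), "icd9")
})

test_that("filter_cohort keeps the closed age band and matches a row filter", {
  subj <- tibble::tibble(subject_id = paste0("S", 1:4),
                         age_at_baseline = c(64L, 65L, 100L, 101L))
  kept <- suppressMessages(filter_cohort(subj, 65, 100))
  expect_equal(kept$subject_id, c("S2", "S3"))
  expect_equal(nrow(suppressMessages(filter_cohort(subj[0, ], 65, 100))), 0)
  expect_error(filter_cohort(subj, 80, 70), "age_min")

  co <- simulate_cohort(sim_config(n_subjects = 50, seed = 4))
  got <- suppressMessages(filter_cohort(co$subjects, 65, 75))
  want <- co$subjects[co$subjects$age_at_baseline >= 65 &
                        co$subjects$age_at_baseline <= 75, ]
  expect_equal(got, want)
})

catalog_250 <- tibble::tibble(condition_id = "DM", icd9_prefixes = "250",
                              label = "diabetes mellitus")
window_2005 <- as.Date(c("2005-01-01", "2005-12-31"))

make_claims <- function(...) {
  rows <- list(...)
  tibble::tibble(
    subject_id = vapply(rows, `[[`, "", 1),
    service_date = as.Date(vapply(rows, `[[`, "", 2)),
    setting = vapply(rows, `[[`, "", 3),
    icd9 = vapply(rows, `[[`, "", 4)
  )
}

test_that("the 3-outpatient / 1-inpatient rule decides deficits", {
  # three outpatient claims in-window -> deficit present
  cl <- make_claims(list("S1", "2005-01-10", "outpatient", "250.01"),
                    list("S1", "2005-03-10", "outpatient", "250.01"),
                    list("S1", "2005-06-10", "outpatient", "250.02"))
  dm <- ascertain_deficits(cl, catalog_250, window_2005)
  expect_equal(dm$values["S1", "DM"], 1L)

  # only two outpatient claims -> no deficit
  dm2 <- ascertain_deficits(cl[1:2, ], catalog_250, window_2005)
  expect_equal(dm2$values["S1", "DM"], 0L)

  # a single inpatient claim suffices
  cl3 <- make_claims(list("S1", "2005-05-01", "inpatient", "250.00"))
  dm3 <- ascertain_deficits(cl3, catalog_250, window_2005)
  expect_equal(dm3$values["S1", "DM"], 1L)

  # claims outside the window are ignored
  cl4 <- make_claims(list("S1", "2004-12-31", "outpatient", "250"),
                     list("S1", "2005-01-10", "outpatient", "250"),
                     list("S1", "2006-01-01", "outpatient", "250"))
  dm4 <- ascertain_deficits(cl4, catalog_250, window_2005)
  expect_equal(dm4$values["S1", "DM"], 0L)
})

test_that("prefix matching works at the code-family boundary", {
  cat2 <- tibble::tibble(condition_id = c("DM", "VAX"),
                         icd9_prefixes = c("250", "V04"),
                         label = c("diabetes", "vaccination"))
  cl <- make_claims(list("S1", "2005-02-01", "inpatient", "250.01"),
                    list("S2", "2005-02-01", "inpatient", "2500"),
                    list("S3", "2005-02-01", "inpatient", "251.0"),
                    list("S4", "2005-02-01", "inpatient", "V04.8"))
  dm <- ascertain_deficits(cl, cat2, window_2005)
  expect_equal(dm$values["S1", "DM"], 1L)  # dotted subcode
  expect_equal(dm$values["S2", "DM"], 1L)  # "2500" normalizes to 250.0
  expect_equal(dm$values["S3", "DM"], 0L)  # different family
  expect_equal(dm$values["S4", "VAX"], 1L) # V-code literal prefix
  expect_equal(dm$values["S4", "DM"], 0L)
})

test_that("deficits are invariant to row order and duplicate rows", {
  co <- simulate_cohort(sim_config(n_subjects = 40, seed = 12, n_conditions = 8))
  w <- ascertain_window(co)
  base <- ascertain_deficits(co$claims, co$catalog, w, co$subjects)

  shuffled <- co$claims[rev(seq_len(nrow(co$claims))), ]
  expect_identical(ascertain_deficits(shuffled, co$catalog, w, co$subjects)$values,
                   base$values)

  duplicated_rows <- dplyr::bind_rows(co$claims, co$claims[1:20, ])
  expect_identical(ascertain_deficits(duplicated_rows, co$catalog, w,
                                      co$subjects)$values,
                   base$values)
})

test_that("claims for unknown subjects warn; registry subjects keep all-zero rows", {
  cl <- make_claims(list("GHOST", "2005-02-01", "inpatient", "250"))
  subj <- tibble::tibble(subject_id = c("S1", "S2"))
  expect_warning(dm <- ascertain_deficits(cl, catalog_250, window_2005, subj),
                 "absent from")
  expect_equal(rownames(dm$values), c("S1", "S2"))
  expect_true(all(dm$values == 0L))
})

test_that("ascertainment equals the brute-force tally on 100 synthetic subjects", {
  co <- simulate_cohort(sim_config(n_subjects = 100, seed = 21,
                                   n_conditions = 10))
  w <- ascertain_window(co)
  dm <- ascertain_deficits(co$claims, co$catalog, w, co$subjects)
  want <- oracle_deficits(co$claims, co$catalog, w, co$subjects$subject_id)
  expect_identical(dm$values, want)
})

test_that("deficit matrix writers emit wide and triplet forms", {
  vals <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("S1", "S2"), c("C1", "C2")))
  dm <- make_deficit_matrix(vals)
  dir <- withr::local_tempdir()
  wide_p <- file.path(dir, "wide.csv"); trip_p <- file.path(dir, "trip.csv")
  write_deficit_matrix(dm, wide_p, trip_p)
  wide <- readr::read_csv(wide_p, show_col_types = FALSE)
  expect_equal(wide$C1, c(1, 0))
  trip <- readr::read_csv(trip_p, show_col_types = FALSE)
  expect_equal(nrow(trip), 2)
  expect_setequal(paste(trip$subject_id, trip$condition_id),
                  c("S1 C1", "S2 C2"))
})
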