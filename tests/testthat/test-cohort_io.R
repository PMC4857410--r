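test_that("patient reader maps fields, rejects bad rows, reports duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,art_start_date,age_at_start,site_id,outcome_status",
    "P001,2007-03-15,34,ZCH,active",
    "P002,2007-13-40,30,ZCH,active", # unparseable date
    "P003,2007-05-01,-1,RHC,active", # invariant violation
    "P001,2008-01-01,40,RHC,unknown" # duplicate id
  ), path)
  pats <- read_patient_table(path)
  rep <- io_report(pats)

  expect_equal(pats$patient_id, "P001")
  expect_equal(pats$art_start_date, as.Date("2007-03-15"))
  expect_equal(pats$age_at_start, 34L)
  expect_equal(pats$outcome_status, "active")
  expect_equal(rep$n_rows_rejected, 2L)
  expect_equal(rep$n_duplicates, 1L)
  # reader never invents records
  expect_equal(nrow(pats) + rep$n_rows_rejected + rep$n_duplicates, rep$n_rows_in)
  expect_true(any(grepl("unparseable date", rep$issues$message)))
  expect_true(any(grepl("invalid age", rep$issues$message)))
})

test_that("missing columns and missing files are configuration errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,art_start_date", "P001,2007-03-15"), path)
  expect_error(read_patient_table(path), "age_at_start")
  expect_error(read_patient_table(file.path(tempdir(), "nope.csv")), "not found")
  # custom column mapping finds renamed columns
  writeLines(c(
    "id,started,age,clinic,status",
    "P001,2007-03-15,34,ZCH,active"
  ), path)
  pats <- read_patient_table(path, patient_columns(
    patient_id = "id", art_start_date = "started", age_at_start = "age",
    site_id = "clinic", outcome_status = "status"
  ))
  expect_equal(pats$patient_id, "P001")
})

test_that("visit reader sorts, collapses duplicates to the larger supply, enforces refill sizes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,visit_date,supply_weeks",
    "P002,2007-05-10,8",
    "P001,2007-03-29,4",
    "P001,2007-03-29,8", # duplicate patient/date
    "P001,2007-02-15,2",
    "P003,2007-04-01,5" # not a refill size
  ), path)
  vis <- read_visit_table(path)
  rep <- io_report(vis)

  expect_equal(vis$patient_id, c("P001", "P001", "P002"))
  expect_equal(vis$visit_date, as.Date(c("2007-02-15", "2007-03-29", "2007-05-10")))
  expect_equal(vis$supply_weeks[vis$visit_date == as.Date("2007-03-29")], 8L)
  expect_equal(rep$n_duplicates, 1L)
  expect_equal(rep$n_rows_rejected, 1L)
  expect_equal(nrow(vis) + rep$n_rows_rejected + rep$n_duplicates, rep$n_rows_in)

  # strict mode off admits any positive supply
  lax <- read_visit_table(path, strict = FALSE)
  expect_true("P003" %in% lax$patient_id)
  expect_error(read_visit_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("validate_cohort counts orphans, duplicates and empties", {
  pats <- tibble::tibble(
    patient_id = c("P1", "P2"), art_start_date = as.Date("2007-01-01"),
    age_at_start = 30L, site_id = "A", outcome_status = "active"
  )
  vis <- tibble::tibble(
    patient_id = c(rep("P1", 3), "P2", "P2"),
    visit_date = as.Date("2007-01-01") + c(0, 28, 56, 0, 28),
    supply_weeks = 4L
  )
  rep <- validate_cohort(pats, vis)
  expect_equal(rep$n_patients, 2L)
  expect_equal(rep$n_visits, 5L)
  expect_equal(rep$n_orphan_visits, 0L)
  expect_equal(rep$n_duplicate_visits, 0L)
  expect_length(rep$messages, 0L)

  vis_orphan <- dplyr::bind_rows(vis, tibble::tibble(
    patient_id = "GHOST", visit_date = as.Date("2007-02-01"), supply_weeks = 4L
  ))
  expect_equal(validate_cohort(pats, vis_orphan)$n_orphan_visits, 1L)

  empty <- validate_cohort(pats, vis[0, ])
  expect_equal(empty$n_visits, 0L)
  expect_true(any(grepl("empty", empty$messages)))
})

test_that("weekly table CSV round-trips losslessly and writes header-only when empty", {
  set.seed(101)
  ep <- make_episodes(sample(c(1:12, NA), 40, replace = TRUE))
  wt <- weekly_table(ep, max_week = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weekly_table(wt, path)
  back <- read_weekly_table(path)

  expect_equal(nrow(back), 12L)
  for (col in c("hazard", "cdf", "survival", "variance", "ci_low", "ci_high")) {
    expect_equal(back[[col]], wt[[col]], tolerance = 1e-6)
  }
  expect_equal(back$n_at_risk, wt$n_at_risk)

  write_weekly_table(wt[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^week,")
})
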