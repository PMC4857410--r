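test_that("expected return date is index date plus 7 days per supply week", {
  expect_equal(
    expected_return_date(as.Date("2007-03-01"), 4L), as.Date("2007-03-29")
  )
  expect_equal(
    expected_return_date(as.Date("2007-03-01"), 2L), as.Date("2007-03-15")
  )
  # 8-week supply traverses the 2008 leap day
  expect_equal(
    expected_return_date(as.Date("2008-02-01"), 8L), as.Date("2008-03-28")
  )
  expect_error(expected_return_date(as.Date("2007-03-01"), 0L), "positive")
})

test_that("days late compares actual to expected, censoring at study end", {
  # the 7-day boundary that defines a late return
  dl <- days_late(as.Date("2007-03-29"), as.Date("2007-04-05"), as.Date("2010-06-30"))
  expect_equal(dl$days, 7L)
  expect_true(dl$returned)

  on_time <- days_late(as.Date("2007-03-29"), as.Date("2007-03-29"), as.Date("2010-06-30"))
  expect_equal(on_time$days, 0L)
  expect_true(on_time$returned)

  cens <- days_late(as.Date("2007-03-29"), as.Date(NA), as.Date("2007-06-28"))
  expect_equal(cens$days, 91L)
  expect_false(cens$returned)

  expect_error(
    days_late(as.Date("2007-03-29"), as.Date(NA), as.Date("2007-03-01")),
    "censor"
  )
})

test_that("weeks late bins days into 1-week intervals, flooring at zero", {
  expect_equal(weeks_late(7L), 1L) # "at least 7 days" = >= 1 week late
  expect_equal(weeks_late(c(6L, 13L, 14L)), c(0L, 1L, 2L))
  expect_equal(weeks_late(63L), 9L)
  expect_equal(weeks_late(-3L), 0L)
  # interval k covers days [7k, 7k + 6]
  expect_equal(weeks_late(c(28L, 34L, 35L)), c(4L, 4L, 5L))
})

toy_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    art_start_date = as.Date("2007-02-01"),
    age_at_start = c(35L, 28L, 52L),
    site_id = "A",
    outcome_status = "active"
  )
  # P1: on-time return, then a final never-returned visit
  # P2: 7-days-late return (the episode), return visit excluded by window
  # P3: early return, return visit excluded by window
  visits <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
    visit_date = as.Date(c(
      "2007-02-01", "2007-03-01",
      "2007-02-01", "2007-03-08",
      "2007-02-01", "2007-02-14"
    )),
    supply_weeks = c(4L, 4L, 4L, 12L, 2L, 12L)
  )
  list(patients = patients, visits = visits)
}

test_that("episode builder reproduces a hand-enumerated toy cohort", {
  toy <- toy_cohort()
  cfg <- lateness_config(study_end = as.Date("2008-04-15"))
  out <- build_late_episodes(toy$patients, toy$visits, cfg)

  # exactly two episodes: P2's 7-days-late return and P1's never-return
  expect_equal(nrow(out$episodes), 2L)
  p2 <- out$episodes[out$episodes$patient_id == "P2", ]
  expect_true(p2$returned)
  expect_equal(p2$days_late, 7L)
  expect_equal(p2$return_week, 1L)
  p1 <- out$episodes[out$episodes$patient_id == "P1", ]
  expect_false(p1$returned)
  # at risk from expected return 2007-03-29 through study end 2008-04-15
  expect_equal(p1$days_late, 383L)
  expect_true(is.na(p1$return_week))

  log <- setNames(out$filter_log$n_removed, out$filter_log$filter)
  expect_equal(unname(log["on_time_or_early"]), 2L) # P1 day-0, P3 early
  expect_equal(unname(log["return_window"]), 2L) # both supply-12 returns
  expect_equal(sum(out$filter_log$n_removed) + nrow(out$episodes), out$n_candidate_visits)
})

test_that("patient-level filters remove under-age, out-of-window and known-outcome patients", {
  toy <- toy_cohort()
  extra <- tibble::tibble(
    patient_id = c("P4", "P5", "P6"),
    art_start_date = as.Date(c("2007-02-01", "2006-06-01", "2007-02-01")),
    age_at_start = c(14L, 40L, 40L),
    site_id = "A",
    outcome_status = c("active", "active", "transferred_out")
  )
  # each has one 10-weeks-late-looking visit pair
  extra_visits <- tibble::tibble(
    patient_id = rep(c("P4", "P5", "P6"), each = 2),
    visit_date = rep(as.Date(c("2007-02-01", "2007-05-11")), 3),
    supply_weeks = rep(c(4L, 12L), 3)
  )
  cfg <- lateness_config(study_end = as.Date("2008-04-15"))
  out <- build_late_episodes(
    dplyr::bind_rows(toy$patients, extra),
    dplyr::bind_rows(toy$visits, extra_visits), cfg
  )
  log <- setNames(out$filter_log$n_removed, out$filter_log$filter)
  expect_equal(unname(log["age"]), 2L) # both of P4's visits
  expect_equal(unname(log["initiation_window"]), 2L) # P5 started pre-study
  expect_equal(unname(log["outcome_excluded"]), 2L) # P6 transferred out
  expect_equal(nrow(out$episodes), 2L) # toy episodes unaffected
  expect_equal(sum(out$filter_log$n_removed) + nrow(out$episodes), out$n_candidate_visits)
})

test_that("episode set shrinks with the lateness threshold and grows with the window, always reconciling", {
  cohort <- simulate_cohort(sim_params(n_patients = 250, seed = 404))
  sizes <- integer(0)
  for (thr in c(7L, 14L, 21L)) {
    cfg <- lateness_config(late_threshold_days = thr)
    out <- build_late_episodes(cohort$patients, cohort$visits, cfg)
    expect_equal(
      sum(out$filter_log$n_removed) + nrow(out$episodes),
      out$n_candidate_visits
    )
    # every emitted episode is at/above threshold or never returned
    with(out$episodes, expect_true(all(days_late >= thr | !returned)))
    sizes <- c(sizes, nrow(out$episodes))
  }
  expect_true(all(diff(sizes) <= 0))

  short <- build_late_episodes(
    cohort$patients, cohort$visits,
    lateness_config(study_end = as.Date("2009-06-30"))
  )
  full <- build_late_episodes(cohort$patients, cohort$visits, lateness_config())
  expect_lte(nrow(short$episodes), nrow(full$episodes))
})
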