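# Minimal episode table from a vector of return-delay weeks (NA = never
# returned), the shape weekly_counts() consumes.
make_episodes <- function(delays) {
  returned <- !is.na(delays)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_along(delays)),
    returned = returned,
    return_week = as.integer(delays),
    days_late = ifelse(returned, 7L * as.integer(delays), NA_integer_)
  )
}

# Weekly-table stand-in from a hazard sequence (cdf via the product limit),
# for exercising the cut-off rule on hand-built shapes.
hazard_table <- function(h) {
  tibble::tibble(
    week = seq_along(h),
    hazard = h,
    cdf = 1 - cumprod(1 - h)
  )
}

# Hand-built hazard shaped like the program data: spikes at the 4- and
# 8-week refill cycles, then a sustained collapse from week 9 on.
fig_shaped_hazard <- function() {
  c(0.5, 0.2, 0.4, 0.45, 0.1, 0.05, 0.06, 0.3, 0.04, 0.03, 0.02, rep(0.04, 15))
}

# File-mode cohort whose analyzable episodes have delays 1, 1, 4, 9 weeks
# and one never-return, all dates worked out by hand. The four return
# visits fall inside the 12-month minimum window and are excluded, leaving
# exactly the five index episodes. Use with
# lateness_config(study_end = "2008-02-02", max_week = 10).
write_five_episode_cohort <- function(dir) {
  patients <- tibble::tibble(
    patient_id = sprintf("P%d", 1:5),
    art_start_date = "2007-01-04",
    age_at_start = 30L,
    site_id = "ZCH",
    outcome_status = "active"
  )
  # index visits 2007-01-04, supply 4 -> expected return 2007-02-01;
  # returns at expected + 7 * {1, 1, 4, 9} days; P5 never returns
  visits <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4", "P5"),
    visit_date = c(
      "2007-01-04", "2007-02-08",
      "2007-01-04", "2007-02-08",
      "2007-01-04", "2007-03-01",
      "2007-01-04", "2007-04-05",
      "2007-01-04"
    ),
    supply_weeks = c(4L, 12L, 4L, 12L, 4L, 12L, 4L, 12L, 4L)
  )
  pp <- file.path(dir, "patients.csv")
  vp <- file.path(dir, "visits.csv")
  readr::write_csv(patients, pp, progress = FALSE)
  readr::write_csv(visits, vp, progress = FALSE)
  list(patients = pp, visits = vp)
}

five_episode_config <- function() {
  lateness_config(study_end = as.Date("2008-02-02"), max_week = 10L)
}
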