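#' Lateness and cohort-filter configuration
#'
#' Bundles the constants that define a "late" follow-up visit and the
#' cohort inclusion window. A patient is late when they return at or after
#' `late_threshold_days` (7 days, the adherence convention in the Malawi
#' treatment guidelines) past the return date implied by the dispensed ART
#' supply. Only visits whose expected return falls at least
#' `min_return_window_days` before `study_end` enter the analysis, so every
#' episode has a full year in which a return could be observed — more than
#' the `max_week` = 26 weeks over which lateness is tabulated, which is why
#' no interior censoring is needed.
#'
#' @param late_threshold_days Days late at which a return counts as late.
#' @param max_week Last weekly lateness interval K tabulated; later returns
#'   pool into the ">= K weeks" tail.
#' @param study_start,study_end Eligibility window for ART initiation.
#' @param min_return_window_days Minimum observation time required after a
#'   visit's expected return date.
#' @param min_age Minimum age (years) at ART start.
#' @return A `lateness_config` list.
#' @export
lateness_config <- function(late_threshold_days = 7L,
                            max_week = 26L,
                            study_start = as.Date("2007-01-01"),
                            study_end = as.Date("2010-06-30"),
                            min_return_window_days = 365L,
                            min_age = 15L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(
    late_threshold_days >= 1, max_week >= 1,
    study_start < study_end,
    min_return_window_days >= 0, min_age >= 0
  )
  structure(
    list(
      late_threshold_days = as.integer(late_threshold_days),
      max_week = as.integer(max_week),
      study_start = study_start,
      study_end = study_end,
      min_return_window_days = as.integer(min_return_window_days),
      min_age = as.integer(min_age)
    ),
    class = "lateness_config"
  )
}

#' Expected return date implied by the dispensed supply
#'
#' A visit at which `supply_weeks` weeks of ART are dispensed implies a
#' return exactly `7 * supply_weeks` calendar days later.
#'
#' @param visit_date `Date` vector of index visit dates.
#' @param supply_weeks Integer vector of dispensed supply, in weeks.
#' @return A `Date` vector.
#' @export
expected_return_date <- function(visit_date, supply_weeks) {
  if (any(supply_weeks < 1, na.rm = TRUE)) {
    stop("supply_weeks must be a positive number of weeks", call. = FALSE)
  }
  as.Date(visit_date) + 7L * as.integer(supply_weeks)
}

#' Days late relative to the expected return
#'
#' Compares an actual return date to the expected one. When no return was
#' observed, lateness accrues up to the censoring date (the study end) and
#' `returned` is `FALSE`. Negative days mean an early return.
#'
#' @param expected `Date` vector of expected return dates.
#' @param actual_return `Date` vector of next-visit dates, `NA` where the
#'   patient never returned.
#' @param censor `Date` (scalar or vector): end of observation.
#' @return A tibble with integer `days` and logical `returned`.
#' @export
days_late <- function(expected, actual_return, censor) {
  expected <- as.Date(expected)
  actual_return <- as.Date(actual_return)
  censor <- as.Date(censor)
  returned <- !is.na(actual_return)
  if (any(!returned & censor < expected)) {
    stop("censor date precedes the expected return for a non-returned visit",
      call. = FALSE
    )
  }
  days <- ifelse(returned,
    as.integer(actual_return - expected),
    as.integer(censor - expected)
  )
  tibble::tibble(days = as.integer(days), returned = returned)
}

#' Weekly lateness interval
#'
#' Week interval `k` covers days `7k` to `7k + 6`; someone 7 days late is in
#' week 1 (">= 1 week late"). Early or on-time returns (days `< 7`,
#' including negative) fall in week 0.
#'
#' @param days Integer vector of days late.
#' @return Integer vector of weeks late.
#' @export
weeks_late <- function(days) {
  pmax(0L, as.integer(floor(days / 7)))
}

filter_order <- c(
  "orphan_visit", "age", "initiation_window", "outcome_excluded",
  "return_window", "on_time_or_early", "late_below_threshold"
)

#' Build the analyzable set of late follow-up episodes
#'
#' Applies the cohort filters and turns each qualifying follow-up visit into
#' a late episode. Patient-level filters (in order): age at ART start below
#' `min_age`; ART initiation outside `[study_start, study_end)`; a known
#' outcome of death, transfer out or stopped ART. Visit-level filters:
#' expected return later than `study_end - min_return_window_days` (so every
#' kept visit has at least a year of potential follow-up); and returns under
#' the lateness threshold (on-time/early, or 1–6 days late). "Returned"
#' means any later visit exists for that patient, regardless of that next
#' visit's own lateness; only a patient's final recorded visit can be a
#' non-returned episode. The analysis is visit-level: a patient contributes
#' one episode per qualifying late visit, with no clustering adjustment.
#'
#' @param patients,visits Cohort tables, see [read_patient_table()] and
#'   [read_visit_table()].
#' @param config A [lateness_config()].
#' @return A list with `episodes` (tibble: `patient_id`, `index_visit_date`,
#'   `supply_weeks`, `expected_return_date`, `days_late`, `returned`,
#'   `return_week`), `filter_log` (tibble `filter`, `n_removed`, in
#'   application order, counting candidate visits) and `n_candidate_visits`.
#'   Every candidate visit is accounted for:
#'   `sum(filter_log$n_removed) + nrow(episodes) == n_candidate_visits`.
#' @export
build_late_episodes <- function(patients, visits, config = lateness_config()) {
  stopifnot(inherits(config, "lateness_config"))
  excl <- c("died", "transferred_out", "stopped_art")

  v <- visits |>
    dplyr::arrange(.data$patient_id, .data$visit_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(next_visit_date = dplyr::lead(.data$visit_date)) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      patients[, c("patient_id", "art_start_date", "age_at_start", "outcome_status")],
      by = "patient_id"
    )

  v$expected <- expected_return_date(v$visit_date, v$supply_weeks)
  # a final visit may expect a return after study_end; such visits are
  # removed by the 12-month window filter below, so clamp the censor date
  dl <- days_late(v$expected, v$next_visit_date, pmax(config$study_end, v$expected))
  v$days_late <- dl$days
  v$returned <- dl$returned

  orphan <- is.na(v$art_start_date)
  fail_age <- !orphan & v$age_at_start < config$min_age
  seen <- orphan | fail_age
  fail_init <- !seen & (v$art_start_date < config$study_start |
    v$art_start_date >= config$study_end)
  seen <- seen | fail_init
  fail_outcome <- !seen & v$outcome_status %in% excl
  seen <- seen | fail_outcome
  window_cut <- config$study_end - config$min_return_window_days
  fail_window <- !seen & v$expected > window_cut
  seen <- seen | fail_window
  fail_on_time <- !seen & v$returned & v$days_late <= 0
  seen <- seen | fail_on_time
  fail_under <- !seen & v$returned & v$days_late > 0 &
    v$days_late < config$late_threshold_days
  keep <- !(seen | fail_under)

  filter_log <- tibble::tibble(
    filter = filter_order,
    n_removed = c(
      sum(orphan), sum(fail_age), sum(fail_init), sum(fail_outcome),
      sum(fail_window), sum(fail_on_time), sum(fail_under)
    )
  )

  episodes <- tibble::tibble(
    patient_id = v$patient_id[keep],
    index_visit_date = v$visit_date[keep],
    supply_weeks = v$supply_weeks[keep],
    expected_return_date = v$expected[keep],
    days_late = v$days_late[keep],
    returned = v$returned[keep],
    return_week = ifelse(v$returned[keep], weeks_late(v$days_late[keep]), NA_integer_)
  )
  episodes$return_week <- as.integer(episodes$return_week)

  if (nrow(episodes) == 0) {
    warning("no late episodes remain after filtering", call. = FALSE)
  }

  list(
    episodes = episodes,
    filter_log = filter_log,
    n_candidate_visits = nrow(v)
  )
}
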