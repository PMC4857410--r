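#' Default column mappings for the patient and visit tables
#'
#' The flat files exported from an ART register do not have a standardized
#' machine schema, so the readers take a column-name mapping. The defaults
#' use the canonical names below; override any entry to match your export.
#'
#' @param patient_id,art_start_date,age_at_start,site_id,outcome_status
#'   Column names in the patient file.
#' @return A named list mapping canonical field names to file column names.
#' @export
patient_columns <- function(patient_id = "patient_id",
                            art_start_date = "art_start_date",
                            age_at_start = "age_at_start",
                            site_id = "site_id",
                            outcome_status = "outcome_status") {
  list(
    patient_id = patient_id,
    art_start_date = art_start_date,
    age_at_start = age_at_start,
    site_id = site_id,
    outcome_status = outcome_status
  )
}

#' @rdname patient_columns
#' @param visit_date,supply_weeks Column names in the visit file.
#' @export
visit_columns <- function(patient_id = "patient_id",
                          visit_date = "visit_date",
                          supply_weeks = "supply_weeks") {
  list(
    patient_id = patient_id,
    visit_date = visit_date,
    supply_weeks = supply_weeks
  )
}

#' Recognized outcome statuses
#'
#' `died`, `transferred_out` and `stopped_art` are the statuses that exclude
#' a patient from the late-return analysis; `active` and `unknown` are kept.
#' @export
outcome_levels <- function() {
  c("active", "died", "transferred_out", "stopped_art", "unknown")
}

read_raw_csv <- function(path, mapping, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(unlist(mapping), names(raw))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s file %s is missing required column(s): %s",
      what, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  out <- raw[, unlist(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

parse_iso_date <- function(x) as.Date(x, format = "%Y-%m-%d")

new_issue <- function(row, field, message) {
  tibble::tibble(row = as.integer(row), field = field, message = message)
}

#' Read a patient table
#'
#' Reads a CSV of one row per patient on ART: identifier, ART start date
#' (ISO-8601), age at start, site, and known outcome status. Rows that fail
#' validation (unparseable date, negative age, unrecognized outcome) are
#' rejected row-by-row and reported, never silently dropped; duplicated
#' patient identifiers keep the first occurrence and are reported.
#'
#' @param path Path to the CSV file (header row required, UTF-8).
#' @param columns Column-name mapping, see [patient_columns()].
#' @return A tibble with columns `patient_id`, `art_start_date` (`Date`),
#'   `age_at_start` (integer), `site_id`, `outcome_status`. The attached
#'   `"io_report"` attribute (see [io_report()]) records rows in, rows
#'   rejected, duplicates dropped, and per-row issue messages.
#' @export
read_patient_table <- function(path, columns = patient_columns()) {
  raw <- read_raw_csv(path, columns, "patient")
  n_in <- nrow(raw)
  issues <- list()

  start <- parse_iso_date(raw$art_start_date)
  age <- suppressWarnings(as.integer(raw$age_at_start))
  status <- ifelse(is.na(raw$outcome_status) | raw$outcome_status == "",
    "unknown", raw$outcome_status
  )

  bad_date <- is.na(start)
  bad_age <- !bad_date & (is.na(age) | age < 0)
  bad_status <- !bad_date & !bad_age & !(status %in% outcome_levels())
  for (i in which(bad_date)) {
    issues[[length(issues) + 1L]] <-
      new_issue(i, "art_start_date", sprintf("unparseable date '%s'", raw$art_start_date[i]))
  }
  for (i in which(bad_age)) {
    issues[[length(issues) + 1L]] <-
      new_issue(i, "age_at_start", sprintf("invalid age '%s'", raw$age_at_start[i]))
  }
  for (i in which(bad_status)) {
    issues[[length(issues) + 1L]] <-
      new_issue(i, "outcome_status", sprintf("unrecognized outcome '%s'", raw$outcome_status[i]))
  }

  keep <- !(bad_date | bad_age | bad_status)
  out <- tibble::tibble(
    patient_id = raw$patient_id[keep],
    art_start_date = start[keep],
    age_at_start = age[keep],
    site_id = raw$site_id[keep],
    outcome_status = status[keep]
  )

  dup <- duplicated(out$patient_id)
  n_dup <- sum(dup)
  for (i in which(dup)) {
    issues[[length(issues) + 1L]] <-
      new_issue(i, "patient_id", sprintf("duplicate patient_id '%s' (first kept)", out$patient_id[i]))
  }
  out <- out[!dup, , drop = FALSE]

  attr(out, "io_report") <- list(
    n_rows_in = n_in,
    n_rows_rejected = n_in - sum(keep),
    n_duplicates = n_dup,
    issues = if (length(issues)) dplyr::bind_rows(issues) else new_issue(integer(), character(), character())
  )
  out
}

#' Read a visit table
#'
#' Reads a CSV of one row per clinic follow-up visit: patient identifier,
#' visit date (ISO-8601) and the ART supply dispensed, in weeks. Rows are
#' returned sorted by `(patient_id, visit_date)`. Duplicate rows for the
#' same patient and date are collapsed to a single visit keeping the larger
#' supply (the conservative choice: a longer expected gap flags fewer false
#' "late" returns) and counted in the report.
#'
#' @inheritParams read_patient_table
#' @param columns Column-name mapping, see [visit_columns()].
#' @param strict If `TRUE` (default) the dispensed supply must be one of the
#'   program's refill sizes 2, 4, 8 or 12 weeks; if `FALSE` any positive
#'   integer is accepted.
#' @return A tibble with columns `patient_id`, `visit_date` (`Date`) and
#'   `supply_weeks` (integer), with an `"io_report"` attribute as in
#'   [read_patient_table()].
#' @export
read_visit_table <- function(path, columns = visit_columns(), strict = TRUE) {
  raw <- read_raw_csv(path, columns, "visit")
  n_in <- nrow(raw)
  issues <- list()

  date <- parse_iso_date(raw$visit_date)
  supply <- suppressWarnings(as.integer(raw$supply_weeks))

  bad_date <- is.na(date)
  bad_supply <- !bad_date & (is.na(supply) | supply < 1 |
    (strict & !(supply %in% c(2L, 4L, 8L, 12L))))
  for (i in which(bad_date)) {
    issues[[length(issues) + 1L]] <-
      new_issue(i, "visit_date", sprintf("unparseable date '%s'", raw$visit_date[i]))
  }
  for (i in which(bad_supply)) {
    issues[[length(issues) + 1L]] <-
      new_issue(i, "supply_weeks", sprintf("invalid supply '%s'", raw$supply_weeks[i]))
  }

  keep <- !(bad_date | bad_supply)
  out <- tibble::tibble(
    patient_id = raw$patient_id[keep],
    visit_date = date[keep],
    supply_weeks = supply[keep]
  )

  # collapse same patient/date to the larger supply
  n_valid <- nrow(out)
  out <- out |>
    dplyr::group_by(.data$patient_id, .data$visit_date) |>
    dplyr::summarise(supply_weeks = max(.data$supply_weeks), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$visit_date)
  n_dup <- n_valid - nrow(out)
  if (n_dup > 0) {
    issues[[length(issues) + 1L]] <- new_issue(
      NA_integer_, "visit_date",
      sprintf("%d duplicate patient/date visit row(s) collapsed to the larger supply", n_dup)
    )
  }

  attr(out, "io_report") <- list(
    n_rows_in = n_in,
    n_rows_rejected = n_in - sum(keep),
    n_duplicates = n_dup,
    issues = if (length(issues)) dplyr::bind_rows(issues) else new_issue(integer(), character(), character())
  )
  out
}

#' Row-level read report attached by the table readers
#'
#' @param x A table returned by [read_patient_table()] or [read_visit_table()].
#' @return A list with `n_rows_in`, `n_rows_rejected`, `n_duplicates` and an
#'   `issues` tibble. Satisfies
#'   `nrow(x) + n_rows_rejected + n_duplicates == n_rows_in`.
#' @export
io_report <- function(x) {
  rep <- attr(x, "io_report", exact = TRUE)
  if (is.null(rep)) {
    rep <- list(
      n_rows_in = nrow(x), n_rows_rejected = 0L, n_duplicates = 0L,
      issues = new_issue(integer(), character(), character())
    )
  }
  rep
}

#' Cross-check the loaded cohort
#'
#' Joins the two tables and reports structural problems: visit rows whose
#' patient is absent from the patient table (orphans), duplicate visits
#' collapsed at read time, and visits dated before the patient's ART start.
#' Orphans and duplicates are warnings; the pipeline refuses to continue
#' only when a table is structurally unusable.
#'
#' @param patients,visits Tables from [read_patient_table()] /
#'   [read_visit_table()] (or equivalently-shaped tibbles).
#' @return A `validation_report`: list with `n_patients`, `n_visits`,
#'   `n_orphan_visits`, `n_duplicate_visits` and `messages`.
#' @export
validate_cohort <- function(patients, visits) {
  msgs <- character()
  n_orphan <- sum(!visits$patient_id %in% patients$patient_id)
  n_dup <- io_report(visits)$n_duplicates

  if (nrow(visits) == 0) {
    msgs <- c(msgs, "visit table is empty")
  }
  if (nrow(patients) == 0) {
    msgs <- c(msgs, "patient table is empty")
  }
  if (n_orphan > 0) {
    msgs <- c(msgs, sprintf("%d visit(s) reference a patient_id absent from the patient table", n_orphan))
  }
  if (n_dup > 0) {
    msgs <- c(msgs, sprintf("%d duplicate visit row(s) were collapsed at read time", n_dup))
  }
  joined <- dplyr::inner_join(
    visits, patients[, c("patient_id", "art_start_date")],
    by = "patient_id"
  )
  n_before_start <- sum(joined$visit_date < joined$art_start_date)
  if (n_before_start > 0) {
    msgs <- c(msgs, sprintf("%d visit(s) dated before the patient's ART start", n_before_start))
  }

  structure(
    list(
      n_patients = nrow(patients),
      n_visits = nrow(visits),
      n_orphan_visits = n_orphan,
      n_duplicate_visits = n_dup,
      messages = msgs
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Cohort: %d patients, %d visits (%d orphan, %d duplicate)\n",
    x$n_patients, x$n_visits, x$n_orphan_visits, x$n_duplicate_visits
  ))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

weekly_table_columns <- c(
  "week", "n_at_risk", "n_returned", "hazard", "cdf", "survival",
  "variance", "ci_low", "ci_high"
)

#' Write / read the weekly estimates table
#'
#' The CSV carries exactly the columns `week, n_at_risk, n_returned, hazard,
#' cdf, survival, variance, ci_low, ci_high` and round-trips losslessly with
#' [read_weekly_table()] at better than 1e-6.
#'
#' @param table A weekly table from [weekly_table()].
#' @param path Output CSV path.
#' @export
write_weekly_table <- function(table, path) {
  missing <- setdiff(weekly_table_columns, names(table))
  if (length(missing) > 0) {
    stop("weekly table is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  readr::write_csv(table[, weekly_table_columns], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_weekly_table
#' @export
read_weekly_table <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      week = readr::col_integer(),
      n_at_risk = readr::col_integer(),
      n_returned = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
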