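#' Parameters of the synthetic ART cohort generator
#'
#' Defines the generative model the simulator draws from. Each patient
#' starts ART uniformly over the study window and follows the program's
#' refill schedule: a 2-week first supply, 4-week (monthly) supplies
#' through the first 6 months, then 8- or 12-week supplies. At each visit
#' the return behaviour is drawn: with `p_on_time` the patient returns
#' within 0–6 days of the expected date; otherwise the visit is late, and
#' with `p_never_given_late` the patient never returns, else the return
#' delay in weeks is drawn from a three-part mixture — a geometric "drift
#' back in" component plus refill-cycle modes at 4 and 8 weeks (each
#' spread over the neighbouring week by a symmetric jitter) — with days
#' within the drawn week uniform. A fraction `p_death_early` of patients
#' dies within 90 days of starting ART; a death is recorded in
#' `outcome_status` only with probability `p_known_outcome`, so most deaths
#' manifest to the pipeline as unlabelled never-returners, reproducing the
#' overestimation of LTFU that poor death ascertainment causes.
#'
#' Delay weeks above `max_delay_week` are folded onto `max_delay_week`
#' (default 25), keeping the true delay distribution strictly inside the
#' 26-week tabulation range so the never-return mass is identifiable from
#' the CDF's asymptote.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param study_start,study_end Study window (ART starts are uniform on it).
#' @param p_on_time Probability a follow-up return is less than 7 days late.
#' @param p_never_given_late Probability a late episode never returns.
#' @param w_early,p_geom Weight and success probability of the geometric
#'   (weeks 1, 2, 3, ...) component of the late-delay mixture.
#' @param w_four,w_eight Weights of the 4- and 8-week refill-cycle modes.
#' @param jitter Length-3 probabilities spreading each mode to (mode - 1,
#'   mode, mode + 1) weeks.
#' @param max_delay_week Cap: mixture mass above this week folds onto it.
#' @param p_death_early Probability a patient dies within 90 days of ART
#'   start *and* that death surfaces in the register only as an unexplained
#'   never-return (deaths occurring before any follow-up visit, or
#'   ascertained and recorded, are not this parameter's job; it models the
#'   residual contamination of the late-episode set).
#' @param p_known_outcome Probability a death is recorded in the register.
#' @param p_supply_12 Probability the post-6-month refill is 12 weeks
#'   rather than 8.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_patients = 5000L,
                       seed = 1L,
                       study_start = as.Date("2007-01-01"),
                       study_end = as.Date("2010-06-30"),
                       p_on_time = 0.83,
                       p_never_given_late = 0.30,
                       w_early = 0.5,
                       p_geom = 0.45,
                       w_four = 0.3,
                       w_eight = 0.2,
                       jitter = c(0.25, 0.5, 0.25),
                       max_delay_week = 25L,
                       p_death_early = 0.01,
                       p_known_outcome = 0.3,
                       p_supply_12 = 0.3) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  probs <- c(
    p_on_time, p_never_given_late, p_geom, p_death_early,
    p_known_outcome, p_supply_12
  )
  stopifnot(
    n_patients >= 1,
    study_start < study_end,
    all(probs >= 0 & probs <= 1), p_geom > 0,
    w_early >= 0, w_four >= 0, w_eight >= 0,
    length(jitter) == 3, all(jitter >= 0), sum(jitter) > 0,
    max_delay_week >= 1
  )
  if (abs(w_early + w_four + w_eight - 1) > 1e-8) {
    stop("mixture weights w_early + w_four + w_eight must sum to 1", call. = FALSE)
  }
  if (as.integer(study_end - study_start) < 14L) {
    stop("study window is shorter than the first 2-week refill", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      study_start = study_start, study_end = study_end,
      p_on_time = p_on_time, p_never_given_late = p_never_given_late,
      w_early = w_early, p_geom = p_geom,
      w_four = w_four, w_eight = w_eight,
      jitter = jitter / sum(jitter),
      max_delay_week = as.integer(max_delay_week),
      p_death_early = p_death_early, p_known_outcome = p_known_outcome,
      p_supply_12 = p_supply_12
    ),
    class = "sim_params"
  )
}

#' Probability mass function of the late-return delay mixture
#'
#' Closed form over weeks `1..max_delay_week`: geometric component
#' `p (1-p)^(k-1)` with its tail beyond the cap folded onto the cap, plus
#' the jittered 4- and 8-week modes (jitter mass falling outside
#' `[1, max_delay_week]` folds onto the nearest in-range week). Sums to 1
#' exactly.
#'
#' @param params A [sim_params()].
#' @return Numeric vector of length `max_delay_week`; entry k is the
#'   probability an eventual returner's delay is k weeks.
#' @export
late_delay_pmf <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  K <- params$max_delay_week
  geo <- stats::dgeom(0:(K - 1), params$p_geom)
  geo[K] <- geo[K] + stats::pgeom(K - 1, params$p_geom, lower.tail = FALSE)

  mode_pmf <- function(mode) {
    out <- numeric(K)
    wk <- pmin(pmax(mode + (-1:1), 1L), K) # fold out-of-range jitter inward
    for (i in 1:3) out[wk[i]] <- out[wk[i]] + params$jitter[i]
    out
  }
  pmf <- params$w_early * geo +
    params$w_four * mode_pmf(4L) +
    params$w_eight * mode_pmf(8L)
  pmf / sum(pmf)
}

#' True return CDF of the late-episode population
#'
#' Closed form `(1 - p_never_given_late) * P(delay <= k)` under the
#' generator's delay mixture — the quantity the estimated weekly CDF
#' targets. Monotone non-decreasing with limit `1 - p_never_given_late`.
#'
#' @param params A [sim_params()].
#' @param week Integer vector of weeks-late values k.
#' @return Probability vector, same length as `week`.
#' @export
true_cdf <- function(params, week) {
  pmf <- late_delay_pmf(params)
  cum <- c(0, cumsum(pmf))
  idx <- pmin(pmax(as.integer(week), 0L), params$max_delay_week) + 1L
  (1 - params$p_never_given_late) * cum[idx]
}

#' Draw late-return delays (in weeks) from the mixture
#'
#' @param n Number of draws.
#' @param params A [sim_params()].
#' @return Integer vector of delay weeks in `1..max_delay_week`.
#' @export
rlate_delay <- function(n, params) {
  sample.int(params$max_delay_week, n, replace = TRUE, prob = late_delay_pmf(params))
}

#' Simulate late episodes directly
#'
#' Draws `n` analyzable late episodes from the generator's return model,
#' bypassing the visit-schedule machinery: each episode never returns with
#' `p_never_given_late`, otherwise its return week comes from the delay
#' mixture. Useful for estimator calibration studies where only the
#' episode-level distribution matters.
#'
#' @param n Number of episodes.
#' @param params A [sim_params()].
#' @return An episode tibble compatible with [weekly_counts()].
#' @export
simulate_episodes <- function(n, params = sim_params()) {
  returned <- stats::runif(n) >= params$p_never_given_late
  week <- rep(NA_integer_, n)
  week[returned] <- rlate_delay(sum(returned), params)
  tibble::tibble(
    patient_id = sprintf("E%06d", seq_len(n)),
    returned = returned,
    return_week = week,
    days_late = ifelse(returned, 7L * week, NA_integer_)
  )
}

# supply dispensed at a visit: 2-week first refill, 4-week through the
# first 26 weeks on ART, then 8 or 12 weeks
draw_supply <- function(visit_number, weeks_on_art, p_supply_12) {
  n <- length(visit_number)
  s <- ifelse(visit_number == 1L, 2L, ifelse(weeks_on_art < 26, 4L, 8L))
  long <- visit_number > 1L & weeks_on_art >= 26
  n_long <- sum(long)
  if (n_long > 0) {
    s[long] <- ifelse(stats::runif(n_long) < p_supply_12, 12L, 8L)
  }
  as.integer(s)
}

#' Simulate a synthetic ART cohort
#'
#' Generates patient and visit tables with the statistical structure the
#' late-return analysis assumes (see [sim_params()] for the model), plus a
#' truth record for parameter-recovery checks. Visit sequences cascade
#' from actual return dates: each next expected visit is the actual
#' previous visit date plus 7 times the dispensed supply, and the actual
#' next visit adds the drawn delay. Sequences end when the patient draws a
#' never-return, dies before the next visit, or the next visit would fall
#' after the study end. The truth record keeps the *intended* delay of
#' every dispensed visit, including intentions cut short by death or study
#' end, so the observable estimates can be compared against the generative
#' truth.
#'
#' @param params A [sim_params()]. All randomness is governed by
#'   `params$seed`; the same parameters reproduce the same cohort exactly.
#' @return A list: `patients`, `visits` (tibbles in the dialects
#'   [read_patient_table()] / [read_visit_table()] read and write),
#'   `truth` (per dispensed visit: intended status `on_time` / `late` /
#'   `never`, intended delay week, and whether death or the study end
#'   truncated the intention) and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  window_days <- as.integer(params$study_end - params$study_start)

  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    art_start_date = params$study_start +
      sample.int(window_days, n, replace = TRUE) - 1L,
    age_at_start = sample(10:70, n, replace = TRUE),
    site_id = sample(sprintf("S%02d", 1:22), n, replace = TRUE),
    outcome_status = "active"
  )

  dies <- stats::runif(n) < params$p_death_early
  death_date <- rep(as.Date(NA), n)
  death_date[dies] <- patients$art_start_date[dies] +
    sample.int(90L, sum(dies), replace = TRUE)
  known <- dies & stats::runif(n) < params$p_known_outcome
  patients$outcome_status[known] <- "died"

  visits <- vector("list", 0L)
  truth <- vector("list", 0L)
  cur <- patients$art_start_date
  active <- rep(TRUE, n)
  # patients who die before their first (initiation) visit never enter care
  active[dies & death_date <= cur] <- FALSE
  visit_number <- rep(1L, n)

  while (any(active)) {
    idx <- which(active)
    date_i <- cur[idx]
    weeks_on <- as.numeric(date_i - patients$art_start_date[idx]) / 7
    supply <- draw_supply(visit_number[idx], weeks_on, params$p_supply_12)

    m <- length(idx)
    on_time <- stats::runif(m) < params$p_on_time
    never <- !on_time & stats::runif(m) < params$p_never_given_late
    late_ret <- !on_time & !never
    delay_week <- rep(NA_integer_, m)
    delay_week[late_ret] <- rlate_delay(sum(late_ret), params)
    within_week_days <- sample(0:6, m, replace = TRUE)
    delay_days <- ifelse(on_time, within_week_days,
      ifelse(never, NA_integer_, 7L * delay_week + within_week_days)
    )

    expected <- date_i + 7L * supply
    next_date <- expected + delay_days # NA for never-returners
    dd <- death_date[idx]
    dies_before_next <- !is.na(dd) & (is.na(next_date) | next_date >= dd)
    past_end <- !is.na(next_date) & next_date > params$study_end

    visits[[length(visits) + 1L]] <- tibble::tibble(
      patient_id = patients$patient_id[idx],
      visit_date = date_i,
      supply_weeks = supply
    )
    truth[[length(truth) + 1L]] <- tibble::tibble(
      patient_id = patients$patient_id[idx],
      visit_date = date_i,
      intended_status = ifelse(never, "never", ifelse(on_time, "on_time", "late")),
      intended_delay_week = ifelse(on_time, 0L, delay_week),
      died_before_return = dies_before_next,
      truncated_by_study_end = !dies_before_next & past_end
    )

    keep_going <- !never & !dies_before_next & !past_end
    cur[idx[keep_going]] <- next_date[keep_going]
    visit_number[idx[keep_going]] <- visit_number[idx[keep_going]] + 1L
    active[idx[!keep_going]] <- FALSE
  }

  visits <- dplyr::arrange(dplyr::bind_rows(visits), .data$patient_id, .data$visit_date)
  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$patient_id, .data$visit_date)
  list(patients = patients, visits = visits, truth = truth, params = params)
}

#' Write a simulated cohort to CSV
#'
#' Emits the exact dialects [read_patient_table()] and [read_visit_table()]
#' read, so the file-mode pipeline runs unchanged on simulated data.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  vp <- file.path(dir, "visits.csv")
  readr::write_csv(cohort$patients, pp, progress = FALSE)
  readr::write_csv(cohort$visits, vp, progress = FALSE)
  invisible(c(patients = pp, visits = vp))
}
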