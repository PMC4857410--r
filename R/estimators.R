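#' Weekly risk-set and return counts
#'
#' Tabulates the late-episode set over weekly lateness intervals
#' `k = 1..max_week`: `n_at_risk` is the number of episodes still out at the
#' start of week `k` (returned in week `k` or later, or never returned) and
#' `n_returned` the number returning during week `k`. There is no interior
#' censoring, so the risk set satisfies `n_{k+1} = n_k - d_k`; episodes
#' returning after `max_week` stay in every risk set (the right tail is
#' pooled into the ">= K" category), and never-returners stay at risk
#' throughout.
#'
#' @param episodes Episode tibble from [build_late_episodes()] (needs
#'   logical `returned` and integer `return_week`).
#' @param max_week Number of weekly intervals K.
#' @return A tibble with `week`, `n_at_risk`, `n_returned` and
#'   `n_will_return` (eventual returners still out at the start of the
#'   week; the denominator of [conditional_return_proportion()]).
#' @export
weekly_counts <- function(episodes, max_week = 26L) {
  max_week <- as.integer(max_week)
  stopifnot(max_week >= 1)
  if (nrow(episodes) == 0) {
    stop("no late episodes to tabulate; the estimator needs a non-empty cohort",
      call. = FALSE
    )
  }
  rw <- episodes$return_week[episodes$returned]
  if (any(is.na(rw)) || any(rw < 1)) {
    stop("returned episodes must carry a return_week >= 1", call. = FALSE)
  }
  n1 <- nrow(episodes)
  d <- tabulate(rw[rw <= max_week], nbins = max_week)
  returned_before <- c(0L, cumsum(d)[-max_week])
  tibble::tibble(
    week = seq_len(max_week),
    n_at_risk = as.integer(n1 - returned_before),
    n_returned = as.integer(d),
    n_will_return = as.integer(length(rw) - returned_before)
  )
}

#' Discrete weekly hazard of return
#'
#' The hazard `h_k = d_k / n_k` is the proportion of episodes returning
#' during week `k` among those that had not yet returned at its start.
#' Weeks with an empty risk set carry `hazard = 0` and are flagged in
#' `zero_risk`.
#'
#' @param table Output of [weekly_counts()].
#' @return The table with `hazard` and `zero_risk` columns added.
#' @export
hazard_function <- function(table) {
  zero <- table$n_at_risk == 0L
  table$hazard <- ifelse(zero, 0, table$n_returned / table$n_at_risk)
  table$zero_risk <- zero
  table
}

#' Survival and cumulative distribution of return
#'
#' Product-limit recursion `S_k = prod_{j<=k} (1 - h_j)`, with the return
#' CDF `F_k = 1 - S_k`. With no interior censoring the product-limit
#' estimate collapses to the plain empirical cumulative fraction
#' `F_k = (sum_{j<=k} d_j) / n_1`; both are computed and the identity is
#' asserted on every call.
#'
#' @param table Output of [hazard_function()].
#' @return The table with `survival` and `cdf` columns added.
#' @export
cdf_function <- function(table) {
  stopifnot("hazard" %in% names(table))
  S <- cumprod(1 - table$hazard)
  F_pl <- 1 - S
  F_emp <- cumsum(table$n_returned) / table$n_at_risk[1]
  if (max(abs(F_pl - F_emp)) > 1e-12) {
    stop("product-limit CDF disagrees with the empirical cumulative fraction; ",
      "the risk-set recursion is inconsistent",
      call. = FALSE
    )
  }
  table$survival <- S
  table$cdf <- F_pl
  table
}

#' Greenwood variance and normal-approximation confidence band
#'
#' Greenwood's estimator
#' `v_k = S_k^2 * sum_{j<=k} d_j / (n_j (n_j - d_j))` gives the variance of
#' the survival curve — and of the CDF, its complement. The interval is the
#' plain normal approximation `F_k +/- z * sqrt(v_k)`, clamped to `[0, 1]`
#' (no log-log transform: the estimator is meant to be reproducible in a
#' spreadsheet). When every episode at risk in some week returns
#' (`n_j = d_j`), that week's Greenwood term is infinite; from there on the
#' survival curve is exactly 0, the variance is flagged `degenerate`, and
#' the interval collapses to `[F_k, F_k]`.
#'
#' @param table Output of [cdf_function()].
#' @param level Coverage probability of the interval, in (0, 1).
#' @return The table with `variance`, `ci_low`, `ci_high` and `degenerate`
#'   columns added.
#' @export
greenwood_ci <- function(table, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("confidence level must be a single number in (0, 1)", call. = FALSE)
  }
  stopifnot(all(c("survival", "cdf") %in% names(table)))
  n <- table$n_at_risk
  d <- table$n_returned
  term <- numeric(length(n))
  pos <- n > 0 & n > d
  term[pos] <- d[pos] / (n[pos] * (n[pos] - d[pos]))
  term[n > 0 & n == d] <- Inf # the whole risk set returned: S hits 0
  gsum <- cumsum(term)
  degenerate <- !is.finite(gsum)
  v <- table$survival^2 * gsum
  v[degenerate] <- Inf

  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(v)
  lo <- pmax(0, table$cdf - half)
  hi <- pmin(1, table$cdf + half)
  lo[degenerate] <- table$cdf[degenerate]
  hi[degenerate] <- table$cdf[degenerate]

  table$variance <- v
  table$ci_low <- lo
  table$ci_high <- hi
  table$degenerate <- degenerate
  table
}

#' Full weekly estimates table
#'
#' Convenience chain: [weekly_counts()], [hazard_function()],
#' [cdf_function()], [greenwood_ci()].
#'
#' @inheritParams weekly_counts
#' @inheritParams greenwood_ci
#' @return The weekly table with all estimate columns filled.
#' @export
weekly_table <- function(episodes, max_week = 26L, level = 0.95) {
  weekly_counts(episodes, max_week) |>
    hazard_function() |>
    cdf_function() |>
    greenwood_ci(level)
}

#' One-week return proportion among eventual returners still out
#'
#' Of the late patients who have not yet returned by the start of week `k`
#' but who will eventually return, the fraction that comes back during week
#' `k` itself: `d_k / #(returners with return_week >= k)`. This answers the
#' clinic's question "of those still out who will come back, how many show
#' up if we wait one more week?". It equals the hazard `h_k` exactly when
#' there are no never-returners, and exceeds it otherwise.
#'
#' @param table A table containing `n_returned` and `n_will_return`
#'   ([weekly_counts()] and downstream).
#' @param week Week-late interval k.
#' @return A single proportion, or `NA` (with a warning) when no eventual
#'   returner is still out at week `k`.
#' @export
conditional_return_proportion <- function(table, week) {
  stopifnot(
    all(c("n_returned", "n_will_return") %in% names(table)),
    week %in% table$week
  )
  i <- match(week, table$week)
  if (table$n_will_return[i] == 0L) {
    warning(sprintf(
      "no eventual returner is still out at week %d; proportion undefined", week
    ), call. = FALSE)
    return(NA_real_)
  }
  table$n_returned[i] / table$n_will_return[i]
}
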