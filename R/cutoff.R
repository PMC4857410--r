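#' Cut-off selection rule
#'
#' Formalizes the visual reading of the weekly return curves into an
#' explicit rule for the weeks-late value at which tracing should begin.
#' Two methods are available. `hazard_drop` (default) recommends the
#' earliest week from which the weekly return hazard stays below
#' `hazard_threshold` — first for a sustained run of `run_length` weeks,
#' and then through the end of the table, tolerating isolated single-week
#' blips that stay under twice the threshold. `cdf_plateau` recommends the
#' earliest week from which the CDF's weekly increment, relative to the
#' remaining mass `1 - F_k`, stays below the threshold for `run_length`
#' weeks (this is the CDF "flattening out"). `min_week` floors the
#' recommendation so a quiet first interval — an artifact of weekly binning
#' — cannot by itself trigger "trace everyone at week 1".
#'
#' @param hazard_threshold Proportion below which the weekly hazard counts
#'   as "returns have dried up".
#' @param run_length Number of consecutive sub-threshold weeks required.
#' @param min_week Earliest candidate recommendation.
#' @param method `"hazard_drop"` or `"cdf_plateau"` — which rule headlines
#'   the result (both are always computed).
#' @return A `cutoff_rule` list.
#' @export
cutoff_rule <- function(hazard_threshold = 0.10,
                        run_length = 2L,
                        min_week = 2L,
                        method = c("hazard_drop", "cdf_plateau")) {
  method <- match.arg(method)
  stopifnot(
    hazard_threshold > 0, hazard_threshold < 1,
    run_length >= 1, min_week >= 1
  )
  structure(
    list(
      hazard_threshold = hazard_threshold,
      run_length = as.integer(run_length),
      min_week = as.integer(min_week),
      method = method
    ),
    class = "cutoff_rule"
  )
}

# earliest k >= min_week with h < theta over [k, k + m - 1] and, beyond the
# run, h < theta everywhere except isolated single-week blips under 2*theta
scan_hazard_drop <- function(h, theta, m, min_week) {
  K <- length(h)
  for (k in seq(min_week, K)) {
    if (k + m - 1L > K) break
    if (any(h[k:(k + m - 1L)] >= theta)) next
    tail_idx <- seq_len(K)[seq_len(K) > k + m - 1L]
    if (length(tail_idx) > 0) {
      exceed <- h[tail_idx] >= theta
      if (any(exceed)) {
        if (any(h[tail_idx][exceed] >= 2 * theta)) next
        adjacent <- which(exceed)
        if (any(diff(adjacent) == 1L)) next
      }
    }
    return(k)
  }
  NA_integer_
}

# earliest k >= min_week whose next m weekly CDF increments are each below
# theta times the mass still outstanding; the strict comparison gets a tiny
# guard so an increment exactly at theta never counts as flat
scan_cdf_plateau <- function(F, theta, m, min_week) {
  K <- length(F)
  flat <- c(
    (diff(F) - theta * (1 - F[-K]) < -1e-9) | (1 - F[-K]) == 0,
    NA # increment beyond the table is unobserved
  )
  for (k in seq(min_week, K)) {
    if (k + m - 1L > K - 1L) break
    if (all(flat[k:(k + m - 1L)])) {
      return(k)
    }
  }
  NA_integer_
}

#' Select the clinical-management LTFU cut-off
#'
#' Applies a [cutoff_rule()] to a filled weekly table. Both methods are
#' evaluated and reported; `recommended_week` comes from the rule's
#' `method`. The `stable` flag records whether perturbing the hazard
#' threshold by +/-20 % leaves the recommendation unchanged — a guard
#' against the recommendation sitting on a knife edge of the (ultimately
#' judgement-based) threshold.
#'
#' @param table A weekly table with `hazard` and `cdf` filled.
#' @param rule A [cutoff_rule()].
#' @return A `cutoff_result`: list with `recommended_week` (`NA` when no
#'   week satisfies the rule — never a silent default), `by_method` (both
#'   methods' answers), `stable`, `rule` and an `evidence` tibble with the
#'   per-week hazard, CDF increment and sub-threshold flag.
#' @export
select_cutoff <- function(table, rule = cutoff_rule()) {
  stopifnot(inherits(rule, "cutoff_rule"), all(c("hazard", "cdf") %in% names(table)))
  h <- table$hazard
  F <- table$cdf
  theta <- rule$hazard_threshold
  m <- rule$run_length

  by_method <- c(
    hazard_drop = scan_hazard_drop(h, theta, m, rule$min_week),
    cdf_plateau = scan_cdf_plateau(F, theta, m, rule$min_week)
  )
  pick <- function(th) {
    switch(rule$method,
      hazard_drop = scan_hazard_drop(h, th, m, rule$min_week),
      cdf_plateau = scan_cdf_plateau(F, th, m, rule$min_week)
    )
  }
  recommended <- by_method[[rule$method]]
  stable <- identical(pick(0.8 * theta), recommended) &&
    identical(pick(1.2 * theta), recommended)

  evidence <- tibble::tibble(
    week = table$week,
    hazard = h,
    cdf = F,
    cdf_increment = c(diff(F), NA_real_),
    below_threshold = h < theta
  )

  structure(
    list(
      recommended_week = recommended,
      by_method = as.list(by_method),
      stable = stable,
      rule = rule,
      evidence = evidence
    ),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (is.na(x$recommended_week)) {
    cat("No weeks-late cut-off satisfies the rule.\n")
  } else {
    cat(sprintf(
      "Recommended clinical-management LTFU cut-off: >= %d weeks late (%s rule, %s)\n",
      x$recommended_week, x$rule$method,
      if (isTRUE(x$stable)) "stable to +/-20% threshold change" else "NOT stable to +/-20% threshold change"
    ))
  }
  cat(sprintf(
    "  hazard_drop: %s   cdf_plateau: %s\n",
    ifelse(is.na(x$by_method$hazard_drop), "none", x$by_method$hazard_drop),
    ifelse(is.na(x$by_method$cdf_plateau), "none", x$by_method$cdf_plateau)
  ))
  invisible(x)
}

#' Sensitivity of the recommendation to the rule parameters
#'
#' Recomputes the recommendation over a full factorial grid of hazard
#' thresholds and run lengths. Because the underlying judgement ("returns
#' decreased substantially") has no canonical formalization, the scan shows
#' how much the answer depends on the formalization's knobs.
#'
#' @inheritParams select_cutoff
#' @param theta_grid Numeric vector of hazard thresholds.
#' @param m_grid Integer vector of run lengths.
#' @return A tibble `hazard_threshold`, `run_length`, `recommended_week`
#'   (`NA` where no week qualifies).
#' @export
sensitivity_scan <- function(table, rule = cutoff_rule(),
                             theta_grid = c(0.05, 0.08, 0.10, 0.12, 0.15),
                             m_grid = 1:3) {
  stopifnot(length(theta_grid) > 0, length(m_grid) > 0)
  grid <- expand.grid(
    hazard_threshold = theta_grid, run_length = as.integer(m_grid),
    KEEP.OUT.ATTRS = FALSE
  )
  grid$recommended_week <- vapply(seq_len(nrow(grid)), function(i) {
    r <- cutoff_rule(
      hazard_threshold = grid$hazard_threshold[i],
      run_length = grid$run_length[i],
      min_week = rule$min_week,
      method = rule$method
    )
    select_cutoff(table, r)$recommended_week
  }, integer(1))
  tibble::as_tibble(grid)
}
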