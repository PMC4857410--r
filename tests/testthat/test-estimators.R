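test_that("weekly counts, hazard, CDF and Greenwood CI reproduce the hand-worked fixture", {
  ep <- make_episodes(c(1, 1, 4, 9, NA))
  wt <- weekly_table(ep, max_week = 10)

  expect_equal(wt$n_at_risk, c(5L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 1L))
  expect_equal(wt$n_returned, c(2L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(wt$hazard, c(0.4, 0, 0, 1 / 3, 0, 0, 0, 0, 0.5, 0))
  expect_equal(wt$cdf, c(0.4, 0.4, 0.4, 0.6, 0.6, 0.6, 0.6, 0.6, 0.8, 0.8))
  # Greenwood: v_1 = 0.6^2 * 2 / (5 * 3); CI clamped at 0
  expect_equal(wt$variance[1], 0.048)
  expect_equal(wt$ci_low[1], 0)
  expect_equal(wt$ci_high[1], 0.8294066, tolerance = 1e-6)
  expect_false(any(wt$degenerate))
})

test_that("degenerate and empty-return corner cases behave as specified", {
  all_back <- weekly_table(make_episodes(rep(1, 4)), max_week = 5)
  expect_equal(all_back$n_at_risk, c(4L, 0L, 0L, 0L, 0L))
  expect_equal(all_back$cdf, rep(1, 5))
  expect_true(all(all_back$degenerate))
  expect_equal(all_back$ci_low, rep(1, 5))
  expect_equal(all_back$ci_high, rep(1, 5))
  expect_true(all(all_back$zero_risk[-1]))

  none_back <- weekly_table(make_episodes(rep(NA, 6)), max_week = 5)
  expect_equal(none_back$cdf, rep(0, 5))
  expect_equal(none_back$variance, rep(0, 5))
  expect_equal(none_back$ci_low, rep(0, 5))
  expect_equal(none_back$ci_high, rep(0, 5))

  single <- weekly_table(make_episodes(3), max_week = 5)
  expect_equal(single$hazard, c(0, 0, 1, 0, 0))

  expect_error(weekly_counts(make_episodes(numeric(0))), "non-empty")
  expect_error(greenwood_ci(all_back, level = 1.2), "level")
})

test_that("estimates depend only on proportions: duplicating every episode changes nothing", {
  delays <- c(1, 2, 2, 4, 4, 4, 8, 11, NA, NA)
  a <- weekly_table(make_episodes(delays), max_week = 12)
  b <- weekly_table(make_episodes(rep(delays, 2)), max_week = 12)
  expect_equal(a$hazard, b$hazard)
  expect_equal(a$cdf, b$cdf)
  expect_equal(b$n_at_risk, 2L * a$n_at_risk)
})

test_that("counts conserve episodes and the product-limit/empirical identity holds on random cohorts", {
  set.seed(2203)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    delays <- sample(c(1:30, NA), n, replace = TRUE)
    ep <- make_episodes(delays)
    K <- sample(5:26, 1)
    wt <- weekly_table(ep, max_week = K)

    n_never <- sum(is.na(delays))
    n_after_k <- sum(!is.na(delays) & delays > K)
    expect_equal(sum(wt$n_returned) + n_never + n_after_k, n)
    # no-censoring identity: product-limit CDF == empirical fraction
    expect_equal(wt$cdf, cumsum(wt$n_returned) / n, tolerance = 1e-12)
    expect_true(all(diff(wt$cdf) >= 0))
    expect_true(all(wt$hazard >= 0 & wt$hazard <= 1))
    expect_true(all(wt$cdf >= 0 & wt$cdf <= 1))
    expect_equal(wt$survival, 1 - wt$cdf)
  }
})

test_that("survival and Greenwood variance match the survival-package product-limit oracle", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:50) {
    n <- sample(8:80, 1)
    delays <- sample(c(1:20, NA), n, replace = TRUE,
      prob = c(rep(1, 20), sample(2:8, 1))
    )
    if (all(is.na(delays))) next
    K <- 20L
    ep <- make_episodes(delays)
    wt <- weekly_table(ep, max_week = K)

    time <- ifelse(is.na(delays), K + 1L, delays)
    event <- !is.na(delays)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    sf <- stats::stepfun(fit$time, c(1, fit$surv))
    gw <- (fit$std.err * fit$surv)^2
    gw[!is.finite(gw)] <- 0 # S = 0 knots; those weeks are excluded below
    vf <- stats::stepfun(fit$time, c(0, gw))
    ok <- !wt$degenerate
    expect_lt(max(abs(wt$survival[ok] - sf(wt$week[ok]))), 1e-9)
    expect_lt(max(abs(wt$variance[ok] - vf(wt$week[ok]))), 1e-9)
  }
})

test_that("conditional return proportion counts only eventual returners still out", {
  wt <- weekly_counts(make_episodes(c(3, 3, 3, 4, 4, NA)), max_week = 10)
  expect_equal(conditional_return_proportion(wt, 3), 3 / 5)
  expect_equal(conditional_return_proportion(wt, 4), 1)
  expect_warning(
    res <- conditional_return_proportion(wt, 5),
    "undefined"
  )
  expect_true(is.na(res))

  # with no never-returners it coincides with the hazard
  full <- weekly_table(make_episodes(c(1, 2, 2, 5, 7)), max_week = 8)
  for (k in c(1, 2, 5, 7)) {
    expect_equal(conditional_return_proportion(full, k), full$hazard[k])
  }
})
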