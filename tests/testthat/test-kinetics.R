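test_that("population statistics follow the N-1 SD and SD/sqrt(N) SE rules", {
  expect_identical(individual_population(c(TRUE, TRUE)), 1)
  expect_identical(individual_population(rep(FALSE, 10)), 0)
  expect_equal(individual_population(c(rep(TRUE, 13), rep(FALSE, 37))),
               0.26)
  expect_error(individual_population(logical(0)), "degenerate")

  expect_equal(aggregate_population(rep(0.35, 20)),
               c(mean = 35, sd = 0, se = 0))
  agg <- aggregate_population(c(0.2, 0.4))
  expect_equal(unname(agg["mean"]), 30)
  expect_equal(unname(agg["sd"]), 14.142, tolerance = 1e-4)
  expect_equal(unname(agg["se"]), 10.0, tolerance = 1e-10)
  expect_error(aggregate_population(0.3), "insufficient")

  # SD = 12 at N = 20 gives SE that rounds to 3
  x <- c(rep(0.35 - 0.12, 10), rep(0.35 + 0.12, 10))
  a <- aggregate_population(x)
  expect_equal(round(unname(a["se"])), 3)
})

test_that("population time series aggregates prefix frames per checkpoint", {
  set.seed(5)
  nsim <- 20; nfr <- 100
  fm <- matrix(runif(nfr * nsim) < 0.3, nfr, nsim)
  cps <- seq(10, 100, 10) * 1e5
  ps <- population_time_series(fm, cps, 1e5, effective_dt = 3.16)
  expect_identical(nrow(ps), 10L)
  expect_equal(ps$aggregated_time_us,
               20 * cps * 3.16 * 1e-9, tolerance = 1e-12)
  # single checkpoint at full length equals the full-run aggregate
  full <- population_time_series(fm, nfr * 1e5, 1e5, 3.16)
  expect_equal(full$mean_pct,
               unname(aggregate_population(colMeans(fm))["mean"]))
  expect_equal(ps[nrow(ps), c("mean_pct", "sd_pct", "se_pct")],
               full[1, c("mean_pct", "sd_pct", "se_pct")],
               ignore_attr = TRUE)
  # the benchmark grid: 500e6 steps, 20 sims, credit 3.16 -> 31.6 us
  expect_equal(20 * 500e6 * 3.16 * 1e-9, 31.6, tolerance = 1e-12)
  expect_error(population_time_series(fm, c(15e4), 1e5, 3.16),
               "alignment")
  expect_error(population_time_series(fm, 101 * 1e5, 1e5, 3.16),
               "alignment")
})

test_that("first passage uses the first at-cutoff frame or censors at the end", {
  r <- first_passage(c(5, 3, 1.9, 1.2), cutoff = 1.96,
                     save_interval = 1e5, effective_dt = 3.1623,
                     n_steps = 500e6)
  expect_true(r$event)
  expect_equal(r$time, 3 * 1e5 * 3.1623 * 1e-6, tolerance = 1e-12)
  expect_equal(r$time, 0.94869, tolerance = 1e-4)

  cens <- first_passage(rep(5, 5000), 1.96, 1e5, 3.1623, 500e6)
  expect_false(cens$event)
  expect_equal(cens$time, 1581.15, tolerance = 1e-4)

  first <- first_passage(c(1.0, 5), 1.96, 1e5, 3.1623, 500e6)
  expect_equal(first$time, 1e5 * 3.1623 * 1e-6)
})

test_that("Kaplan-Meier fit matches hand-computed product-limit results", {
  # no censoring: restricted mean equals the arithmetic mean exactly
  set.seed(8)
  for (i in 1:5) {
    t <- rexp(20, 1 / 100)
    f <- km_fit(folding_records(t, rep(TRUE, 20)))
    expect_equal(f$tau_f, mean(t), tolerance = 1e-12)
    expect_identical(f$estimator, "kaplan_meier")
    expect_true(f$lcl <= f$tau_f && f$tau_f <= f$ucl)
  }
  # hand-computed curve with one censored record: S steps
  # 1 -> .8 -> .6 -> .4 -> .2 at t = 2,4,6,8; area to t = 10 is 6.0
  r <- folding_records(c(2, 4, 6, 8, 10), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  f <- km_fit(r)
  expect_equal(f$tau_f, 6.0, tolerance = 1e-12)
  s <- summary(f$curve)
  expect_equal(s$surv, c(0.8, 0.6, 0.4, 0.2))
  expect_error(km_fit(folding_records(c(1, 2), c(FALSE, FALSE))),
               "no folding events")
})

test_that("exponential MLE handles censoring and recovers the true mean", {
  set.seed(31)
  t <- rexp(20, 1 / 50)
  f <- exponential_fit(folding_records(t, rep(TRUE, 20)))
  expect_equal(f$tau_f, mean(t), tolerance = 1e-12)

  r <- folding_records(c(rep(100, 19), 500), c(rep(TRUE, 19), FALSE))
  expect_equal(exponential_fit(r)$tau_f, 2400 / 19, tolerance = 1e-12)

  # exposure-splitting invariance: replacing one record by censored
  # fragments with the same total exposure leaves the MLE unchanged
  r2 <- folding_records(c(rep(100, 19), 200, 180, 120),
                        c(rep(TRUE, 19), FALSE, FALSE, FALSE))
  expect_equal(exponential_fit(r2)$tau_f, exponential_fit(r)$tau_f)

  # Monte-Carlo recovery: 500 draws of 20 exponential(100) times
  set.seed(99)
  taus <- numeric(500); cover <- logical(500)
  for (i in 1:500) {
    fi <- exponential_fit(folding_records(rexp(20, 1 / 100),
                                          rep(TRUE, 20)))
    taus[i] <- fi$tau_f
    cover[i] <- fi$lcl <= 100 && 100 <= fi$ucl
  }
  expect_lt(abs(mean(taus) - 100) / 100, 0.02)
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("the two-step folding-time procedure selects and refuses correctly", {
  set.seed(12)
  t <- rexp(20, 1 / 100)
  all_ev <- folding_records(t, rep(TRUE, 20))
  f <- estimate_folding_time(all_ev, full_length = TRUE)
  expect_identical(f$estimator, "exponential")
  expect_true(attr(f, "selected"))
  expect_false(attr(f, "disagreement"))
  # KM and MLE means agree exactly with no censoring
  expect_equal(f$tau_f, km_fit(all_ev)$tau_f, tolerance = 1e-12)

  # 19/20 events: the exponential fit is used
  part <- folding_records(c(t[1:19], 1581), c(rep(TRUE, 19), FALSE))
  fp <- estimate_folding_time(part, full_length = TRUE)
  expect_identical(fp$estimator, "exponential")
  expect_equal(fp$n_events, 19)

  # any censoring in a full-length set routes to the exponential fit
  mixed <- folding_records(c(1, 2, 3, rep(200, 17)),
                           c(TRUE, TRUE, TRUE, rep(FALSE, 17)))
  fm <- estimate_folding_time(mixed, full_length = TRUE)
  expect_identical(fm$estimator, "exponential")

  # shortened runs with >= half censored are discarded
  short <- folding_records(c(rexp(10, 1 / 50), rep(100, 10)),
                           c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_error(estimate_folding_time(short, full_length = FALSE),
               "discarded")
  # 9/20 censored shortened runs pass through
  short2 <- folding_records(c(rexp(11, 1 / 50), rep(100, 9)),
                            c(rep(TRUE, 11), rep(FALSE, 9)))
  expect_s3_class(estimate_folding_time(short2, full_length = FALSE),
                  "survival_fit")

  # parameter recovery: true tau inside the reported 95% CI >= 90% of 200
  # seeded replicates of 20 records
  set.seed(77)
  hits <- 0
  for (i in 1:200) {
    fr <- estimate_folding_time(
      folding_records(rexp(20, 1 / 100), rep(TRUE, 20)))
    if (fr$lcl <= 100 && 100 <= fr$ucl) hits <- hits + 1
  }
  expect_gte(hits, 180)
})

test_that("ln-nonnative regression diagnoses two-state decay", {
  # exactly exponential empirical fractions: 1024 records engineered so
  # the nonnative fraction at grid point 10k is exactly 2^-k, hence
  # ln(fraction) is exactly linear with slope -ln(2)/10
  grid <- seq(10, 100, 10)
  n <- 1024
  fold_counts <- n * 2^-(1:10)          # folds inside interval k
  times <- c(rep(grid - 5, fold_counts), rep(1e9, n * 2^-10))
  rec <- folding_records(times, times < 1e8)
  fit <- ln_nonnative_regression(rec, grid)
  expect_equal(fit$slope, -log(2) / 10, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)

  # constant nonnative fraction: slope 0
  rec2 <- folding_records(c(1, 1, 1, rep(1e9, 7)),
                          c(rep(TRUE, 3), rep(FALSE, 7)))
  fit2 <- ln_nonnative_regression(rec2, c(10, 20, 30, 40))
  expect_equal(fit2$slope, 0)

  # all folded before the grid: degenerate
  rec3 <- folding_records(c(1, 2, 3), rep(TRUE, 3))
  expect_error(ln_nonnative_regression(rec3, c(10, 20, 30)),
               "degenerate")

  # Monte-Carlo: with a 10-point grid at observed event times, r^2 > 0.9
  # in >= 90% of 200 replicates at N = 20, tau = 100 ns
  set.seed(123)
  good <- 0
  for (i in 1:200) {
    t <- rexp(20, 1 / 100)
    g <- sort(t)[round(seq(1, 16, length.out = 10))]
    f <- ln_nonnative_regression(folding_records(t, rep(TRUE, 20)), g)
    if (f$r_squared > 0.9) good <- good + 1
  }
  expect_gte(good, 180)
})

test_that("curve t test reproduces pooled-variance Student results", {
  a <- c(0, 0, 4, 6, 9, 12, 14, 15, 16, 17)
  b <- c(0, 0, 0, 1, 3, 4, 5, 6, 8, 9)
  res <- curve_ttest(a, b)
  expect_equal(res$df, 18)
  # hand-computed pooled t
  sp2 <- (9 * var(a) + 9 * var(b)) / 18
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 10))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$t, 2.47, tolerance = 0.005)

  same <- curve_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(curve_ttest(1, a), "insufficient")
})
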