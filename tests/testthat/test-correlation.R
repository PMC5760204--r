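test_that("the correlation rule picks Pearson only for large normal samples", {
  set.seed(31)
  x <- rnorm(40)
  res <- trial_correlation(x, 2 * x + 1)
  expect_equal(res$method, "pearson")
  expect_equal(res$r, 1)

  x25 <- rnorm(25)
  expect_equal(trial_correlation(x25, 2 * x25 + rnorm(25, sd = 0.1))$method,
               "spearman")

  skewed <- exp(rnorm(60, sd = 1.5))
  expect_equal(trial_correlation(skewed, skewed + rnorm(60))$method,
               "spearman")

  const <- trial_correlation(rep(1, 20), rnorm(20))
  expect_false(const$defined)
  expect_true(is.na(const$r))
})

test_that("correlation matrices match a per-bin loop and find the lead band", {
  set.seed(32)
  n_trials <- 25
  n_bins <- 30
  # independent per-(bin, trial) activity; eyelid is the spike activity
  # delayed by exactly one 20 ms bin
  A <- matrix(rnorm(n_bins * n_trials), n_bins, n_trials)
  spike <- 60 + A[rep(seq_len(n_bins), each = 20), ] * 10
  etime <- seq(0, 596, by = 4)
  ebin <- pmax(floor((etime - 20) / 20) + 1, 1)
  eyelid <- A[ebin, ] * 5
  cm <- correlation_matrix(spike, eyelid, etime, bin_ms = 20)
  expect_equal(dim(cm$r), c(30, 30))
  ref <- naive_corr_matrix(spike, eyelid, etime, 20)
  expect_equal(cm$r, ref, tolerance = 1e-12, ignore_attr = TRUE)
  # strongest correlation one eyelid bin after the spike bin (spikes lead)
  off <- sapply(2:29, function(i) which.max(cm$r[i, ]) - i)
  expect_true(all(off == 1))
})

test_that("null traces exceed the significance threshold at the nominal rate", {
  set.seed(33)
  n_trials <- 40
  rcrit <- qt(0.975, n_trials - 2) /
    sqrt(n_trials - 2 + qt(0.975, n_trials - 2)^2)
  hits <- 0; total <- 0
  for (rep in 1:4) {
    spike <- matrix(rnorm(400 * n_trials, 60, 5), 400, n_trials)
    eyelid <- matrix(rnorm(100 * n_trials), 100, n_trials)
    cm <- correlation_matrix(spike, eyelid, seq(0, 396, 4), 20)
    hits <- hits + sum(abs(cm$r) > rcrit)
    total <- total + length(cm$r)
  }
  expect_lt(abs(hits / total - 0.05), 0.02)
})

test_that("sign-nullified averaging zeroes the opposite sign before the mean", {
  base <- correlation_matrix(matrix(rnorm(40 * 12, 60, 5), 40, 12),
                             matrix(rnorm(10 * 12), 10, 12),
                             seq(0, 36, 4), 20)
  m1 <- base; m1$r <- matrix(0.4, 2, 2)
  m2 <- base; m2$r <- matrix(-0.4, 2, 2)
  avg <- average_matrices(list(m1, m2), "positive")
  expect_equal(avg$r, matrix(0.2, 2, 2))
  expect_equal(average_matrices(list(m1), "positive")$r, m1$r)
  expect_equal(average_matrices(list(m1), "negative")$r, matrix(0, 2, 2))
})

test_that("temporal cross-correlation recovers constructed lags and is antisymmetric", {
  timing <- timing_dataset1()
  t <- seq_len(2000) - 0.5
  base <- 60 + 20 * plogis((t - 650) / 20) + 2 * sin(t / 15)
  etime <- seq(0, 1996, by = 4)
  same <- approx(t, base, etime, rule = 2)$y
  expect_equal(temporal_cross_correlation(base, etime, same,
                                          timing)$best_lag, 0)
  delayed <- approx(t + 25, base, etime, rule = 2)$y  # eyelid lags by 25 ms
  xc <- temporal_cross_correlation(base, etime, delayed, timing)
  expect_equal(xc$best_lag, 25)
  # swapping the traces negates the best lag
  delayed_ms <- approx(t + 25, base, t, rule = 2)$y
  back <- temporal_cross_correlation(delayed_ms, etime, same, timing)
  expect_equal(back$best_lag, -25)
})

test_that("the bootstrap population test is seeded, granular, and separates strong coupling", {
  set.seed(34)
  cells <- lapply(1:8, function(i) {
    x <- rnorm(40)
    list(x = x, y = 0.8 * x + rnorm(40, sd = 0.6))
  })
  b1 <- bootstrap_population_test(cells, reps = 200, seed = 99)
  b2 <- bootstrap_population_test(cells, reps = 200, seed = 99)
  expect_identical(b1$null_counts, b2$null_counts)
  expect_equal(b1$p, 0)
  expect_equal(b1$p_label, "< 0.005")
  expect_gte(b1$observed, 7)
  # p always a multiple of 1/reps
  null_cells <- lapply(1:6, function(i) list(x = rnorm(35), y = rnorm(35)))
  b3 <- bootstrap_population_test(null_cells, reps = 100, seed = 7)
  expect_equal(b3$p * 100, round(b3$p * 100))
})

test_that("pooled slopes combine per-cell fits and respect boundaries", {
  cells <- lapply(1:6, function(i) {
    x <- seq(0, 10, length.out = 20)
    list(x = x, y = 0.5 * x + i)
  })
  ps <- suppressWarnings(pooled_slope(cells))  # exact fits warn in lm
  expect_equal(ps$slope, 0.5, tolerance = 1e-8)

  one <- suppressWarnings(pooled_slope(cells[1]))
  expect_true(one$single_cell)
  expect_true(is.na(one$tau2))

  set.seed(35)
  sim <- lapply(1:15, function(i) {
    x <- rnorm(40, 10, 4)
    b <- rnorm(1, 0.5, 0.05)
    list(x = x, y = b * x + rnorm(40, sd = 1))
  })
  ps2 <- pooled_slope(sim)
  expect_lt(abs(ps2$slope - 0.5), 2.5 * sqrt(ps2$se^2 + 0.05^2 / 15))
})

test_that("required sample size for 80% power matches the exact computation", {
  expect_equal(required_trials_for_power(0.73)$n, 12)
  expect_equal(required_trials_for_power(0.34)$n, 65)
  # Fisher-z approximation stays within one trial of the exact answer
  r1 <- required_trials_for_power(0.73)
  r2 <- required_trials_for_power(0.34)
  expect_lte(abs(r1$n_fisher - r1$n_exact), 1)
  expect_lte(abs(r2$n_fisher - r2$n_exact), 1)
})

test_that("required n decreases with |r| and increases with power", {
  ns <- sapply(c(0.2, 0.34, 0.5, 0.73, 0.9),
               function(r) required_trials_for_power(r)$n)
  expect_true(all(diff(ns) < 0))
  np <- sapply(c(0.5, 0.8, 0.95),
               function(p) required_trials_for_power(0.5, power = p)$n)
  expect_true(all(diff(np) > 0))
  expect_error(required_trials_for_power(1.2))
  expect_error(required_trials_for_power(0))
})
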