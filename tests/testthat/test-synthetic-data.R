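test_that("stimulus timing encodes co-terminating CS-US protocols", {
  t1 <- timing_dataset1()
  expect_equal(t1$csus_interval, 250)
  expect_equal(t1$us_onset + t1$us_duration, t1$cs_onset + t1$cs_duration)
  t2 <- timing_dataset2()
  expect_equal(t2$csus_interval, 200)
  expect_error(stimulus_timing(cs_duration = 10, us_duration = 20),
               "positive")
})

test_that("identical config and seed reproduce a session exactly", {
  cfg <- sim_config(n_trials = 5)
  a <- generate_session(cfg, timing_dataset1(), seed = 11)
  b <- generate_session(cfg, timing_dataset1(), seed = 11)
  expect_identical(a$recording$spikes, b$recording$spikes)
  expect_identical(a$recording$eyelid$pos, b$recording$eyelid$pos)
  expect_identical(a$ground_truth$trials, b$ground_truth$trials)
})

test_that("eyelid traces have the expected grid and clipping", {
  cfg <- sim_config(n_trials = 1)
  set.seed(1)
  ey <- generate_eyelid_trial(cfg, timing_dataset1(), latent_cr = 40)
  expect_equal(nrow(ey), 500)          # 2000 ms at 4 ms period
  expect_true(all(ey$eyelid_pct >= -20 & ey$eyelid_pct <= 100))
  expect_error(generate_eyelid_trial(cfg, stimulus_timing(cs_onset = 100),
                                     0),
               "500 ms")
})

test_that("zero baseline rate yields an empty spike train", {
  cfg <- sim_config(n_trials = 1, baseline_rate = 0, facilitation_amp = 0,
                    us_peak_amp = 0, us_pause_depth = 0,
                    second_peak_amp = 0)
  set.seed(1)
  expect_length(generate_spike_trial(cfg, timing_dataset1(), 0), 0)
})

test_that("unmodulated sessions conserve the configured baseline rate", {
  s <- quiet_session(100, seed = 21)
  bs <- baseline_stats(s$recording$spikes, timing_dataset1())
  expect_lt(abs(bs$mean_rate - 67), 2)
  # whole-trial rate too, not just the baseline window
  overall <- mean(lengths(s$recording$spikes)) / 2
  expect_lt(abs(overall - 67), 2)
})

test_that("a unit-gain facilitation plateau raises the window rate by its amplitude", {
  cfg <- plateau_config(30, n_trials = 200)
  s <- generate_session(cfg, timing_dataset1(), seed = 31)
  timing <- timing_dataset1()
  avg <- average_sdf(s$recording$spikes, timing$trial_window)
  win <- avg$time > timing$us_onset - 200 & avg$time <= timing$us_onset
  # early baseline, before the (deliberately early) ramp starts rising
  base <- avg$time >= 20 & avg$time < 300
  expect_lt(abs(mean(avg$rate[win]) - mean(avg$rate[base]) - 30), 3)
})

test_that("noise-only eyelid trials rarely cross the CR criterion", {
  cfg <- sim_config(n_trials = 1, eyelid_noise_sd = 1)
  timing <- timing_dataset1()
  set.seed(41)
  n_cross <- 0
  for (i in 1:1000) {
    ey <- generate_eyelid_trial(cfg, timing, latent_cr = 0)
    win <- ey$time_ms > timing$cs_onset & ey$time_ms < timing$us_onset
    base <- ey$time_ms < timing$cs_onset
    if (max(ey$eyelid_pct[win]) - mean(ey$eyelid_pct[base]) >= 5)
      n_cross <- n_cross + 1
  }
  expect_lte(n_cross, 50)
})

test_that("generated CR amplitude matches the latent amplitude by construction", {
  cfg <- sim_config(n_trials = 1, eyelid_noise_sd = 1e-9)
  timing <- timing_dataset1()
  set.seed(5)
  ey <- generate_eyelid_trial(cfg, timing, latent_cr = 40)
  cr <- detect_cr(ey$eyelid_pct, ey$time_ms, timing)
  expect_true(cr$is_cr)
  expect_lt(abs(cr$amplitude - 40), 1)
})

test_that("Purkinje-cell sets express the requested suppression profile", {
  timing <- timing_dataset1()
  prof <- c(rep(0, timing$cs_onset + 50), rep(40, 150),
            rep(0, timing$trial_window - timing$cs_onset - 200))
  pc <- generate_pc_simple_spike_set(10, 30, prof, timing,
                                     baseline_rate = 70, seed = 51)
  trials <- unlist(pc, recursive = FALSE)
  avg <- average_sdf(trials, timing$trial_window)
  trough <- avg$time > timing$cs_onset + 80 & avg$time < timing$cs_onset + 170
  base <- avg$time >= 20 & avg$time < timing$cs_onset
  dip <- mean(avg$rate[base]) - mean(avg$rate[trough])
  expect_lt(abs(dip - 40), 5)

  flat <- generate_pc_simple_spike_set(5, 40, 0, timing, seed = 52)
  avgf <- average_sdf(unlist(flat, recursive = FALSE), timing$trial_window)
  mid <- avgf$time >= 100 & avgf$time <= 1900
  expect_lt(abs(mean(avgf$rate[mid]) - 70), 2)
})
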