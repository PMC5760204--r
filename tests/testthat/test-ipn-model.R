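timing <- timing_dataset1()

test_that("per-bin ISI statistics are exact for periodic trains", {
  trains <- lapply(1:10, function(i) seq(10, 1990, by = 20))  # 50 Hz
  st <- bin_isi_stats(trains, 2000)
  mid <- 100:1900
  expect_true(all(abs(st$mean[mid] - 20) < 1e-9))
  expect_true(all(st$sd[mid] == 0))
  expect_false(any(st$unreliable[mid]))
})

test_that("two trials define an SD but flag higher moments as unreliable", {
  trains <- list(seq(5, 1995, by = 15), seq(12, 1990, by = 17))
  st <- bin_isi_stats(trains, 2000)
  mid <- 200:1800
  expect_true(all(is.finite(st$sd[mid])))
  expect_true(all(st$unreliable[mid]))
})

test_that("de-biased per-bin ISI moments match the exponential law", {
  set.seed(61)
  trains <- lapply(1:200, function(i) {
    s <- cumsum(rexp(220, rate = 0.067))
    s[s < 2000]
  })
  st <- bin_isi_stats(trains, 2000)
  mid <- 500:1500
  # exponential ISIs: mean 1/rate ~ 14.9 ms, skewness 2
  expect_lt(abs(mean(st$mean[mid]) - 14.9), 0.8)
  expect_lt(abs(mean(st$skew[mid]) - 2), 0.4)
})

test_that("surrogate expansion preserves a deterministic train exactly", {
  trains <- lapply(1:3, function(i) seq(10, 1990, by = 20))
  st <- bin_isi_stats(trains, 2000)
  surr <- expand_simple_spike_trials(st, 4)
  for (s in surr) {
    expect_true(all(abs(diff(s) - 20) < 1e-9))
    expect_lt(abs(length(s) - 100), 2)
  }
})

test_that("surrogate trials preserve the rate and modulation profile", {
  prof <- pc_suppression_profile(40, center = 150, width = 60, timing)
  pc <- generate_pc_simple_spike_set(1, 30, prof, timing, seed = 62)[[1]]
  st <- bin_isi_stats(pc, timing$trial_window)
  set.seed(63)
  surr <- expand_simple_spike_trials(st, 200)
  avg_src <- average_sdf(pc, timing$trial_window)
  avg_sur <- average_sdf(surr, timing$trial_window)
  base <- avg_src$time >= 100 & avg_src$time < timing$cs_onset
  trough <- abs(avg_src$time - (timing$cs_onset + 150)) < 40
  expect_lt(abs(mean(avg_sur$rate[base]) / mean(avg_src$rate[base]) - 1),
            0.05)
  dip_src <- mean(avg_src$rate[base]) - mean(avg_src$rate[trough])
  dip_sur <- mean(avg_sur$rate[base]) - mean(avg_sur$rate[trough])
  expect_lt(abs(dip_sur - dip_src), 8)
})

test_that("thirty inputs by thirty trials give 900 surrogate trains", {
  trains <- lapply(1:4, function(i) sort(runif(130, 0, 2000)))
  mc <- model_ipn_cell(trains, ipn_params(), n_output_trials = 30,
                       window_ms = 2000, seed = 64)
  expect_length(mc$surrogates, 900)
  expect_length(mc$output, 30)
})

test_that("without inhibition the simulator matches the analytic LIF rate", {
  p <- ipn_params()
  out <- simulate_ipn_neuron(list(list(numeric(0))), p, 5000)[[1]]
  rate <- length(out) / 5
  expect_lt(abs(rate / lif_rate_analytic(p) - 1), 0.02)
})

test_that("synchronized input silence disinhibits the model neuron", {
  set.seed(65)
  p <- ipn_params()
  mk_inputs <- function(gap) lapply(1:10, function(trial)
    lapply(1:30, function(i) {
      s <- simple_gamma_train(70, 0.5, 2000)
      if (gap) s <- s[s < 1000 | s >= 1050] else s
    }))
  with_gap <- simulate_ipn_neuron(mk_inputs(TRUE), p, 2000)
  rate_in <- function(out, a, b)
    mean(sapply(out, function(s) sum(s >= a & s < b))) / ((b - a) / 1000)
  gap_rate <- rate_in(with_gap, 1005, 1055)
  base_rate <- rate_in(with_gap, 500, 1000)
  expect_gt(gap_rate, base_rate + 20)
})

test_that("lowering the mean input rate never lowers the output rate", {
  set.seed(66)
  p <- ipn_params()
  rates <- c(90, 70, 50)
  out_rates <- sapply(rates, function(r) {
    inputs <- lapply(1:6, function(trial)
      lapply(1:30, function(i) simple_gamma_train(r, 0.5, 1500)))
    out <- simulate_ipn_neuron(inputs, p, 1500)
    mean(lengths(out)) / 1.5
  })
  expect_true(all(diff(out_rates) > 0))
})

test_that("model output baseline lies in the recorded nuclear range", {
  set.seed(67)
  p <- ipn_params()
  inputs <- lapply(1:8, function(trial)
    lapply(1:30, function(i) simple_gamma_train(70, 0.5, 2000)))
  out <- simulate_ipn_neuron(inputs, p, 2000)
  rate <- mean(lengths(out)) / 2
  expect_gt(rate, 40)
  expect_lt(rate, 94)
})

test_that("unstable integration parameters are rejected", {
  expect_error(ipn_params(dt = 5), "unstable")
  expect_error(ipn_params(v_thresh = -80), "threshold")
})
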