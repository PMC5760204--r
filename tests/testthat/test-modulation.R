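timing <- timing_dataset1()

test_that("a partial plateau scores its window-average amplitude", {
  # +30 Hz over the last 150 ms of the interval, quiet baseline:
  # window mean = 30 * 150 / 200 = 22.5 Hz
  rate <- rep(60, 2000)
  rate[(timing$us_onset - 150 + 1):timing$us_onset] <- 90
  prof <- classify_csus(make_sdf(rate), make_stats(60, 1), timing)
  expect_equal(prof$label, "facilitation")
  expect_equal(prof$amplitude, 22.5, tolerance = 0.01)
  expect_equal(prof$duration, 150)
})

test_that("a flat trace is unmodulated with zero duration", {
  prof <- classify_csus(make_sdf(rep(60, 2000)), make_stats(60, 1), timing)
  expect_equal(prof$label, "none")
  expect_equal(prof$duration, 0)
  expect_true(is.na(prof$onset))
})

test_that("the 5 Hz criterion is inclusive and exact", {
  mk <- function(amp) {
    rate <- rep(60, 2000)
    rate[(timing$us_onset - 199):timing$us_onset] <- 60 + amp
    classify_csus(make_sdf(rate), make_stats(60, 1), timing)
  }
  expect_equal(mk(5.0)$label, "facilitation")
  expect_equal(mk(4.99)$label, "none")
  expect_equal(mk(-6)$label, "suppression")   # mirror criterion
  # monotonicity of the measured amplitude in the injected step
  amps <- c(5, 10, 20, 40, 60)
  measured <- sapply(amps, function(a) mk(a)$amplitude)
  expect_true(all(diff(measured) > 0))
})

test_that("suppression duration tracks the injected trough width", {
  rate <- rep(80, 2000)
  trough <- (timing$us_onset - 120):(timing$us_onset - 41)  # 80 ms
  rate[trough] <- 65   # window mean depth 15 * 80/200 = 6 Hz
  prof <- classify_csus(make_sdf(rate), make_stats(80, 2), timing)
  expect_equal(prof$label, "suppression")
  expect_equal(prof$duration, 80)
  expect_equal(prof$onset, timing$us_onset - 120.5 - timing$cs_onset)
})

test_that("the classifier agrees with a per-bin textual-rule scan", {
  set.seed(23)
  for (i in 1:25) {
    rate <- 60 + cumsum(rnorm(2000, sd = 1.5)) * 0.1 + rnorm(2000, sd = 4)
    rate <- pmax(rate, 0)
    st <- make_stats(60, 3)
    got <- classify_csus(make_sdf(rate), st, timing)
    ref <- naive_classify(rate, 60, 3, timing)
    expect_equal(got$label, ref$label)
    expect_equal(got$fac_score, ref$fac, tolerance = 1e-10)
    expect_equal(got$sup_score, ref$sup, tolerance = 1e-10)
    expect_equal(got$duration, ref$duration)
    expect_equal(got$onset, ref$onset)
  }
})

gauss_bump <- function(center, amp, sd = 8, n = 2000) {
  t <- seq_len(n) - 0.5
  amp * exp(-(t - center)^2 / (2 * sd^2))
}

test_that("CS pauses need both the 4.5 SD drop and the 2 SD rebound", {
  z_pause <- gauss_bump(timing$cs_onset + 88, -6) +
    gauss_bump(timing$cs_onset + 135, 3)
  res <- detect_cs_transient(z_pause, timing)
  expect_true(res$cs_pause$present)
  expect_lt(abs(res$cs_pause$latency - 88), 3)
  expect_false(res$cs_peak$present)

  shallow <- detect_cs_transient(gauss_bump(timing$cs_onset + 88, -4) +
                                   gauss_bump(timing$cs_onset + 135, 3),
                                 timing)
  expect_false(shallow$cs_pause$present)

  no_rebound <- detect_cs_transient(gauss_bump(timing$cs_onset + 88, -6),
                                    timing)
  expect_false(no_rebound$cs_pause$present)

  peak <- detect_cs_transient(gauss_bump(timing$cs_onset + 70, 6) +
                                gauss_bump(timing$cs_onset + 120, -3),
                              timing)
  expect_true(peak$cs_peak$present)
})

test_that("US responses follow their dual criteria and turnaround rules", {
  us <- timing$us_onset
  # dominant first-peak clause: +6 z above the interval-end level
  r1 <- detect_us_responses(gauss_bump(us + 12, 6, sd = 4), timing)
  expect_true(r1$us_peak1$present)
  expect_lt(abs(r1$us_peak1$latency - 12), 2)

  # +3 vs interval end but only +4 vs baseline: second clause fails
  z2 <- gauss_bump(us + 12, 3, sd = 4)
  z2[(us - 50):us] <- 1   # raises interval-end reference to ~1 -> m = 4
  z2 <- z2 + gauss_bump(us + 12, 1, sd = 4)
  r2 <- detect_us_responses(z2, timing)
  expect_false(r2$us_peak1$present)

  # pause: -6 vs interval end, -3 vs baseline, with rebound
  z3 <- gauss_bump(us + 30, -3, sd = 5)
  z3[1:(us)] <- z3[1:(us)] + 3 * (seq_len(us) > us - 60)  # end level ~ +3
  r3 <- detect_us_responses(z3, timing)
  expect_true(r3$us_pause$present)

  # second peak present only with the 2 SD turnaround
  z4 <- gauss_bump(us + 45, 6, sd = 5)
  r4 <- detect_us_responses(z4, timing)
  expect_true(r4$us_peak2$present)
  t <- seq_len(2000) - 0.5
  z5 <- 6 * plogis((t - (us + 35)) / 5)  # blunt rise, never turns around
  r5 <- detect_us_responses(z5, timing)
  expect_false(r5$us_peak2$present)
})

test_that("trialwise metrics take the extremum in the 30 ms window", {
  rate <- rep(60, 2000)
  rate[1200] <- 120
  trials <- replicate(4, make_sdf(rate, "trial"), simplify = FALSE)
  pk <- trialwise_us_metrics(trials, center_ms = 1199.5, kind = "peak")
  expect_equal(pk$value, rep(120, 4))
  expect_false(pk$clipped)
  dip <- rate; dip[1205] <- 10
  tr2 <- list(make_sdf(dip, "trial"))
  pa <- trialwise_us_metrics(tr2, 1199.5, kind = "pause")
  expect_equal(pa$value, 10)
  expect_lte(pa$value, mean(dip))
})
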