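# Naive reference implementations, kept deliberately loop-based and close
# to the textual definitions, used to cross-check the vectorized package
# code on small problems.

# build an sdf_trace-like object from a bare rate vector
make_sdf <- function(rate, provenance = "average") {
  structure(list(rate = rate, time = seq_along(rate) - 0.5,
                 kernel_sd = 5, provenance = provenance),
            class = "sdf_trace")
}

make_stats <- function(mean_rate, sd, cv = 0.4) {
  structure(list(mean_rate = mean_rate, sd = sd, cv = cv,
                 cv_defined = TRUE, n_trials = NA, n_spikes = NA),
            class = "baseline_stats")
}

# per-bin scan re-implementing the CS-US modulation rules
naive_classify <- function(rate, mu, sd, timing, threshold = 5,
                           sd_mult = 3, min_run = 10,
                           baseline_ms = 500, edge_ms = 20) {
  t <- seq_along(rate) - 0.5
  win <- which(t > timing$us_onset - 200 & t <= timing$us_onset)
  base <- which(t >= timing$cs_onset - baseline_ms & t < timing$cs_onset &
                  t >= edge_ms & t <= timing$trial_window - edge_ms)
  fac <- mean(rate[win]) - mu -
    mean(sapply(base, function(b) max(rate[b] - mu, 0)))
  sup <- mu - mean(rate[win]) -
    mean(sapply(base, function(b) max(mu - rate[b], 0)))
  label <- "none"
  if (fac >= threshold || sup >= threshold)
    label <- if (fac >= sup) "facilitation" else "suppression"
  sgn <- if (label == "suppression") -1 else 1
  dur <- 0
  for (b in win) if (sgn * (rate[b] - mu) > sd_mult * sd) dur <- dur + 1
  interval <- which(t > timing$cs_onset & t <= timing$us_onset)
  onset <- NA_real_
  run <- 0
  for (b in interval) {
    if (sgn * (rate[b] - mu) > sd_mult * sd) {
      run <- run + 1
      if (run >= min_run) { onset <- t[b - run + 1] - timing$cs_onset; break }
    } else run <- 0
  }
  list(label = label, fac = fac, sup = sup, duration = dur, onset = onset)
}

# triple-loop correlation matrix on binned trial means
naive_corr_matrix <- function(spike_rate, eyelid_pos, eyelid_time, bin_ms) {
  n_bins <- nrow(spike_rate) %/% bin_ms
  n_trials <- ncol(spike_rate)
  sb <- matrix(0, n_bins, n_trials)
  eb <- matrix(0, n_bins, n_trials)
  for (tr in seq_len(n_trials)) {
    for (b in seq_len(n_bins)) {
      rows <- ((b - 1) * bin_ms + 1):(b * bin_ms)
      sb[b, tr] <- mean(spike_rate[rows, tr])
      keep <- eyelid_time >= (b - 1) * bin_ms & eyelid_time < b * bin_ms
      eb[b, tr] <- mean(eyelid_pos[keep, tr])
    }
  }
  r <- matrix(NA_real_, n_bins, n_bins)
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (stats::sd(sb[i, ]) > 0 && stats::sd(eb[j, ]) > 0)
      r[i, j] <- stats::cor(sb[i, ], eb[j, ])
  }
  r
}

# homogeneous gamma-renewal train via plain cumulative sums (no rescaling);
# used as independent input where the package generator is under test
simple_gamma_train <- function(rate_hz, cv, window_ms) {
  k <- 1 / cv^2
  n <- ceiling(rate_hz * window_ms / 1000 * 1.5 + 30)
  isi <- stats::rgamma(n, shape = k, rate = k) * 1000 / rate_hz
  s <- cumsum(isi)
  s[s < window_ms]
}

quiet_session <- function(n_trials, seed, cv = 0.4, rate = 67,
                          timing = timing_dataset1()) {
  cfg <- sim_config(n_trials = n_trials, baseline_rate = rate,
                    baseline_cv = cv, facilitation_amp = 0,
                    us_peak_amp = 0, us_pause_depth = 0,
                    second_peak_amp = 0, cr_incidence = 0,
                    coupling_r = 0)
  generate_session(cfg, timing, seed)
}

# config whose facilitation plateau spans the whole scored window (fast
# ramp right after CS onset, so the baseline stays uncontaminated)
plateau_config <- function(amp, n_trials, cv = 0.4, ...) {
  sim_config(n_trials = n_trials, baseline_cv = cv,
             facilitation_amp = amp, modulation_onset = 15,
             modulation_rise = 20,
             cr_incidence = 1, gain_sd = 0, coupling_r = 0,
             us_peak_amp = 0, us_pause_depth = 0, second_peak_amp = 0, ...)
}
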