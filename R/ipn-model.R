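#' Per-millisecond inter-spike-interval statistics across trials
#'
#' For every 1 ms bin of the trial timespan, collects the inter-spike
#' interval (ISI) in effect at that bin — the interval containing the bin
#' center — across trials, and summarizes its distribution (mean, SD,
#' skewness, kurtosis). Because an interval containing a fixed time point is
#' sampled with probability proportional to its length, the summary moments
#' are computed with weights proportional to 1/ISI, which removes the
#' length bias and recovers the ordinary ISI distribution local to that
#' time; the raw (length-biased) samples are kept for resampling. An
#' unweighted "ISI starting in this bin" variant is available via `mode`.
#'
#' @param pc_trials list of spike-time vectors (ms), one per trial (>= 2).
#' @param window_ms trial window, ms.
#' @param mode `"containing"` (default, de-biased by 1/length weighting) or
#'   `"starting"` (only ISIs whose first spike falls in the bin).
#' @return A `bin_isi_stats`: vectors `mean`, `sd`, `skew`, `kurt` (per
#'   bin, ms units; `NA` where undefined), `n_samples` per bin, `samples`
#'   (trials x bins matrix of containing ISIs, `NA` outside spike spans),
#'   `unreliable` (bins with fewer than 8 samples, where skewness and
#'   kurtosis estimates are poor), `window_ms`, `mode`.
#' @export
bin_isi_stats <- function(pc_trials, window_ms, mode = c("containing",
                                                         "starting")) {
  mode <- match.arg(mode)
  stopifnot(length(pc_trials) >= 2)
  n_trials <- length(pc_trials)
  centers <- seq_len(window_ms) - 0.5
  samples <- matrix(NA_real_, n_trials, window_ms)
  for (i in seq_len(n_trials)) {
    s <- sort(pc_trials[[i]])
    if (length(s) < 2) next
    if (mode == "containing") {
      idx <- findInterval(centers, s)
      ok <- idx >= 1 & idx < length(s)
      samples[i, ok] <- diff(s)[idx[ok]]
    } else {
      b <- floor(s[-length(s)]) + 1L
      keep <- b >= 1 & b <= window_ms
      samples[i, b[keep]] <- diff(s)[keep]
    }
  }
  mom <- matrix(NA_real_, 4, window_ms,
                dimnames = list(c("mean", "sd", "skew", "kurt"), NULL))
  n_samples <- colSums(!is.na(samples))
  for (b in which(n_samples >= 2)) {
    v <- samples[, b]
    v <- v[!is.na(v)]
    w <- if (mode == "containing") 1 / v else rep(1, length(v))
    mom[, b] <- weighted_moments(v, w)
  }
  structure(list(mean = mom["mean", ], sd = mom["sd", ],
                 skew = mom["skew", ], kurt = mom["kurt", ],
                 n_samples = n_samples, samples = samples,
                 unreliable = n_samples < 8,
                 window_ms = window_ms, mode = mode),
            class = "bin_isi_stats")
}

#' Expand a recorded cell into surrogate simple-spike trials
#'
#' Generates new trials by iteratively sampling an ISI from the local
#' (per-bin) ISI distribution at the current time and advancing by it, so
#' that the surrogate trains carry the firing-rate and modulation profile of
#' the source cell without reusing its trials. The default sampler draws
#' from the pooled per-bin empirical ISI samples with 1/length weights
#' (de-biased, see [bin_isi_stats()]); `sampler = "moment"` instead draws
#' from a gamma distribution matched to the de-biased per-bin mean and SD.
#' Bins with undefined statistics fall back to the nearest defined bin.
#'
#' @param stats a [bin_isi_stats()].
#' @param n_trials_out number of surrogate trials.
#' @param sampler `"empirical"` or `"moment"`.
#' @param refractory minimum ISI, ms.
#' @return List of `n_trials_out` spike-time vectors spanning the window.
#' @export
expand_simple_spike_trials <- function(stats, n_trials_out,
                                       sampler = c("empirical", "moment"),
                                       refractory = 1) {
  sampler <- match.arg(sampler)
  w <- stats$window_ms
  defined <- which(stats$n_samples >= 2 & is.finite(stats$mean) &
                     stats$mean > 0)
  if (!length(defined)) stop("no bin has defined ISI statistics")
  # nearest defined bin for every bin
  nearest <- defined[pmax(findInterval(seq_len(w), defined), 1)]
  gap <- abs(seq_len(w) - nearest)
  alt <- defined[pmin(findInterval(seq_len(w), defined) + 1, length(defined))]
  swap <- abs(seq_len(w) - alt) < gap
  nearest[swap] <- alt[swap]

  pool <- vector("list", w)
  if (sampler == "empirical") {
    for (b in defined) {
      v <- stats$samples[, b]
      v <- v[!is.na(v)]
      pool[[b]] <- list(v = v, p = (1 / v) / sum(1 / v))
    }
  }
  draw_isi <- function(b) {
    b <- nearest[b]
    if (sampler == "empirical") {
      pl <- pool[[b]]
      if (length(pl$v) == 1) pl$v else sample(pl$v, 1, prob = pl$p)
    } else {
      m <- stats$mean[b]; s <- stats$sd[b]
      if (s <= 0) m
      else stats::rgamma(1, shape = (m / s)^2, rate = m / s^2)
    }
  }
  lapply(seq_len(n_trials_out), function(i) {
    t <- 0
    out <- numeric(0)
    repeat {
      b <- min(max(floor(t) + 1L, 1L), w)
      t <- t + max(draw_isi(b), refractory)
      if (t >= w) break
      out <- c(out, t)
    }
    out
  })
}

#' Parameters of the convergent inhibitory integrate-and-fire neuron
#'
#' Conductance-based leaky integrate-and-fire model of a cerebellar nuclear
#' neuron under convergent Purkinje-cell inhibition: each input spike
#' increments an exponentially decaying inhibitory conductance (reversal
#' below reset), and a constant excitatory drive sets the baseline firing
#' rate. Defaults use 30 inputs, matching the reported 20-50:1 convergence
#' of Purkinje cells onto nuclear neurons, and are tuned so that ~70 Hz
#' tonic input per fiber yields baseline output in the observed 40-94 Hz
#' range.
#'
#' @param tau_m membrane time constant, ms.
#' @param e_leak,v_thresh,v_reset leak reversal, spike threshold and reset
#'   potential, mV.
#' @param e_inh inhibitory reversal potential, mV.
#' @param w_inh conductance increment per input spike, units of the leak
#'   conductance.
#' @param tau_inh inhibitory conductance decay, ms.
#' @param drive tonic excitatory drive, mV (input resistance times current).
#' @param dt integration step, ms.
#' @param refractory absolute refractory period, ms.
#' @param noise_sd membrane noise SD, mV per sqrt(ms) (0 = deterministic).
#' @param n_inputs number of convergent inputs per modeled trial.
#' @return An `ipn_params` list.
#' @export
ipn_params <- function(tau_m = 10, e_leak = -70, v_thresh = -50,
                       v_reset = -70, e_inh = -85, w_inh = 0.04,
                       tau_inh = 5, drive = 40, dt = 0.1,
                       refractory = 1.5, noise_sd = 0, n_inputs = 30) {
  p <- as.list(environment())
  if (p$v_thresh <= p$v_reset) stop("threshold must exceed reset")
  if (p$tau_inh <= 0 || p$tau_m <= 0) stop("time constants must be positive")
  if (p$dt > min(p$tau_m, p$tau_inh) / 5)
    stop("unstable integration: dt too large relative to the time constants")
  structure(p, class = "ipn_params")
}

#' Closed-form firing rate of the deterministic LIF neuron without inhibition
#'
#' @param params an [ipn_params()].
#' @return Firing rate, Hz (0 when the drive is subthreshold).
#' @export
lif_rate_analytic <- function(params) {
  vinf <- params$e_leak + params$drive
  if (vinf <= params$v_thresh) return(0)
  t_isi <- params$refractory + params$tau_m *
    log((vinf - params$v_reset) / (vinf - params$v_thresh))
  1000 / t_isi
}

#' Simulate the nuclear neuron under convergent inhibitory input
#'
#' Integrates the conductance-based leaky integrate-and-fire equation
#' (forward Euler at `params$dt`) for each modeled trial, pooling the
#' trial's input trains into one inhibitory conductance.
#'
#' @param input_trials list of modeled trials; each trial a list of input
#'   spike-time vectors (ms), typically `params$n_inputs` of them.
#' @param params an [ipn_params()].
#' @param window_ms trial window, ms.
#' @return List of output spike-time vectors, one per input trial.
#' @export
simulate_ipn_neuron <- function(input_trials, params, window_ms) {
  stopifnot(inherits(params, "ipn_params"))
  lapply(input_trials, function(trains) {
    spk <- sort(unlist(trains))
    simulate_ipn_trial(spk, params, window_ms)
  })
}

simulate_ipn_trial <- function(input_spikes, params, window_ms) {
  p <- params
  nstep <- as.integer(round(window_ms / p$dt))
  gin <- numeric(nstep)
  if (length(input_spikes)) {
    idx <- floor(input_spikes[input_spikes >= 0 &
                                input_spikes < window_ms] / p$dt) + 1L
    inc <- tabulate(idx, nbins = nstep) * p$w_inh
    gin <- as.numeric(stats::filter(inc, exp(-p$dt / p$tau_inh),
                                    method = "recursive"))
  }
  v <- p$v_reset
  refr <- 0L
  refr_steps <- as.integer(round(p$refractory / p$dt))
  noise <- if (p$noise_sd > 0)
    stats::rnorm(nstep, sd = p$noise_sd * sqrt(p$dt)) else numeric(nstep)
  out <- numeric(0)
  for (i in seq_len(nstep)) {
    if (refr > 0L) { refr <- refr - 1L; next }
    v <- v + p$dt / p$tau_m *
      (-(v - p$e_leak) - gin[i] * (v - p$e_inh) + p$drive) + noise[i]
    if (v >= p$v_thresh) {
      out <- c(out, i * p$dt)
      v <- p$v_reset
      refr <- refr_steps
    }
  }
  out
}

#' Model one IpN cell from a Purkinje-cell recording
#'
#' Full modeling chain for a single cell: per-bin ISI statistics of the
#' source simple-spike trials, surrogate expansion into
#' `n_output_trials * params$n_inputs` trains (30 x 30 = 900 at the
#' defaults), grouping into `params$n_inputs` inputs per modeled trial, and
#' integrate-and-fire simulation.
#'
#' @param pc_trials list of simple-spike-time vectors (ms), one per trial.
#' @param params an [ipn_params()].
#' @param n_output_trials number of modeled output trials.
#' @param window_ms trial window, ms.
#' @param seed integer seed for the surrogate expansion.
#' @param sampler passed to [expand_simple_spike_trials()].
#' @return List: `output` (modeled spike trials), `surrogates` (the
#'   expanded input trains), `isi_stats`.
#' @export
model_ipn_cell <- function(pc_trials, params = ipn_params(),
                           n_output_trials = 30, window_ms = 2000,
                           seed = NULL, sampler = "empirical") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- bin_isi_stats(pc_trials, window_ms)
  surr <- expand_simple_spike_trials(st,
                                     n_output_trials * params$n_inputs,
                                     sampler = sampler)
  grouped <- split(surr, rep(seq_len(n_output_trials),
                             each = params$n_inputs))
  out <- simulate_ipn_neuron(grouped, params, window_ms)
  list(output = out, surrogates = surr, isi_stats = st)
}

#' Summarize a population of modeled cells
#'
#' Runs the CS-US modulation classifier on each modeled cell's output
#' trials and tabulates amplitude, peak rate and rate-of-rise, optionally
#' grouped by the strength of the input suppression.
#'
#' @param modeled_cells list of modeled cells (each a list of output
#'   spike-time vectors).
#' @param timing a [stimulus_timing()].
#' @param groups optional labels (e.g. input-suppression depth) per cell.
#' @param kernel_sd SDF kernel SD, ms.
#' @return Data frame with one row per cell: `cell`, `group`, `label`,
#'   `amplitude`, `max_rate`, `max_rate_velocity`, `baseline_rate`.
#' @export
model_population_summary <- function(modeled_cells, timing, groups = NULL,
                                     kernel_sd = 5) {
  stopifnot(length(modeled_cells) >= 1)
  rows <- lapply(seq_along(modeled_cells), function(i) {
    trials <- modeled_cells[[i]]
    avg <- average_sdf(trials, timing$trial_window, kernel_sd)
    bs <- baseline_stats(trials, timing, kernel_sd)
    prof <- classify_csus(avg, bs, timing)
    data.frame(cell = i,
               group = if (is.null(groups)) NA else groups[i],
               label = prof$label, amplitude = prof$amplitude,
               max_rate = prof$max_rate,
               max_rate_velocity = prof$max_rate_velocity,
               baseline_rate = bs$mean_rate)
  })
  do.call(rbind, rows)
}
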