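#' Noise-free firing-rate profile for one synthetic trial
#'
#' Builds the per-millisecond rate profile (Hz) that drives the spike
#' generator: tonic baseline, a logistic facilitation ramp (or suppression
#' trough) scaled by the trial's latent gain and sustained until US onset, a
#' transient Gaussian CS pause with rebound, and Gaussian US transients
#' (first peak, pause, second peak). Negative rates are clipped to zero with
#' a warning, as deep suppression can exceed the baseline.
#'
#' @param config a [sim_config()].
#' @param timing a [stimulus_timing()].
#' @param latent_gain multiplicative gain on the CS-US modulation component.
#' @return Numeric vector of rates (Hz), one per 1 ms bin.
#' @keywords internal
rate_profile <- function(config, timing, latent_gain = 1) {
  t <- seq_len(timing$trial_window) - 0.5
  rate <- rep(config$baseline_rate, length(t))

  mod_amp <- config$facilitation_amp - config$suppression_amp
  if (mod_amp != 0 && latent_gain != 0)
    rate <- rate + latent_gain * mod_amp * csus_ramp(t, config, timing)

  if (config$cs_pause_depth > 0) {
    sd_hat <- predicted_avg_sdf_sd(config$baseline_rate, config$baseline_cv,
                                   config$n_trials)
    tp <- timing$cs_onset + config$cs_pause_latency
    rate <- rate -
      config$cs_pause_depth * sd_hat * exp(-(t - tp)^2 / (2 * 8^2)) +
      config$cs_pause_rebound * sd_hat * exp(-(t - (tp + 35))^2 / (2 * 10^2))
  }

  us <- timing$us_onset
  rate <- rate +
    config$us_peak_amp * exp(-(t - (us + config$us_peak_latency))^2 / (2 * 4^2)) -
    config$us_pause_depth * exp(-(t - (us + config$us_pause_latency))^2 / (2 * 5^2)) +
    config$second_peak_amp * exp(-(t - (us + config$second_peak_latency))^2 / (2 * 5^2))

  if (any(rate < 0)) {
    warning("rate profile clipped at 0 (components exceed baseline)")
    rate <- pmax(rate, 0)
  }
  rate
}

# logistic CS-US modulation ramp, 0 -> 1, decaying after the US
csus_ramp <- function(t, config, timing) {
  s <- config$modulation_rise / (2 * log(4))   # 20-80% rise time -> scale
  t_mid <- timing$cs_onset + config$modulation_onset + config$modulation_rise
  ramp <- stats::plogis((t - t_mid) / s)
  us <- timing$us_onset
  post <- t > us
  ramp[post] <- stats::plogis((us - t_mid) / s) * exp(-(t[post] - us) / 60)
  ramp
}

# expected SD across bins of the n-trial-averaged SDF of a stationary
# gamma-renewal train smoothed with a Gaussian kernel: integrates the
# renewal-process spectral density against the squared kernel transform.
# For a gamma(k) renewal process with rate lambda (per ms),
# S(w) = lambda * (1 + 2 Re(phi / (1 - phi))), phi = (1 + i w mu / k)^-k,
# and Var = (1/2pi) Int S(w) exp(-w^2 sigma^2) dw (Hz^2 after x 1e6).
predicted_avg_sdf_sd <- function(rate_hz, cv, n_trials, kernel_sd = 5) {
  lam <- rate_hz / 1000
  if (lam <= 0) return(0)
  k <- 1 / cv^2
  mu <- 1 / lam
  sdens <- function(w) {
    phi <- (1 + 1i * w * mu / k)^(-k)
    lam * (1 + 2 * Re(phi / (1 - phi)))
  }
  f <- function(w) ifelse(w == 0, lam * cv^2, sdens(w)) *
    exp(-w^2 * kernel_sd^2)
  v <- stats::integrate(f, 0, 6 / kernel_sd, rel.tol = 1e-8)$value / pi
  1000 * sqrt(v / n_trials)
}

#' Generate one synthetic spike trial
#'
#' Draws spike times from an inhomogeneous gamma renewal process by time
#' rescaling: unit-mean gamma intervals (shape `1/baseline_cv^2`) are mapped
#' through the inverse of the integrated rate profile. A 1 ms refractory
#' floor is enforced by dropping violating spikes.
#'
#' @inheritParams rate_profile
#' @return Sorted numeric vector of spike times (ms).
#' @examples
#' set.seed(1)
#' spk <- generate_spike_trial(sim_config(), timing_dataset1(), 1)
#' @export
generate_spike_trial <- function(config, timing, latent_gain = 1) {
  rate <- rate_profile(config, timing, latent_gain)
  sample_renewal_train(rate, config$baseline_cv)
}

# inhomogeneous gamma renewal sampler on a per-ms rate vector (Hz)
sample_renewal_train <- function(rate_hz, cv, refractory = 1) {
  lam <- cumsum(rate_hz / 1000)              # integrated rate at bin ends
  total <- lam[length(lam)]
  if (total <= 0) return(numeric(0))
  shape <- 1 / cv^2
  # equilibrium start: the first interval is the forward-recurrence time
  # (a length-biased interval times a uniform), so the process is
  # stationary from the window edge on
  draws <- stats::rgamma(1, shape = shape + 1, rate = shape) *
    stats::runif(1)
  acc <- draws
  while (acc < total) {
    m <- ceiling(total - acc + 10 + 6 * sqrt(max(total, 1)))
    inc <- stats::rgamma(m, shape = shape, rate = shape)
    draws <- c(draws, inc)
    acc <- acc + sum(inc)
  }
  arr <- cumsum(draws)
  arr <- arr[arr <= total]
  if (!length(arr)) return(numeric(0))
  times <- stats::approx(x = c(0, lam), y = 0:length(lam), xout = arr,
                         ties = "ordered")$y
  times <- times[!is.na(times)]
  if (length(times) > 1)
    times <- times[c(TRUE, diff(times) >= refractory)]
  times
}

#' Generate one synthetic eyelid trial
#'
#' Produces a 250 samples/s eyelid position trace (% of the full blink
#' range): Gaussian measurement noise around the resting open-eye position,
#' a logistic conditioned-response (CR) closure reaching `latent_cr` near US
#' onset and lagging the spike facilitation ramp by `spike_lead`, and an
#' alpha-shaped unconditioned response (UR) after the US. Values are clipped
#' to [-20, 100] %.
#'
#' @inheritParams rate_profile
#' @param latent_cr latent CR amplitude for this trial, % closure (0 = no CR).
#' @param paired whether the trial includes the US (drives the UR).
#' @return Data frame with `time_ms` and `eyelid_pct`.
#' @export
generate_eyelid_trial <- function(config, timing, latent_cr, paired = TRUE) {
  if (config$sample_ms <= 0) stop("sample period must be positive")
  if (timing$cs_onset < 500 ||
      timing$trial_window < timing$cs_onset + timing$csus_interval + 500)
    stop("trial window too short: need >=500 ms pre-CS baseline and 500 ms tail")
  t <- seq(0, timing$trial_window - config$sample_ms, by = config$sample_ms)
  pos <- config$eyelid_open_pos +
    stats::rnorm(length(t), sd = config$eyelid_noise_sd)
  if (latent_cr > 0)
    pos <- pos + latent_cr * cr_waveform(t, config, timing)
  if (paired) {
    x <- (t - timing$us_onset) / config$ur_rise
    ur <- ifelse(x > 0, x * exp(1 - x), 0) *
      exp(-pmax(t - timing$us_onset, 0) / config$ur_decay)
    pos <- pos + config$ur_amp * ur
  }
  data.frame(time_ms = t, eyelid_pct = pmin(pmax(pos, -20), 100))
}

# CR waveform: the spike modulation ramp delayed by spike_lead, scaled so
# the latent amplitude is reached at US onset, relaxing well after the US
cr_waveform <- function(t, config, timing) {
  s <- config$modulation_rise / (2 * log(4))
  t_mid <- timing$cs_onset + config$modulation_onset +
    config$modulation_rise + config$spike_lead
  w <- stats::plogis((t - t_mid) / s) /
    stats::plogis((timing$us_onset - t_mid) / s)
  rel <- timing$us_onset + 150
  w[t > rel] <- w[t > rel] * exp(-(t[t > rel] - rel) / 300)
  w
}

# latency (ms post-CS) at which the noise-free CR waveform reaches 5% of
# its at-US amplitude; ground truth for CR-onset recovery
cr_onset_ms <- function(config, timing) {
  s <- config$modulation_rise / (2 * log(4))
  t_mid <- config$modulation_onset + config$modulation_rise +
    config$spike_lead
  w_us <- stats::plogis((timing$us_onset - timing$cs_onset - t_mid) / s)
  t_mid + s * stats::qlogis(0.05 * w_us)
}

#' Generate a full synthetic session with ground truth
#'
#' Draws per-trial latent CR amplitudes and latent spike-modulation gains
#' from a shared standard-normal variable. The latent correlation is chosen
#' so that the measured trial-by-trial correlation between window spike
#' rate and CR amplitude targets `coupling_r` on CR trials: because
#' spike-count noise attenuates any latent coupling, the generator divides
#' the target by the predictable attenuation factor (recorded in the
#' ground truth as `latent_coupling`). It flags a `cr_incidence` fraction
#' of trials as CR trials
#' (non-CR trials get zero CR amplitude and zero modulation gain), and
#' generates spikes and eyelid traces for every trial. Identical
#' `(config, timing, seed)` reproduce the session exactly.
#'
#' @inheritParams rate_profile
#' @param seed integer seed.
#' @return A list with `recording` (class `cell_recording`: `spikes` — list
#'   of spike-time vectors; `eyelid` — list with `time` and a
#'   samples-by-trials `pos` matrix; `timing`; `meta`) and `ground_truth`
#'   (per-trial latents, the echoed config, the expected classifier
#'   amplitude implied by the noise-free profile, and the CR onset latency).
#' @examples
#' s <- generate_session(sim_config(n_trials = 12), timing_dataset1(), seed = 7)
#' length(s$recording$spikes)
#' @export
generate_session <- function(config, timing, seed) {
  stopifnot(inherits(config, "sim_config"), inherits(timing, "stimulus_timing"))
  set.seed(as.integer(seed))
  n <- config$n_trials
  r_lat <- latent_coupling(config, timing)
  z <- stats::rnorm(n)
  e <- stats::rnorm(n)
  u2 <- r_lat * z + sqrt(1 - r_lat^2) * e
  has_cr <- stats::runif(n) < config$cr_incidence
  latent_cr <- ifelse(has_cr, pmax(config$cr_amp_mean + config$cr_amp_sd * z, 0), 0)
  latent_gain <- ifelse(has_cr, pmax(1 + config$gain_sd * u2, 0), 0)

  spikes <- vector("list", n)
  pos <- NULL
  for (i in seq_len(n)) {
    spikes[[i]] <- generate_spike_trial(config, timing, latent_gain[i])
    ey <- generate_eyelid_trial(config, timing, latent_cr[i])
    if (is.null(pos)) pos <- matrix(0, nrow(ey), n)
    pos[, i] <- ey$eyelid_pct
  }
  time <- seq(0, timing$trial_window - config$sample_ms, by = config$sample_ms)

  # expected classifier amplitude: mean of the noise-free modulation over
  # the last 200 ms of the CS-US interval at the mean realized gain, minus
  # the expected same-signed baseline excursion the classifier subtracts
  # (mean positive part of a centered Gaussian = 0.3989 * SD)
  t <- seq_len(timing$trial_window) - 0.5
  win <- t > timing$us_onset - 200 & t <= timing$us_onset
  mod_amp <- config$facilitation_amp - config$suppression_amp
  sd_pred <- predicted_avg_sdf_sd(config$baseline_rate, config$baseline_cv, n)
  expected_amp <- mean(latent_gain) * mod_amp *
    mean(csus_ramp(t, config, timing)[win]) -
    sign(mod_amp) * stats::dnorm(0) * sd_pred

  recording <- structure(
    list(spikes = spikes,
         eyelid = list(time = time, pos = pos),
         timing = timing,
         meta = list(seed = as.integer(seed), depth_um = NA_real_,
                     training_day = NA_integer_)),
    class = "cell_recording")
  ground_truth <- list(
    trials = data.frame(trial = seq_len(n), has_cr = has_cr,
                        latent_cr = latent_cr, latent_gain = latent_gain),
    latent_coupling = r_lat,
    config = config,
    expected_csus_amp = expected_amp,
    cr_onset_ms = cr_onset_ms(config, timing),
    predicted_baseline_sd = sd_pred)
  list(recording = recording, ground_truth = ground_truth)
}

# Latent correlation needed so that the MEASURED trial-by-trial correlation
# between the spike metric (mean rate over the last 200 ms of the CS-US
# interval) and the CR amplitude targets config$coupling_r on CR trials.
# Spike-count noise attenuates the latent correlation by
# sd_signal / sqrt(sd_signal^2 + var_noise), with var_noise the asymptotic
# renewal count variance rate * CV^2 / T over the T = 0.2 s window; eyelid
# measurement noise attenuates analogously (negligibly at the defaults).
# The latent correlation is the target divided by both attenuations.
latent_coupling <- function(config, timing) {
  if (config$coupling_r == 0) return(0)
  t <- seq_len(timing$trial_window) - 0.5
  win <- t > timing$us_onset - 200 & t <= timing$us_onset
  mod_win <- abs(config$facilitation_amp - config$suppression_amp) *
    mean(csus_ramp(t, config, timing)[win])
  sd_sig <- config$gain_sd * mod_win
  if (sd_sig <= 0)
    stop("coupling_r != 0 requires modulation with a positive gain_sd")
  var_noise <- (config$baseline_rate + mod_win) *
    config$baseline_cv^2 / 0.2
  att_x <- sd_sig / sqrt(sd_sig^2 + var_noise)
  att_y <- config$cr_amp_sd /
    sqrt(config$cr_amp_sd^2 + config$eyelid_noise_sd^2)
  r_lat <- config$coupling_r / (att_x * att_y)
  if (abs(r_lat) >= 1)
    stop(sprintf(paste0("target coupling_r = %g is unreachable at this ",
                        "noise level (would need latent r = %.2f)"),
                 config$coupling_r, r_lat))
  r_lat
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("cell_recording: %d trials, %d ms window, %.1f Hz overall\n",
              length(x$spikes), x$timing$trial_window,
              mean(lengths(x$spikes)) / x$timing$trial_window * 1000))
  invisible(x)
}

#' Generate a set of Purkinje-cell simple-spike recordings
#'
#' Produces per-cell sets of simple-spike trials at a tonic baseline with a
#' CS-US suppression trough given by `suppression_profile`; these serve as
#' the input to the convergent nuclear-neuron model.
#'
#' @param n_cells number of cells.
#' @param n_trials trials per cell (at least 2).
#' @param suppression_profile numeric vector of suppression depths (Hz,
#'   positive = rate decrease), one per 1 ms bin, or a single 0 for no
#'   modulation.
#' @param timing a [stimulus_timing()].
#' @param baseline_rate,baseline_cv tonic simple-spike rate (Hz) and ISI CV.
#' @param seed integer seed.
#' @return List of cells; each cell a list of spike-time vectors.
#' @export
generate_pc_simple_spike_set <- function(n_cells, n_trials,
                                         suppression_profile = 0,
                                         timing = timing_dataset1(),
                                         baseline_rate = 70,
                                         baseline_cv = 0.5,
                                         seed = 1) {
  stopifnot(n_trials >= 2,
            length(suppression_profile) %in% c(1L, timing$trial_window))
  set.seed(as.integer(seed))
  rate <- rep(baseline_rate, timing$trial_window) -
    rep_len(suppression_profile, timing$trial_window)
  if (any(rate < 0)) {
    warning("PC rate profile clipped at 0")
    rate <- pmax(rate, 0)
  }
  lapply(seq_len(n_cells), function(c)
    lapply(seq_len(n_trials), function(i)
      sample_renewal_train(rate, baseline_cv)))
}

#' Gaussian CS-US suppression profile for Purkinje-cell simulations
#'
#' @param depth trough depth, Hz.
#' @param center trough center, ms post-CS.
#' @param width Gaussian SD, ms.
#' @param timing a [stimulus_timing()].
#' @return Numeric vector (Hz of suppression) per 1 ms bin.
#' @export
pc_suppression_profile <- function(depth, center = 150, width = 60,
                                   timing = timing_dataset1()) {
  t <- seq_len(timing$trial_window) - 0.5
  depth * exp(-(t - (timing$cs_onset + center))^2 / (2 * width^2))
}
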