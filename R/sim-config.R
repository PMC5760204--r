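#' Configuration for the synthetic session generator
#'
#' Bundles every tunable of the synthetic IpN session generator. The defaults
#' emulate a conditioned animal recorded during paired CS-US trials: tonic
#' baseline firing around 67 Hz with moderately irregular inter-spike
#' intervals, spike facilitation building up over the second half of the
#' CS-US interval, a well-trained CR incidence of 80%, CR amplitudes of
#' 30 +/- 10% eyelid closure, spikes leading the eyelid by 30 ms, and a
#' moderate trial-by-trial coupling between spike gain and CR amplitude.
#'
#' @param n_trials number of paired trials in the session.
#' @param baseline_rate tonic firing rate, Hz.
#' @param baseline_cv coefficient of variation of baseline inter-spike
#'   intervals (gamma-renewal shape is `1/cv^2`).
#' @param facilitation_amp plateau amplitude of CS-US facilitation, Hz, at
#'   unit latent gain.
#' @param suppression_amp plateau depth of CS-US suppression, Hz (use one of
#'   facilitation/suppression, not both).
#' @param modulation_onset latency of the modulation ramp onset, ms post-CS.
#' @param modulation_rise 20-80% rise time of the logistic ramp, ms.
#' @param cs_pause_depth depth of the transient CS pause in baseline-SD units
#'   of the trial-averaged spike density function (0 disables it).
#' @param cs_pause_latency CS-pause trough latency, ms post-CS.
#' @param cs_pause_rebound rebound amplitude after the pause, SD units.
#' @param us_peak_amp,us_peak_latency first US peak amplitude (Hz) and
#'   latency (ms post-US).
#' @param us_pause_depth,us_pause_latency US pause depth (Hz) and latency.
#' @param second_peak_amp,second_peak_latency second US peak amplitude (Hz)
#'   and latency.
#' @param cr_incidence fraction of trials carrying a CR.
#' @param cr_amp_mean,cr_amp_sd mean and SD of latent CR amplitude, % of the
#'   full blink range.
#' @param spike_lead lead of spike facilitation over the eyelid, ms.
#' @param coupling_r target trial-by-trial correlation between latent spike
#'   gain and latent CR amplitude (|r| < 1).
#' @param gain_sd SD of the latent multiplicative modulation gain around 1.
#' @param eyelid_noise_sd eyelid measurement noise, % closure.
#' @param eyelid_open_pos resting open-eye position, % closure.
#' @param ur_amp,ur_rise,ur_decay unconditioned-response peak (% closure),
#'   rise time (ms) and decay time constant (ms).
#' @param sample_ms eyelid sample period, ms (250 samples/s).
#' @return An object of class `sim_config` (a named list).
#' @seealso [generate_session()]
#' @export
sim_config <- function(n_trials = 100,
                       baseline_rate = 67,
                       baseline_cv = 0.4,
                       facilitation_amp = 50,
                       suppression_amp = 0,
                       modulation_onset = 100,
                       modulation_rise = 60,
                       cs_pause_depth = 0,
                       cs_pause_latency = 88,
                       cs_pause_rebound = 3,
                       us_peak_amp = 40,
                       us_peak_latency = 10,
                       us_pause_depth = 25,
                       us_pause_latency = 30,
                       second_peak_amp = 20,
                       second_peak_latency = 45,
                       cr_incidence = 0.8,
                       cr_amp_mean = 30,
                       cr_amp_sd = 10,
                       spike_lead = 30,
                       coupling_r = 0.5,
                       gain_sd = 0.35,
                       eyelid_noise_sd = 1,
                       eyelid_open_pos = 0,
                       ur_amp = 85,
                       ur_rise = 30,
                       ur_decay = 150,
                       sample_ms = 4) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_trials >= 1, cfg$baseline_rate >= 0,
            cfg$baseline_cv > 0, cfg$sample_ms > 0)
  if (cfg$cr_incidence < 0 || cfg$cr_incidence > 1)
    stop("cr_incidence must lie in [0, 1]")
  if (abs(cfg$coupling_r) >= 1) stop("|coupling_r| must be < 1")
  if (cfg$facilitation_amp < 0 || cfg$suppression_amp < 0)
    stop("modulation amplitudes must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  %d trials, baseline %g Hz (CV %g)\n",
              x$n_trials, x$baseline_rate, x$baseline_cv))
  cat(sprintf("  facilitation %g Hz / suppression %g Hz from %g ms post-CS\n",
              x$facilitation_amp, x$suppression_amp, x$modulation_onset))
  cat(sprintf("  CR incidence %g, amplitude %g +/- %g%%, spike lead %g ms, coupling r %g\n",
              x$cr_incidence, x$cr_amp_mean, x$cr_amp_sd, x$spike_lead,
              x$coupling_r))
  invisible(x)
}
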