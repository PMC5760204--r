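#' Spike density function of a single trial
#'
#' Bins spike times into 1 ms bins over the trial window and convolves the
#' binary bin vector with a Gaussian kernel (SD `kernel_sd`, truncated at
#' +/- 4 SD, normalized to unit mass), yielding an instantaneous firing-rate
#' trace in Hz. Outside the window the spike train is treated as empty
#' (zero padding), so rate estimates within roughly `4 * kernel_sd` of the
#' window edges are biased low.
#'
#' @param spikes numeric vector of spike times, ms from trial start.
#' @param window_ms trial window length, ms.
#' @param kernel_sd Gaussian kernel SD, ms.
#' @return An `sdf_trace`: list with `rate` (Hz, one value per 1 ms bin),
#'   `time` (bin centers, ms), `kernel_sd`, and `provenance` ("trial").
#' @examples
#' sdf <- compute_sdf(c(100, 120, 500), 1000)
#' sum(sdf$rate) / 1000  # integral ~ 3 spikes
#' @export
compute_sdf <- function(spikes, window_ms, kernel_sd = 5) {
  stopifnot(window_ms >= 1)
  counts <- bin_spikes(spikes, window_ms)
  new_sdf(smooth_bins(counts, kernel_sd) * 1000, kernel_sd, "trial")
}

#' Trial-averaged spike density function
#'
#' Averages 1 ms bin counts across trials before convolution; by linearity
#' of the convolution this equals the average of per-trial SDFs.
#'
#' @param trials list of spike-time vectors (ms), one per trial.
#' @inheritParams compute_sdf
#' @return An `sdf_trace` with provenance "average".
#' @export
average_sdf <- function(trials, window_ms, kernel_sd = 5) {
  stopifnot(length(trials) >= 1)
  counts <- rowMeans(vapply(trials, bin_spikes, numeric(window_ms),
                            window_ms = window_ms))
  new_sdf(smooth_bins(counts, kernel_sd) * 1000, kernel_sd, "average")
}

new_sdf <- function(rate, kernel_sd, provenance) {
  structure(list(rate = rate, time = seq_along(rate) - 0.5,
                 kernel_sd = kernel_sd, provenance = provenance),
            class = "sdf_trace")
}

bin_spikes <- function(spikes, window_ms) {
  spikes <- spikes[spikes >= 0 & spikes < window_ms]
  tabulate(floor(spikes) + 1L, nbins = as.integer(window_ms))
}

# zero-padded Gaussian smoothing of a per-ms bin vector
smooth_bins <- function(x, kernel_sd) {
  half <- ceiling(4 * kernel_sd)
  k <- stats::dnorm(seq(-half, half), sd = kernel_sd)
  k <- k / sum(k)
  n <- length(x)
  y <- stats::convolve(c(numeric(half), x, numeric(half)), rev(k),
                       type = "filter")
  y[seq_len(n)]
}

#' Baseline firing statistics over the 500 ms pre-CS window
#'
#' @param trials list of spike-time vectors (ms), one per trial.
#' @param timing a [stimulus_timing()].
#' @param kernel_sd Gaussian kernel SD used for the SDF, ms.
#' @param baseline_ms length of the pre-CS baseline, ms.
#' @param edge_ms bins closer than this to the trial-window edges are
#'   excluded from the SD (kernel truncation biases them).
#' @return A `baseline_stats` list: `mean_rate` (Hz; baseline spike count
#'   over total baseline time), `sd` (SD across 1 ms bins of the
#'   trial-averaged baseline SDF, Hz), `cv` (SD/mean of baseline
#'   inter-spike intervals pooled over trials; `NA` and flagged when fewer
#'   than 2 baseline ISIs exist), `n_trials`, `n_spikes`, `cv_defined`.
#' @export
baseline_stats <- function(trials, timing, kernel_sd = 5,
                           baseline_ms = 500, edge_ms = 20) {
  stopifnot(inherits(timing, "stimulus_timing"), length(trials) >= 1)
  b0 <- timing$cs_onset - baseline_ms
  if (b0 < 0) stop("trial window does not contain the baseline period")
  n_spk <- sum(vapply(trials, function(s)
    sum(s >= b0 & s < timing$cs_onset), 0))
  mean_rate <- n_spk / (length(trials) * baseline_ms / 1000)

  avg <- average_sdf(trials, timing$trial_window, kernel_sd)
  bins <- seq.int(b0 + 1, timing$cs_onset)      # 1-based bins of baseline
  bins <- bins[avg$time[bins] >= edge_ms &
               avg$time[bins] <= timing$trial_window - edge_ms]
  sd_hz <- stats::sd(avg$rate[bins])

  isis <- unlist(lapply(trials, function(s)
    diff(s[s >= b0 & s < timing$cs_onset])))
  cv_ok <- length(isis) >= 2 && mean(isis) > 0
  structure(
    list(mean_rate = mean_rate, sd = sd_hz,
         cv = if (cv_ok) stats::sd(isis) / mean(isis) else NA_real_,
         cv_defined = cv_ok, n_trials = length(trials), n_spikes = n_spk),
    class = "baseline_stats")
}

#' Standardize an SDF to its baseline
#'
#' @param sdf an [`sdf_trace`][compute_sdf].
#' @param stats a [`baseline_stats`][baseline_stats].
#' @return Numeric z-score trace, one value per 1 ms bin.
#' @export
standardize_to_baseline <- function(sdf, stats) {
  if (!is.finite(stats$sd) || stats$sd <= 0)
    stop("degenerate baseline: SD is zero or undefined, cannot standardize")
  (sdf$rate - stats$mean_rate) / stats$sd
}

#' @export
print.sdf_trace <- function(x, ...) {
  cat(sprintf("sdf_trace (%s): %d ms, kernel SD %g ms, mean %.1f Hz\n",
              x$provenance, length(x$rate), x$kernel_sd, mean(x$rate)))
  invisible(x)
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("baseline: %.1f Hz (SDF SD %.2f Hz), ISI CV %s, %d trials / %d spikes\n",
              x$mean_rate, x$sd,
              if (x$cv_defined) sprintf("%.2f", x$cv) else "undefined",
              x$n_trials, x$n_spikes))
  invisible(x)
}
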