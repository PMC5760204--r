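#' Normalize an eyelid trace to the full blink range and smooth it
#'
#' Maps a raw eyelid signal to percent of the full blink range — 0% at the
#' resting open-eye level and 100% at the closed-eye level (the mean of the
#' UR peak values across trials) — and smooths it with a 2nd-order
#' Savitzky-Golay filter. At 250 samples/s the nominal 10 ms span is 2.5
#' samples; the nearest odd window of 3 samples (12 ms) is used, which for
#' an order-2 polynomial fit reproduces any locally quadratic segment
#' exactly.
#'
#' @param raw numeric vector, raw eyelid signal (arbitrary units).
#' @param open_level raw value of the resting open eye.
#' @param closed_level raw value of the closed eye (mean UR peak).
#' @param sg_window Savitzky-Golay window length, samples (odd).
#' @param sg_order Savitzky-Golay polynomial order.
#' @return Numeric vector, % of full blink range.
#' @export
normalize_and_smooth <- function(raw, open_level, closed_level,
                                 sg_window = 3, sg_order = 2) {
  if (closed_level <= open_level)
    stop("degenerate blink range: closed_level must exceed open_level")
  pct <- 100 * (raw - open_level) / (closed_level - open_level)
  if (sg_window > sg_order + 1 && length(pct) >= sg_window)
    pct <- as.numeric(signal::sgolayfilt(pct, p = sg_order, n = sg_window))
  pct
}

#' Quality-filter eyelid trials
#'
#' Removes trials with an unstable baseline via an iterative Grubbs test
#' (`alpha`) on per-trial baseline standard deviations, then removes trials
#' in which the eye was not at least halfway open (baseline mean position
#' >= 50% closure).
#'
#' @param pos samples-by-trials matrix of eyelid position, % closure.
#' @param time sample times, ms.
#' @param timing a [stimulus_timing()].
#' @param alpha Grubbs significance level.
#' @param baseline_ms baseline length, ms before CS onset.
#' @return List with `kept` (column indices retained), `exclusions` (data
#'   frame of `trial` and `reason`: "unstable_baseline" or
#'   "eye_half_closed"), `baseline_sd` and `baseline_mean` per trial. If
#'   every trial is excluded `kept` is `integer(0)`.
#' @export
filter_trials <- function(pos, time, timing, alpha = 0.05,
                          baseline_ms = 500) {
  stopifnot(is.matrix(pos), length(time) == nrow(pos))
  base <- time >= timing$cs_onset - baseline_ms & time < timing$cs_onset
  if (!any(base)) stop("baseline window not covered by the trace")
  bsd <- apply(pos[base, , drop = FALSE], 2, stats::sd)
  bmu <- colMeans(pos[base, , drop = FALSE])

  out_sd <- if (ncol(pos) >= 3) grubbs_outliers(bsd, alpha) else integer(0)
  out_cl <- setdiff(which(bmu >= 50), out_sd)
  exclusions <- rbind(
    if (length(out_sd)) data.frame(trial = out_sd, reason = "unstable_baseline"),
    if (length(out_cl)) data.frame(trial = out_cl, reason = "eye_half_closed"))
  if (is.null(exclusions))
    exclusions <- data.frame(trial = integer(0), reason = character(0))
  kept <- setdiff(seq_len(ncol(pos)), exclusions$trial)
  list(kept = kept, exclusions = exclusions,
       baseline_sd = bsd, baseline_mean = bmu)
}

#' Detect a conditioned response in one eyelid trial
#'
#' CR amplitude is the maximum eyelid position within the CS-US interval
#' minus the trial-baseline mean; a trial contains a CR when that amplitude
#' exceeds 5% of the full blink range. CR onset is the start of the last
#' unbroken run of positive eyelid velocity that carries the trace up to 5%
#' of the baseline-to-peak amplitude.
#'
#' @param trace numeric vector, eyelid position (% closure), already
#'   normalized and smoothed.
#' @param time sample times, ms.
#' @param timing a [stimulus_timing()].
#' @param threshold CR amplitude criterion, % closure (strict `>`).
#' @param baseline_ms baseline length, ms.
#' @return List: `is_cr`, `amplitude` (%), `amplitude_at_us` (%), `onset`
#'   (ms post-CS, `NA` unless `is_cr`), `peak_time` (ms post-CS).
#' @export
detect_cr <- function(trace, time, timing, threshold = 5,
                      baseline_ms = 500) {
  base <- time >= timing$cs_onset - baseline_ms & time < timing$cs_onset
  win <- time > timing$cs_onset & time < timing$us_onset
  if (!any(win)) stop("CS-US interval not covered by the trace")
  bmu <- mean(trace[base])
  widx <- which(win)
  ipk <- widx[which.max(trace[widx])]
  amplitude <- trace[ipk] - bmu
  at_us <- stats::approx(time, trace, xout = timing$us_onset, rule = 2)$y - bmu
  is_cr <- amplitude > threshold
  onset <- NA_real_
  if (is_cr) {
    # velocity by central differences on the smoothed trace
    vel <- c(NA, diff(trace, lag = 2) / (2 * diff(time)[1]), NA)
    level <- bmu + 0.05 * amplitude
    # last sample before the peak where the trace is still below the 5% level
    pre <- which(time < time[ipk] & trace <= level &
                   time >= timing$cs_onset - baseline_ms)
    icross <- if (length(pre)) max(pre) + 1L else widx[1]
    i <- icross
    while (i > 1 && !is.na(vel[i - 1]) && vel[i - 1] > 0) i <- i - 1L
    onset <- time[i] - timing$cs_onset
  }
  list(is_cr = is_cr, amplitude = amplitude, amplitude_at_us = at_us,
       onset = onset, peak_time = time[ipk] - timing$cs_onset)
}

#' Summarize behavioral performance across a session
#'
#' @param cr_results list of [detect_cr()] results for the retained trials.
#' @return List: `n_trials`, `cr_percent`, `mean_cr_amplitude` (mean
#'   amplitude of CR trials, %), `mean_amp_at_us` (all trials),
#'   `with_behavior` (`TRUE` when CRs occur in at least 20% of trials,
#'   inclusive boundary).
#' @export
behavior_summary <- function(cr_results) {
  stopifnot(length(cr_results) >= 1)
  is_cr <- vapply(cr_results, `[[`, logical(1), "is_cr")
  amp <- vapply(cr_results, `[[`, numeric(1), "amplitude")
  at_us <- vapply(cr_results, `[[`, numeric(1), "amplitude_at_us")
  pct <- 100 * mean(is_cr)
  list(n_trials = length(is_cr), cr_percent = pct,
       mean_cr_amplitude = if (any(is_cr)) mean(amp[is_cr]) else NA_real_,
       mean_amp_at_us = mean(at_us),
       with_behavior = pct >= 20)
}

#' Eyelid velocity trace
#'
#' Central-difference derivative of a (smoothed) eyelid position trace, in
#' % closure per ms; endpoints use one-sided differences.
#'
#' @param trace eyelid position, % closure.
#' @param sample_ms sample period, ms.
#' @return Numeric vector, same length as `trace`.
#' @export
eyelid_velocity <- function(trace, sample_ms = 4) {
  n <- length(trace)
  if (n < 3) return(rep(NA_real_, n))
  c(trace[2] - trace[1],
    diff(trace, lag = 2) / 2,
    trace[n] - trace[n - 1]) / sample_ms
}
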