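#' Classify CS-US spike facilitation or suppression
#'
#' Scores modulation over the last 200 ms of the CS-US interval relative to
#' the baseline mean, correcting for same-signed excursions within the
#' baseline itself: the facilitation score is the mean above-baseline rate
#' in the window minus the mean above-baseline activity within the baseline;
#' the suppression score is the mirror image. A cell is labeled facilitation
#' (suppression) when the corresponding score reaches at least 5 Hz; when
#' both scores pass, the larger magnitude wins (ties go to facilitation).
#' Modulation duration is the total number of 1 ms bins in the window
#' exceeding 3 baseline SDs; onset is the first bin of the first
#' supra-threshold run of at least 10 ms anywhere in the CS-US interval
#' (undefined when no such run exists).
#'
#' @param avg_sdf trial-averaged [`sdf_trace`][average_sdf].
#' @param stats a [baseline_stats()].
#' @param timing a [stimulus_timing()].
#' @param threshold_hz modulation criterion, Hz (inclusive).
#' @param sd_mult threshold (in baseline SDs) for the duration/onset bins.
#' @param min_run_ms minimum supra-threshold run for onset, ms.
#' @param window_ms scored portion at the end of the CS-US interval, ms.
#' @param baseline_ms,edge_ms baseline definition, as in [baseline_stats()].
#' @return A `modulation_profile` list: `label` ("facilitation",
#'   "suppression" or "none"), `amplitude` (winning score, Hz),
#'   `fac_score`, `sup_score`, `duration` (ms), `onset` and `peak_time`
#'   (ms post-CS), `max_rate` (Hz), `max_rate_velocity` (Hz/ms, in the
#'   direction of the modulation).
#' @export
classify_csus <- function(avg_sdf, stats, timing, threshold_hz = 5,
                          sd_mult = 3, min_run_ms = 10, window_ms = 200,
                          baseline_ms = 500, edge_ms = 20) {
  if (timing$csus_interval < window_ms)
    stop("CS-US interval shorter than the scoring window")
  rate <- avg_sdf$rate
  t <- avg_sdf$time
  if (timing$us_onset > length(rate))
    stop("SDF trace does not cover the CS-US interval")
  mu <- stats$mean_rate
  win <- t > timing$us_onset - window_ms & t <= timing$us_onset
  base <- t >= timing$cs_onset - baseline_ms & t < timing$cs_onset &
    t >= edge_ms & t <= timing$trial_window - edge_ms

  fac_score <- mean(rate[win] - mu) - mean(pmax(rate[base] - mu, 0))
  sup_score <- mean(mu - rate[win]) - mean(pmax(mu - rate[base], 0))

  label <- "none"
  if (fac_score >= threshold_hz || sup_score >= threshold_hz)
    label <- if (fac_score >= sup_score) "facilitation" else "suppression"

  interval <- t > timing$cs_onset & t <= timing$us_onset
  dirsign <- if (label == "suppression") -1 else 1
  excess <- dirsign * (rate - mu)
  above <- excess > sd_mult * stats$sd
  duration <- sum(above & win)

  onset <- NA_real_
  run <- first_long_run(above & interval, min_run_ms)
  if (!is.null(run)) onset <- t[run[1]] - timing$cs_onset

  iext <- which(interval)[which.max(excess[interval])]
  drate <- c(0, diff(rate, lag = 2) / 2, 0)     # Hz/ms, central differences
  vel <- if (label == "none") NA_real_ else max(dirsign * drate[interval])

  structure(
    list(label = label,
         amplitude = if (label == "suppression") sup_score else fac_score,
         fac_score = fac_score, sup_score = sup_score,
         duration = duration, onset = onset,
         peak_time = t[iext] - timing$cs_onset,
         max_rate = rate[iext], max_rate_velocity = vel),
    class = "modulation_profile")
}

#' @export
print.modulation_profile <- function(x, ...) {
  cat(sprintf("CS-US modulation: %s (%.1f Hz, duration %g ms, onset %s ms, peak %g ms)\n",
              x$label, x$amplitude, x$duration,
              if (is.na(x$onset)) "undefined" else format(x$onset),
              x$peak_time))
  invisible(x)
}

#' Detect transient CS responses (pause or peak)
#'
#' Searches the baseline-standardized trial-averaged SDF between 50 and
#' 125 ms post-CS. A rapid drop below -4.5 SD is a CS pause if it is
#' followed, within the rebound window, by a peak of at least +2 SD relative
#' to baseline; an upstroke above +4.5 SD is a CS peak if followed by a drop
#' below -2 SD.
#'
#' @param z baseline-standardized trial-averaged SDF (per 1 ms bin).
#' @param timing a [stimulus_timing()].
#' @param window search window, ms post-CS.
#' @param threshold_sd extremum criterion, SD.
#' @param rebound_sd rebound criterion, SD (relative to baseline).
#' @param rebound_ms rebound search window after the extremum, ms.
#' @return List of two `transient_response` records (`cs_pause`,
#'   `cs_peak`), each with `kind`, `present`, `latency` (ms post-CS) and
#'   `amplitude_z`.
#' @export
detect_cs_transient <- function(z, timing, window = c(50, 125),
                                threshold_sd = 4.5, rebound_sd = 2,
                                rebound_ms = 100) {
  t <- seq_along(z) - 0.5
  win <- t >= timing$cs_onset + window[1] & t <= timing$cs_onset + window[2]
  if (!any(win)) stop("z-trace does not cover the CS search window")
  res <- list()
  for (kind in c("cs_pause", "cs_peak")) {
    sgn <- if (kind == "cs_pause") -1 else 1
    v <- sgn * z
    iext <- which(win)[which.max(v[win])]
    hit <- v[iext] > threshold_sd
    if (hit) {
      after <- t > t[iext] & t <= t[iext] + rebound_ms
      hit <- any(-sgn * z[after] > rebound_sd)
    }
    res[[kind]] <- transient_response(kind, hit, t[iext] - timing$cs_onset,
                                      z[iext])
  }
  res
}

transient_response <- function(kind, present, latency, amplitude_z) {
  structure(list(kind = kind, present = present,
                 latency = if (present) latency else NA_real_,
                 amplitude_z = amplitude_z),
            class = "transient_response")
}

#' Detect US-locked transient responses
#'
#' Evaluates three stereotyped responses of the standardized trial-averaged
#' SDF after the US, each in its own window and against dual criteria that
#' reference both the baseline (z = 0) and the mean level over the last
#' 50 ms of the CS-US interval (`e`):
#' \itemize{
#'   \item first US peak (1-30 ms post-US): maximum exceeds `e` by 5 SD, or
#'     exceeds `e` by 2 SD while also lying 5 SD above baseline;
#'   \item US pause (16-45 ms): minimum lies 5 SD below `e` and at least
#'     2 SD below baseline, or 2 SD below `e` and 5 SD below baseline; the
#'     subsequent turnaround must regress at least 2 SD back toward
#'     baseline;
#'   \item second US peak (31-60 ms): at least 2 SD above `e` and 5 SD above
#'     baseline, with the same 2 SD turnaround requirement.
#' }
#'
#' @inheritParams detect_cs_transient
#' @param turnaround_ms search window for the turnaround, ms.
#' @return List of `transient_response` records (`us_peak1`, `us_pause`,
#'   `us_peak2`) with latencies in ms post-US; also carries
#'   `interval_end_ref` (`e`).
#' @export
detect_us_responses <- function(z, timing, turnaround_ms = 100) {
  t <- seq_along(z) - 0.5
  us <- timing$us_onset
  if (length(z) < us + 80)
    stop("z-trace must extend at least 80 ms past US onset")
  e <- mean(z[t > us - 50 & t <= us])

  eval_resp <- function(kind, w0, w1, sgn, needs_turnaround) {
    win <- t >= us + w0 & t <= us + w1
    v <- sgn * z
    iext <- which(win)[which.max(v[win])]
    m <- z[iext]
    hit <- switch(kind,
      us_peak1 = (m - e >= 5) || (m - e >= 2 && m >= 5),
      us_peak2 = (m - e >= 2) && m >= 5,
      us_pause = (e - m >= 5 && m <= -2) || (e - m >= 2 && m <= -5))
    if (hit && needs_turnaround) {
      after <- t > t[iext] & t <= t[iext] + turnaround_ms
      hit <- any(sgn * (m - z[after]) >= 2)
    }
    transient_response(kind, hit, t[iext] - us, m)
  }

  out <- list(
    us_peak1 = eval_resp("us_peak1", 1, 30, 1, FALSE),
    us_pause = eval_resp("us_pause", 16, 45, -1, TRUE),
    us_peak2 = eval_resp("us_peak2", 31, 60, 1, TRUE))
  attr(out, "interval_end_ref") <- e
  out
}

#' Per-trial amplitude of a detected US response
#'
#' For each trial, takes the extremum of the absolute firing rate (maximum
#' for peaks, minimum for pauses) within a 30 ms window centered at the
#' cell-average response time.
#'
#' @param trial_sdfs list of single-trial [`sdf_trace`][compute_sdf]s.
#' @param center_ms cell-average response time, ms from trial start.
#' @param kind one of `"peak"` or `"pause"`.
#' @param half_ms half-width of the window, ms.
#' @return List: `value` (Hz per trial), `clipped` (`TRUE` when the window
#'   had to be clipped at a trace edge).
#' @export
trialwise_us_metrics <- function(trial_sdfs, center_ms, kind = "peak",
                                 half_ms = 15) {
  stopifnot(kind %in% c("peak", "pause"))
  n_bins <- length(trial_sdfs[[1]]$rate)
  lo <- max(1, floor(center_ms - half_ms) + 1)
  hi <- min(n_bins, ceiling(center_ms + half_ms))
  clipped <- lo > floor(center_ms - half_ms) + 1 ||
    hi < ceiling(center_ms + half_ms)
  f <- if (kind == "peak") max else min
  list(value = vapply(trial_sdfs, function(s) f(s$rate[lo:hi]), 0),
       clipped = clipped)
}
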