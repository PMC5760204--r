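#' Stimulus timing for a paired CS-US trial
#'
#' Describes when the conditional stimulus (CS, an LED light) and the
#' unconditional stimulus (US, a corneal air puff) occur within the trial
#' window. In paired trials the two stimuli co-terminate, so the US onset is
#' derived as `cs_onset + cs_duration - us_duration` and the CS-US interval
#' (the learning-relevant delay) as `us_onset - cs_onset`.
#'
#' @param cs_onset CS onset, ms from trial start. Default 500 ms, leaving a
#'   500 ms pre-CS baseline.
#' @param cs_duration CS duration, ms.
#' @param us_duration US duration, ms.
#' @param trial_window total trial length, ms.
#' @return An object of class `stimulus_timing`: a list with fields
#'   `cs_onset`, `cs_duration`, `us_duration`, `us_onset`, `csus_interval`,
#'   `trial_window` (all ms).
#' @examples
#' stimulus_timing()                      # 260/10 ms -> 250 ms interval
#' stimulus_timing(cs_duration = 220, us_duration = 20)  # 200 ms interval
#' @export
stimulus_timing <- function(cs_onset = 500, cs_duration = 260,
                            us_duration = 10, trial_window = 2000) {
  us_onset <- cs_onset + cs_duration - us_duration
  csus_interval <- us_onset - cs_onset
  if (csus_interval <= 0)
    stop("CS-US interval must be positive (cs_duration > us_duration)")
  if (cs_onset + cs_duration > trial_window)
    stop("stimuli do not fit inside the trial window")
  structure(
    list(cs_onset = cs_onset, cs_duration = cs_duration,
         us_duration = us_duration, us_onset = us_onset,
         csus_interval = csus_interval, trial_window = trial_window),
    class = "stimulus_timing")
}

#' @rdname stimulus_timing
#' @details `timing_dataset1()` gives the first-dataset protocol (260 ms CS
#'   co-terminating with a 10 ms US, 250 ms CS-US interval);
#'   `timing_dataset2()` the second-dataset protocol (220 ms CS, 20 ms US,
#'   200 ms interval).
#' @export
timing_dataset1 <- function() stimulus_timing(500, 260, 10, 2000)

#' @rdname stimulus_timing
#' @export
timing_dataset2 <- function() stimulus_timing(500, 220, 20, 2000)

#' @export
print.stimulus_timing <- function(x, ...) {
  cat(sprintf(
    "stimulus_timing: CS %g ms at t=%g ms, US %g ms at t=%g ms (CS-US interval %g ms), window %g ms\n",
    x$cs_duration, x$cs_onset, x$us_duration, x$us_onset,
    x$csus_interval, x$trial_window))
  invisible(x)
}
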