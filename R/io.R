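#' Write a session to the pipeline's canonical on-disk formats
#'
#' Writes `spikes.csv` (`cell_id`, `trial_id`, `spike_time_ms`),
#' `eyelid.csv` (`cell_id`, `trial_id`, `time_ms`, `eyelid_pct`) and
#' `metadata.json` (stimulus timing, recording metadata, and — for
#' synthetic sessions — the generator config and per-trial ground truth).
#'
#' @param session result of [generate_session()], or a bare
#'   `cell_recording`.
#' @param dir output directory (created if needed).
#' @param cell_id identifier written to the tables.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir, cell_id = "cell01") {
  if (inherits(session, "cell_recording"))
    session <- list(recording = session, ground_truth = NULL)
  rec <- session$recording
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(rec$spikes)

  spikes <- data.frame(
    cell_id = cell_id,
    trial_id = rep(seq_len(n), lengths(rec$spikes)),
    spike_time_ms = unlist(rec$spikes))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)

  ey <- rec$eyelid
  eyelid <- data.frame(
    cell_id = cell_id,
    trial_id = rep(seq_len(n), each = length(ey$time)),
    time_ms = rep(ey$time, n),
    eyelid_pct = as.vector(ey$pos))
  utils::write.csv(eyelid, file.path(dir, "eyelid.csv"), row.names = FALSE)

  meta <- list(cell_id = cell_id,
               timing = unclass(rec$timing),
               meta = rec$meta,
               n_trials = n)
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    meta$ground_truth <- list(
      config = unclass(gt$config),
      trials = gt$trials,
      expected_csus_amp = gt$expected_csus_amp,
      cr_onset_ms = gt$cr_onset_ms)
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, c("spikes.csv", "eyelid.csv", "metadata.json")))
}

#' Read a session written by [write_session()]
#'
#' @param dir directory holding `spikes.csv`, `eyelid.csv`,
#'   `metadata.json`.
#' @return A list with `recording` (class `cell_recording`) and
#'   `ground_truth` (`NULL` when the session carries none).
#' @export
read_session <- function(dir) {
  paths <- file.path(dir, c("spikes.csv", "eyelid.csv", "metadata.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing session file(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  timing <- stimulus_timing(meta$timing$cs_onset, meta$timing$cs_duration,
                            meta$timing$us_duration,
                            meta$timing$trial_window)
  n <- meta$n_trials

  spikes_df <- utils::read.csv(paths[1])
  spikes <- lapply(seq_len(n), function(i)
    spikes_df$spike_time_ms[spikes_df$trial_id == i])

  ey_df <- utils::read.csv(paths[2])
  time <- sort(unique(ey_df$time_ms))
  pos <- matrix(0, length(time), n)
  for (i in seq_len(n)) {
    sub <- ey_df[ey_df$trial_id == i, ]
    pos[, i] <- sub$eyelid_pct[order(sub$time_ms)]
  }

  recording <- structure(
    list(spikes = spikes, eyelid = list(time = time, pos = pos),
         timing = timing, meta = meta$meta),
    class = "cell_recording")
  gt <- NULL
  if (!is.null(meta$ground_truth))
    gt <- list(config = meta$ground_truth$config,
               trials = meta$ground_truth$trials,
               expected_csus_amp = meta$ground_truth$expected_csus_amp,
               cr_onset_ms = meta$ground_truth$cr_onset_ms)
  list(recording = recording, ground_truth = gt)
}
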