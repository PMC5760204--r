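#' Configuration for the end-to-end analysis pipeline
#'
#' Collects paths, stimulus timing, stage toggles, the generator config and
#' every numerical detection criterion, each defaulting to the value the
#' analysis is defined with (5 Hz modulation criterion, 3 SD duration
#' threshold, 4.5/2 SD CS-transient criteria, 5/2 SD US criteria, 20 ms
#' correlation bins, 500 bootstrap repetitions). Overrides of any criterion
#' are recorded in the run manifest.
#'
#' @param out_dir output directory for all stage products.
#' @param seed master seed for the run.
#' @param timing a [stimulus_timing()].
#' @param sim a [sim_config()] for the simulate stage.
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "preprocess", "spike", "classify", "correlate",
#'   "model")`.
#' @param input_dir directory with an existing session (used when
#'   "simulate" is not among the stages).
#' @param thresholds named list of criterion overrides; see Details.
#' @param model named list of model-stage settings: `n_cells`,
#'   `pc_trials`, `suppression_depth` (Hz), `n_output_trials`, `params`
#'   (an [ipn_params()]).
#' @details Recognized threshold keys and defaults: `modulation_hz` (5),
#'   `duration_sd` (3), `min_run_ms` (10), `cs_sd` (4.5), `cs_rebound_sd`
#'   (2), `cr_pct` (5), `corr_bin_ms` (20), `bootstrap_reps` (500),
#'   `alpha` (0.05), `kernel_sd` (5), `lag_range` (c(-200, 200)).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            timing = timing_dataset1(),
                            sim = sim_config(),
                            stages = c("simulate", "preprocess", "spike",
                                       "classify", "correlate", "model"),
                            input_dir = NULL,
                            thresholds = list(),
                            model = list()) {
  defaults <- list(modulation_hz = 5, duration_sd = 3, min_run_ms = 10,
                   cs_sd = 4.5, cs_rebound_sd = 2, cr_pct = 5,
                   corr_bin_ms = 20, bootstrap_reps = 500, alpha = 0.05,
                   kernel_sd = 5, lag_range = c(-200, 200))
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  model_defaults <- list(n_cells = 1, pc_trials = 10,
                         suppression_depth = 40, n_output_trials = 10,
                         params = ipn_params())
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), timing = timing,
         sim = sim, stages = stages, input_dir = input_dir,
         thresholds = utils::modifyList(defaults, thresholds),
         overridden = names(thresholds),
         model = utils::modifyList(model_defaults, model)),
    class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages in order — simulate, preprocess (eyelid
#' filtering and CR detection), spike (SDF and baseline statistics),
#' classify (CS-US modulation and CS/US transients), correlate
#' (trial-by-trial correlation, correlation matrices, temporal
#' cross-correlation), model (surrogate expansion and the
#' integrate-and-fire nuclear neuron) — writing each stage's tables under
#' `config$out_dir` and returning a run manifest. A stage failure halts the
#' run and leaves a machine-readable `error.json`.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (also written to `manifest.json`): package version,
#'   seed, config hash, stages run and their output files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  outputs <- list()
  state <- new.env(parent = emptyenv())

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(
    list(seed = config$seed, timing = unclass(config$timing),
         sim = unclass(config$sim), stages = config$stages,
         thresholds = th, overridden = config$overridden),
    cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config_hash <- unname(tools::md5sum(cfg_path))

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      jsonlite::write_json(
        list(stage = name, error = conditionMessage(res)),
        file.path(config$out_dir, "error.json"), auto_unbox = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    outputs[[name]] <<- res
  }

  load_session <- function() {
    if (!is.null(state$session)) return(state$session)
    dir <- if ("simulate" %in% config$stages) config$out_dir
           else config$input_dir
    if (is.null(dir)) stop("no input_dir configured and simulate disabled")
    state$session <- read_session(dir)
    state$session
  }

  for (stage in config$stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        sess <- generate_session(config$sim, config$timing, config$seed)
        state$session <- sess
        as.character(write_session(sess, config$out_dir))
      }),
      preprocess = run_stage("preprocess", function() {
        sess <- load_session()
        ey <- sess$recording$eyelid
        flt <- filter_trials(ey$pos, ey$time, config$timing,
                             alpha = th$alpha)
        crs <- lapply(flt$kept, function(i)
          detect_cr(ey$pos[, i], ey$time, config$timing,
                    threshold = th$cr_pct))
        cr_table <- data.frame(
          trial = flt$kept,
          is_cr = vapply(crs, `[[`, TRUE, "is_cr"),
          amplitude = vapply(crs, `[[`, 0, "amplitude"),
          amplitude_at_us = vapply(crs, `[[`, 0, "amplitude_at_us"),
          onset = vapply(crs, `[[`, 0, "onset"))
        utils::write.csv(cr_table,
                         file.path(config$out_dir, "cr_table.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          c(list(exclusions = flt$exclusions),
            behavior_summary(crs)),
          file.path(config$out_dir, "behavior.json"),
          auto_unbox = TRUE, digits = NA)
        state$cr_table <- cr_table
        state$kept <- flt$kept
        c("cr_table.csv", "behavior.json")
      }),
      spike = run_stage("spike", function() {
        sess <- load_session()
        trials <- sess$recording$spikes
        avg <- average_sdf(trials, config$timing$trial_window,
                           th$kernel_sd)
        bs <- baseline_stats(trials, config$timing, th$kernel_sd)
        utils::write.csv(
          data.frame(time_ms = avg$time, rate_hz = avg$rate),
          file.path(config$out_dir, "sdf_average.csv"), row.names = FALSE)
        utils::write.csv(
          data.frame(mean_rate = bs$mean_rate, sd = bs$sd, cv = bs$cv,
                     n_trials = bs$n_trials, n_spikes = bs$n_spikes),
          file.path(config$out_dir, "baseline_stats.csv"),
          row.names = FALSE)
        state$avg_sdf <- avg
        state$bstats <- bs
        c("sdf_average.csv", "baseline_stats.csv")
      }),
      classify = run_stage("classify", function() {
        if (is.null(state$avg_sdf)) stop("classify requires the spike stage")
        prof <- classify_csus(state$avg_sdf, state$bstats, config$timing,
                              threshold_hz = th$modulation_hz,
                              sd_mult = th$duration_sd,
                              min_run_ms = th$min_run_ms)
        z <- standardize_to_baseline(state$avg_sdf, state$bstats)
        cs <- detect_cs_transient(z, config$timing,
                                  threshold_sd = th$cs_sd,
                                  rebound_sd = th$cs_rebound_sd)
        us <- detect_us_responses(z, config$timing)
        jsonlite::write_json(
          list(modulation = unclass(prof),
               cs = lapply(cs, unclass), us = lapply(us, unclass)),
          file.path(config$out_dir, "classification.json"),
          auto_unbox = TRUE, digits = NA)
        state$profile <- prof
        "classification.json"
      }),
      correlate = run_stage("correlate", function() {
        sess <- load_session()
        if (is.null(state$cr_table)) stop("correlate requires preprocess")
        kept <- state$kept
        timing <- config$timing
        spk_rate <- vapply(sess$recording$spikes[kept], function(s)
          compute_sdf(s, timing$trial_window, th$kernel_sd)$rate,
          numeric(timing$trial_window))
        win <- seq.int(timing$us_onset - 199, timing$us_onset)
        x <- colMeans(spk_rate[win, , drop = FALSE])
        y <- state$cr_table$amplitude_at_us
        tc <- trial_correlation(x, y, alpha = th$alpha)
        ey <- sess$recording$eyelid
        cm_pos <- correlation_matrix(spk_rate, ey$pos[, kept, drop = FALSE],
                                     ey$time, th$corr_bin_ms, "position")
        vel <- apply(ey$pos[, kept, drop = FALSE], 2, eyelid_velocity,
                     sample_ms = diff(ey$time)[1])
        cm_vel <- correlation_matrix(spk_rate, vel, ey$time,
                                     th$corr_bin_ms, "velocity")
        avg <- average_sdf(sess$recording$spikes[kept],
                           timing$trial_window, th$kernel_sd)
        xc <- temporal_cross_correlation(avg, ey$time,
                                         rowMeans(ey$pos[, kept,
                                                         drop = FALSE]),
                                         timing, th$lag_range)
        utils::write.csv(cm_pos$r,
                         file.path(config$out_dir, "corr_matrix_position.csv"))
        utils::write.csv(cm_vel$r,
                         file.path(config$out_dir, "corr_matrix_velocity.csv"))
        jsonlite::write_json(
          list(trial_correlation = tc,
               cross_correlation = list(best_lag = xc$best_lag,
                                        peak_r = xc$peak_r)),
          file.path(config$out_dir, "correlation.json"),
          auto_unbox = TRUE, digits = NA)
        c("corr_matrix_position.csv", "corr_matrix_velocity.csv",
          "correlation.json")
      }),
      model = run_stage("model", function() {
        mc <- config$model
        prof <- pc_suppression_profile(mc$suppression_depth,
                                       timing = config$timing)
        cells <- lapply(seq_len(mc$n_cells), function(i) {
          pc <- generate_pc_simple_spike_set(
            1, mc$pc_trials, prof, config$timing,
            seed = config$seed + i)[[1]]
          model_ipn_cell(pc, mc$params, mc$n_output_trials,
                         config$timing$trial_window,
                         seed = config$seed + 1000 + i)$output
        })
        summ <- model_population_summary(cells, config$timing)
        utils::write.csv(summ, file.path(config$out_dir, "model_summary.csv"),
                         row.names = FALSE)
        "model_summary.csv"
      }),
      stop("unknown stage: ", stage))
  }

  manifest <- list(
    package = "ipnblink",
    version = as.character(utils::packageVersion("ipnblink")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = config_hash,
    stages = lapply(outputs, identity),
    n_stages = length(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
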