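#' Write an experiment to a plain-text directory
#'
#' One directory per experiment: `traces.csv` and `neuropil.csv` (frames x
#' neurons), `positions.csv`, `trial_table.csv`, `ground_truth.csv` (when
#' present), and `params.yaml` holding the stimulus spec, frame rate and
#' seed. Everything is plain text so experiments round-trip across tools.
#'
#' @param experiment an `ild_experiment`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(experiment$recording$traces),
                     file.path(dir, "traces.csv"))
  data.table::fwrite(as.data.frame(experiment$recording$neuropil),
                     file.path(dir, "neuropil.csv"))
  data.table::fwrite(experiment$recording$positions,
                     file.path(dir, "positions.csv"))
  data.table::fwrite(as.data.frame(experiment$trials),
                     file.path(dir, "trial_table.csv"))
  if (!is.null(experiment$neurons))
    data.table::fwrite(experiment$neurons, file.path(dir, "ground_truth.csv"))
  spec <- experiment$spec
  yaml::write_yaml(list(spec = unclass(spec),
                        frame_rate_hz = experiment$recording$frame_rate_hz,
                        seed = experiment$seed),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir the experiment directory.
#' @return an `ild_experiment`.
#' @export
read_experiment <- function(dir) {
  params <- yaml::read_yaml(file.path(dir, "params.yaml"))
  spec <- do.call(stimulus_spec, params$spec[
    intersect(names(params$spec), names(formals(stimulus_spec)))])
  trials <- as.data.frame(data.table::fread(file.path(dir,
                                                      "trial_table.csv")))
  class(trials) <- c("trial_table", "data.frame")
  traces <- as.matrix(data.table::fread(file.path(dir, "traces.csv")))
  neuropil <- as.matrix(data.table::fread(file.path(dir, "neuropil.csv")))
  positions <- as.data.frame(data.table::fread(file.path(dir,
                                                         "positions.csv")))
  gt_path <- file.path(dir, "ground_truth.csv")
  neurons <- if (file.exists(gt_path))
    as.data.frame(data.table::fread(gt_path)) else NULL
  structure(list(spec = spec, trials = trials, neurons = neurons,
                 recording = list(traces = unname(traces),
                                  neuropil = unname(neuropil),
                                  frame_rate_hz = params$frame_rate_hz,
                                  positions = positions),
                 seed = params$seed),
            class = "ild_experiment")
}

#' Export a response tensor as a tidy CSV
#'
#' One row per (neuron, trial): condition labels and the response, pre-
#' and post-window peaks.
#'
#' @param tensor a `response_tensor`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_responses <- function(tensor, path) {
  tr <- tensor$trials
  n <- nrow(tensor$responses)
  out <- data.frame(
    neuron = rep(seq_len(n), times = nrow(tr)),
    trial = rep(tr$trial, each = n),
    stim_class = rep(tr$stim_class, each = n),
    ild_db = rep(tr$ild_db, each = n),
    abl_db = rep(tr$abl_db, each = n),
    freq_hz = rep(tr$freq_hz, each = n),
    level_db = rep(tr$level_db, each = n),
    pre_peak = as.vector(tensor$pre_peaks),
    post_peak = as.vector(tensor$post_peaks),
    response = as.vector(tensor$responses))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Export a run report's summary tables
#'
#' Writes the report summaries as CSV (responsiveness, categories,
#' decoder curve, pairwise correlations when present) and a JSON overview
#' (counts, config hash, cluster-test outcomes, gradient).
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$summary$responsiveness))
    data.table::fwrite(report$summary$responsiveness,
                       file.path(dir, "responsiveness.csv"))
  if (!is.null(report$summary$categories))
    data.table::fwrite(report$summary$categories,
                       file.path(dir, "categories.csv"))
  if (!is.null(report$decoder$curve))
    data.table::fwrite(report$decoder$curve,
                       file.path(dir, "decoder_curve.csv"))
  if (!is.null(report$profiles$noise))
    data.table::fwrite(report$profiles$noise,
                       file.path(dir, "noise_profiles.csv"))
  if (!is.null(report$profiles$tone))
    data.table::fwrite(report$profiles$tone,
                       file.path(dir, "tone_profiles.csv"))
  ov <- list(version = report$version, config_hash = report$config_hash,
             counts = report$counts,
             cluster = lapply(report$spatial[c("ild", "bf", "category")],
                              function(ct) if (inherits(ct, "cluster_test"))
                                list(observed = ct$observed,
                                     percentile = ct$percentile,
                                     significant = ct$significant,
                                     conclusive = ct$conclusive)),
             gradient_angle_deg = report$spatial$gradient$angle_deg,
             bf_variation_oct = report$spatial$bf_variation_oct)
  jsonlite::write_json(ov, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
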