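#' Default analysis configuration
#'
#' Every analysis parameter surfaced in one list. The defaults are the
#' study's standard protocol: response t-tests at alpha 0.01, ANOVAs at
#' alpha 0.05, 14-frame response windows, 0.02 Hz high-pass cutoff,
#' neuropil contamination ratio 0.6, BII facilitation/inhibition bounds
#' 1.2 / 0.8, 150 um spatial clustering threshold, 10 kHz BF floor for the
#' ILD/category cluster tests, and 1000 bootstrap or resampling iterations.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    alpha_response = 0.01,
    alpha_anova = 0.05,
    alpha_cluster = 0.05,
    alpha_correlation = 0.01,
    bii_low = 0.8,
    bii_high = 1.2,
    window_frames = 14L,
    response_statistic = "max",
    highpass_cutoff_hz = 0.02,
    r_np = 0.6,
    cluster_threshold_um = 150,
    min_bf_hz = 10000,
    n_boot = 1000L,
    decoder_n_rep = 1000L,
    decoder_sizes = c(10, 25, 50, 100, 200, 300),
    correlation_n_iter = 1000L,
    floor_negative = TRUE,
    stages = c("extract", "tune", "categorize", "decode", "spatial"),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Validate experiment inputs
#'
#' Structural diagnostics on an experiment before analysis: trace /
#' neuropil shape agreement, finite frame rate, trial onsets inside the
#' recording, presence of positions, and condition completeness of the
#' trial table. Returns diagnostics; never throws.
#'
#' @param experiment an `ild_experiment` (or any list with `recording` and
#'   `trials`).
#' @return data.frame of issues (`check`, `message`); zero rows when clean.
#' @export
validate_inputs <- function(experiment) {
  issues <- list()
  add <- function(check, msg)
    issues[[length(issues) + 1L]] <<- data.frame(check = check,
                                                 message = msg)
  rec <- experiment$recording
  tr <- experiment$trials
  if (is.null(rec$traces)) add("traces", "missing traces matrix")
  if (is.null(rec$neuropil)) {
    add("neuropil",
        "missing neuropil traces; supply them or set r_np = 0")
  } else if (!is.null(rec$traces) &&
             !all(dim(rec$traces) == dim(rec$neuropil))) {
    add("neuropil", "neuropil shape differs from traces")
  }
  if (is.null(rec$frame_rate_hz) || !is.finite(rec$frame_rate_hz) ||
      rec$frame_rate_hz <= 0)
    add("frame_rate", "frame rate missing or non-positive")
  if (is.null(rec$positions))
    add("positions", "missing neuron positions; spatial stages will fail")
  if (is.null(tr)) {
    add("trials", "missing trial table")
  } else {
    if (!is.null(rec$traces) && max(tr$onset_frame) > nrow(rec$traces))
      add("trials", "trial onset beyond trace length")
    if (anyDuplicated(tr$trial)) add("trials", "duplicate trial ids")
    bin <- tr[tr$stim_class == "binaural", ]
    if (nrow(bin) && any(table(bin$ild_db, bin$abl_db) == 0))
      add("trials", "incomplete ILD x ABL condition grid")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(check = character(), message = character())
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — extract (trace preprocessing and
#' windowed responses), tune (per-neuron profiles), categorize (binaural
#' classes per ABL), decode (channel assignment and opponent-channel error
#' curve), spatial (cluster tests and tonotopic gradient) — and assembles
#' a run report with per-stage counts, exclusion logs, summary tables, a
#' config hash and the package version. Reruns with the same inputs and
#' config are reproducible through the config seed.
#'
#' @param experiment an `ild_experiment` (from [simulate_experiment()] or
#'   [read_experiment()]).
#' @param config a [default_config()] list.
#' @return a list of class `run_report`.
#' @export
run_pipeline <- function(experiment, config = default_config()) {
  stages <- config$stages
  report <- list(config = config,
                 config_hash = rlang::hash(unclass(config)),
                 version = as.character(utils::packageVersion("ildtuning")),
                 counts = list(), exclusions = list(), timings = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  proc <- NULL; profiles <- NULL
  if ("extract" %in% stages) {
    proc <- run_stage("extract", function() {
      process_recording(experiment$recording, experiment$trials,
                        cutoff_hz = config$highpass_cutoff_hz,
                        r_np = config$r_np,
                        window_frames = config$window_frames,
                        statistic = config$response_statistic)
    })
    report$counts$neurons_in <- ncol(experiment$recording$traces)
    report$counts$neurons_analyzed <- length(proc$kept)
    report$counts$neurons_excluded <- nrow(proc$excluded)
    report$exclusions$extract <- proc$excluded
    report$counts$trials <- nrow(proc$tensor$trials)
    report$tensor <- proc$tensor
  }

  if ("tune" %in% stages && !is.null(proc)) {
    profiles <- run_stage("tune", function() {
      profile_neurons(proc$tensor, config$alpha_response,
                      config$alpha_anova, config$floor_negative)
    })
    report$profiles <- profiles
    agg <- stats::aggregate(cbind(responsive, ild_sensitive) ~ abl_db,
                            profiles$noise, mean)
    names(agg) <- c("abl_db", "pct_responsive", "pct_ild_sensitive")
    agg$pct_responsive <- 100 * agg$pct_responsive
    agg$pct_ild_sensitive <- 100 * agg$pct_ild_sensitive
    report$summary$responsiveness <- agg
  }

  if ("categorize" %in% stages && !is.null(proc)) {
    report$binaural <- run_stage("categorize", function() {
      abls <- sort(unique(experiment$trials$abl_db))
      do.call(rbind, lapply(abls, function(a)
        classify_binaural(proc$tensor, a, config$alpha_response)))
    })
    report$summary$categories <- category_table(report$binaural)
  }

  if ("decode" %in% stages && !is.null(proc) && !is.null(profiles)) {
    report$decoder <- run_stage("decode", function() {
      tr <- proc$tensor$trials
      bin <- which(tr$stim_class == "binaural")
      responsive <- profiles$noise_any$neuron[
        profiles$noise_any$responsive_any]
      if (length(responsive) < 2) return(NULL)
      chan <- lapply(responsive, function(j)
        assign_channel(proc$tensor$responses[j, bin], tr$ild_db[bin]))
      mono <- responsive[vapply(chan, `[[`, TRUE, "monotonic")]
      signs <- vapply(chan, `[[`, "", "sign")[
        vapply(chan, `[[`, TRUE, "monotonic")]
      if (length(mono) < 2 || length(unique(signs)) < 2) return(NULL)
      resp <- t(proc$tensor$responses[mono, bin, drop = FALSE])
      sizes <- config$decoder_sizes[config$decoder_sizes <= length(mono)]
      pm <- population_matrix(proc$tensor, neurons = responsive)
      list(n_monotonic = length(mono),
           channels = data.frame(neuron = mono, sign = signs),
           full = opponent_decode(resp, tr$ild_db[bin], signs),
           curve = if (length(sizes))
             decoder_curve(resp, tr$ild_db[bin], signs, sizes,
                           config$decoder_n_rep, config$seed),
           pca = run_pca(pm))
    })
  }

  if ("spatial" %in% stages && !is.null(proc) && !is.null(profiles)) {
    report$spatial <- run_stage("spatial", function() {
      pos <- experiment$recording$positions[proc$kept, , drop = FALSE]
      mid_abl <- stats::median(sort(unique(experiment$trials$abl_db)))
      noise_mid <- profiles$noise[profiles$noise$abl_db == mid_abl, ]
      wild <- ifelse(noise_mid$ild_sensitive, noise_mid$weighted_ild_db,
                     NA_real_)
      bf <- if (!is.null(profiles$tone))
        ifelse(profiles$tone$bf_valid, profiles$tone$bf_hz, NA_real_)
      else rep(NA_real_, nrow(pos))
      cat_mid <- if (!is.null(report$binaural))
        report$binaural$category[report$binaural$abl_db == mid_abl]
      else rep(NA_character_, nrow(pos))
      out <- list(
        ild = cluster_test_ild(wild, bf, pos, config$min_bf_hz,
                               config$cluster_threshold_um, config$n_boot,
                               config$alpha_cluster, config$seed),
        bf = cluster_test_bf(bf, pos, config$cluster_threshold_um,
                             config$n_boot, config$alpha_cluster,
                             config$seed),
        category = cluster_test_category(cat_mid, bf, pos,
                                         config$min_bf_hz,
                                         config$cluster_threshold_um,
                                         config$n_boot,
                                         config$alpha_cluster,
                                         config$seed))
      if (sum(is.finite(bf)) >= 3 &&
          stats::sd(log2(bf[is.finite(bf)])) > 0) {
        out$gradient <- tonotopic_gradient(pos, bf)
        out$bf_variation_oct <- bf_variation(bf)
      }
      out
    })
  }
  structure(report, class = "run_report")
}

#' Tabulate binaural category percentages
#'
#' Percentage of classified (non-unresponsive) neurons per category and
#' ABL, the per-experiment analogue of a binaural-class distribution plot.
#'
#' @param binaural data.frame from [classify_binaural()] (possibly several
#'   ABLs bound together).
#' @return data.frame: `abl_db`, `category`, `n`, `pct`.
#' @export
category_table <- function(binaural) {
  keep <- binaural$monaural_class != "unresponsive"
  b <- binaural[keep, ]
  if (!nrow(b)) return(data.frame(abl_db = numeric(), category = character(),
                                  n = integer(), pct = numeric()))
  tab <- as.data.frame(table(abl_db = b$abl_db, category = b$category))
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, ]
  tab$abl_db <- as.numeric(as.character(tab$abl_db))
  tot <- stats::ave(tab$n, tab$abl_db, FUN = sum)
  tab$pct <- 100 * tab$n / tot
  rownames(tab) <- NULL
  tab
}
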