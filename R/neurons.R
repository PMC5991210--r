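#' Ground-truth neuron populations for synthetic experiments
#'
#' Draws a population of model neurons with heterogeneous ILD tuning
#' (monotonic-contra, monotonic-ipsi, peaked, untuned), a binaural
#' interaction class that fixes the relation between monaural and diotic
#' responses, optional frequency tuning (best frequency with a
#' Gaussian-in-log-frequency response area), baseline and evoked firing
#' rates, and a weight on the field-common trial-to-trial latent. The
#' default mixture mirrors what small-rodent A1 populations look like:
#' mostly contralateral-preferring monotonic neurons, a minority of peaked
#' and ipsilateral-preferring ones, and a sizeable unresponsive fraction.
#'
#' @param n number of neurons.
#' @param seed integer seed (substream `neurons`).
#' @param p_tuning named probabilities over tuning types
#'   `monotonic-contra`, `monotonic-ipsi`, `peaked`, `untuned`.
#' @param p_class named probabilities over binaural classes.
#' @param p_has_bf probability that a neuron is frequency tuned.
#' @param p_unresponsive fraction of neurons with zero evoked gain.
#' @param baseline_hz_range,gain_hz_range uniform ranges for spontaneous
#'   rate and peak evoked rate (spikes/s).
#' @param noise_share_range uniform range of the field-common latent weight.
#' @return a `data.frame`, one row per neuron, with the ground-truth fields.
#' @export
synth_neurons <- function(n, seed = 1L,
                          p_tuning = c("monotonic-contra" = 0.45,
                                       "monotonic-ipsi" = 0.15,
                                       "peaked" = 0.25,
                                       "untuned" = 0.15),
                          p_class = c("EO/I" = 0.30, "OO/F" = 0.34,
                                      "EO/F" = 0.08, "EO/N" = 0.05,
                                      "OE/I" = 0.05, "OE/F" = 0.02,
                                      "OE/N" = 0.02, "EE/N" = 0.05,
                                      "EE/F" = 0.03, "EE/O" = 0.06),
                          p_has_bf = 0.7,
                          p_unresponsive = 0.15,
                          baseline_hz_range = c(0.5, 3),
                          gain_hz_range = c(30, 90),
                          noise_share_range = c(0.2, 0.8)) {
  with_substream(seed, "neurons", {
    tuning <- sample(names(p_tuning), n, TRUE, prob = p_tuning)
    cls <- sample(names(p_class), n, TRUE, prob = p_class)
    gain <- stats::runif(n, gain_hz_range[1], gain_hz_range[2])
    unresp <- stats::runif(n) < p_unresponsive
    cls[unresp] <- "unresponsive"
    gain[unresp] <- 0
    has_bf <- stats::runif(n) < p_has_bf
    data.frame(
      id = seq_len(n),
      tuning_type = tuning,
      ild_peak_db = ifelse(tuning == "peaked",
                           stats::runif(n, -30, 30), 0),
      ild_mid_db = stats::runif(n, -15, 15),
      ild_width_db = stats::runif(n, 8, 15),
      binaural_class = cls,
      baseline_hz = stats::runif(n, baseline_hz_range[1],
                                 baseline_hz_range[2]),
      gain_hz = gain,
      tone_gain_hz = ifelse(has_bf, stats::runif(n, 30, 90), 0),
      bf_hz = ifelse(has_bf, 2 ^ stats::runif(n, log2(4000), log2(45000)),
                     NA_real_),
      fra_width_oct = stats::runif(n, 0.5, 1.2),
      noise_share = stats::runif(n, noise_share_range[1],
                                 noise_share_range[2]),
      f0 = stats::runif(n, 80, 120),
      x_um = NA_real_, y_um = NA_real_, depth_um = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

# monaural weight split and target binaural interaction index per class.
# bii fixes diotic = bii * (contra + ipsi); for OO/F the monaural responses
# are zero and the diotic response is driven by the binaural tuning alone.
binaural_class_params <- function(cls) {
  switch(cls,
    "EO/F" = list(wc = 1, wi = 0, bii = 1.5),
    "EO/N" = list(wc = 1, wi = 0, bii = 1.0),
    "EO/I" = list(wc = 1, wi = 0, bii = 0.5),
    "OE/F" = list(wc = 0, wi = 1, bii = 1.5),
    "OE/N" = list(wc = 0, wi = 1, bii = 1.0),
    "OE/I" = list(wc = 0, wi = 1, bii = 0.5),
    "EE/F" = list(wc = 1, wi = 0.9, bii = 1.5),
    "EE/N" = list(wc = 1, wi = 0.9, bii = 1.0),
    # diotic = 0.474*(c+i) = 0.9*contra: below the facilitation band but
    # above 80% of the dominant ear -> binaural occlusion
    "EE/O" = list(wc = 1, wi = 0.9, bii = 0.9 / 1.9),
    "EE/I" = list(wc = 1, wi = 0.9, bii = 0.5 / 1.9),
    "OO/F" = list(wc = 0, wi = 0, bii = NA_real_),
    "unresponsive" = list(wc = 0, wi = 0, bii = NA_real_),
    stop("unknown binaural class: ", cls)
  )
}

# normalized ILD tuning in [0, 1]
ild_tuning_value <- function(neuron, ild) {
  switch(neuron$tuning_type,
    "monotonic-contra" = stats::plogis((neuron$ild_mid_db - ild) /
                                         neuron$ild_width_db),
    "monotonic-ipsi" = stats::plogis((ild - neuron$ild_mid_db) /
                                       neuron$ild_width_db),
    "peaked" = exp(-(ild - neuron$ild_peak_db) ^ 2 /
                     (2 * neuron$ild_width_db ^ 2)),
    "untuned" = rep(1, length(ild)),
    stop("unknown tuning type: ", neuron$tuning_type)
  )
}

# monotone ABL gain in (0, 1], indexed on the sorted ABL list
abl_gain_value <- function(abl, abl_levels) {
  idx <- match(abl, abl_levels)
  g <- seq(0.6, 1, length.out = max(length(abl_levels), 2L))
  g[idx]
}

#' Expected firing rate of a ground-truth neuron for one stimulus
#'
#' For binaural noise the evoked rate is `gain x tuning(ILD) x abl_gain`,
#' with the tuning curve normalized to unit maximum. Monaural rates follow
#' the neuron's planted binaural class: the diotic (0 dB ILD) evoked rate
#' equals `BII x (contra + ipsi)` for the class's target BII, so the class
#' is recoverable from the simulated responses. Tone rates are Gaussian in
#' log frequency around the neuron's best frequency with a monotone level
#' gain and mildly level-dependent bandwidth. Rates are clamped at zero.
#'
#' @param neuron one row of [synth_neurons()].
#' @param trials a [build_stimulus_schedule()] table (or subset of rows).
#' @param spec the [stimulus_spec()].
#' @return numeric vector, expected rate in spikes/s during each stimulus
#'   (baseline + evoked).
#' @export
expected_rate <- function(neuron, trials, spec) {
  neuron$baseline_hz + evoked_rate(neuron, trials, spec)
}

# evoked component only (spikes/s above baseline during the stimulus)
evoked_rate <- function(neuron, trials, spec) {
  cp <- binaural_class_params(neuron$binaural_class)
  out <- numeric(nrow(trials))
  ablg <- rep(1, nrow(trials))
  has_abl <- !is.na(trials$abl_db)
  ablg[has_abl] <- abl_gain_value(trials$abl_db[has_abl], spec$abl_db)

  bin <- trials$stim_class == "binaural"
  if (any(bin)) {
    tun <- ild_tuning_value(neuron, trials$ild_db[bin])
    tmax <- max(ild_tuning_value(neuron, spec$ild_db))
    out[bin] <- neuron$gain_hz * (tun / tmax) * ablg[bin]
  }
  mon_c <- trials$stim_class == "monaural_contra"
  mon_i <- trials$stim_class == "monaural_ipsi"
  if (any(mon_c | mon_i) && (cp$wc + cp$wi) > 0) {
    # diotic evoked at this ABL, from the binaural curve at ILD 0
    t0 <- ild_tuning_value(neuron, 0) /
      max(ild_tuning_value(neuron, spec$ild_db))
    d0 <- neuron$gain_hz * t0
    mon_total <- d0 / cp$bii
    out[mon_c] <- mon_total * cp$wc / (cp$wc + cp$wi) * ablg[mon_c]
    out[mon_i] <- mon_total * cp$wi / (cp$wc + cp$wi) * ablg[mon_i]
  }
  tone <- trials$stim_class == "tone"
  if (any(tone) && !is.na(neuron$bf_hz) && neuron$tone_gain_hz > 0) {
    lvl_idx <- match(trials$level_db[tone], spec$tone_level_db)
    lgain <- seq(0.4, 1, length.out = length(spec$tone_level_db))[lvl_idx]
    w <- neuron$fra_width_oct * (1 + 0.15 * (lvl_idx - 1))
    out[tone] <- neuron$tone_gain_hz *
      exp(-(log2(trials$freq_hz[tone] / neuron$bf_hz)) ^ 2 / (2 * w ^ 2)) *
      lgain
  }
  pmax(out, 0)
}

#' Ground-truth weighted ILD preference of a model neuron
#'
#' Centroid of the noise-free binaural evoked-rate curve at one ABL:
#' `sum(ILD_i * r_i) / sum(r_i)`.
#'
#' @param neuron one row of [synth_neurons()].
#' @param spec the [stimulus_spec()].
#' @param abl_db ABL at which to evaluate (default: middle tested ABL).
#' @return signed dB value, or NA for neurons with no evoked response.
#' @export
true_weighted_ild <- function(neuron, spec,
                              abl_db = stats::median(spec$abl_db)) {
  tr <- data.frame(stim_class = "binaural", ild_db = spec$ild_db,
                   abl_db = abl_db, freq_hz = NA_real_, level_db = NA_real_)
  r <- evoked_rate(neuron, tr, spec)
  if (sum(r) <= 0) return(NA_real_)
  sum(spec$ild_db * r) / sum(r)
}

#' Plant spatial structure into a neuron population
#'
#' Assigns uniform positions within a rectangular imaging field and,
#' optionally, a tonotopic gradient (log2 best frequency decreasing
#' linearly along a stated axis, plus jitter) and/or spatial clusters of
#' ILD preference (each neuron takes its nearest cluster's preferred ILD
#' plus a small within-cluster spread, realized as peaked tuning).
#'
#' @param neurons a [synth_neurons()] table.
#' @param field_um field extent (x = rostro-caudal, y = dorso-ventral), um.
#' @param depth_um imaging depth range below the pia, um.
#' @param gradient NULL, or `list(angle_deg, oct_per_um, bf_at_origin_hz,
#'   jitter_oct)`: BF decreases along the `angle_deg` axis.
#' @param clusters NULL, or `list(centers, values_db, spread_db)` where
#'   `centers` is a k x 2 matrix of um coordinates and `values_db` gives
#'   each cluster's preferred ILD.
#' @param seed integer seed (substream `layout`).
#' @return the neuron table with positions (and possibly bf/tuning) filled.
#' @export
plant_spatial_structure <- function(neurons, field_um = c(250, 250),
                                    depth_um = c(200, 350),
                                    gradient = NULL, clusters = NULL,
                                    seed = 1L) {
  if (!is.null(clusters)) {
    if (any(clusters$centers[, 1] < 0 | clusters$centers[, 1] > field_um[1]) ||
        any(clusters$centers[, 2] < 0 | clusters$centers[, 2] > field_um[2]))
      stop("cluster centers must lie within the field extent")
    if ((clusters$radius_um %||% 0) > max(field_um))
      stop("cluster radius exceeds the field extent")
  }
  n <- nrow(neurons)
  with_substream(seed, "layout", {
    neurons$x_um <- stats::runif(n, 0, field_um[1])
    neurons$y_um <- stats::runif(n, 0, field_um[2])
    neurons$depth_um <- stats::runif(n, depth_um[1], depth_um[2])
    if (!is.null(gradient)) {
      th <- gradient$angle_deg * pi / 180
      proj <- neurons$x_um * cos(th) + neurons$y_um * sin(th)
      jit <- gradient$jitter_oct %||% 0
      neurons$bf_hz <- 2 ^ (log2(gradient$bf_at_origin_hz) -
                              gradient$oct_per_um * proj +
                              stats::rnorm(n, 0, jit))
      neurons$tone_gain_hz <- pmax(neurons$tone_gain_hz, 30)
    }
    if (!is.null(clusters)) {
      d2 <- outer(neurons$x_um, clusters$centers[, 1], `-`) ^ 2 +
        outer(neurons$y_um, clusters$centers[, 2], `-`) ^ 2
      nearest <- max.col(-d2)
      neurons$tuning_type <- "peaked"
      neurons$ild_peak_db <- clusters$values_db[nearest] +
        stats::rnorm(n, 0, clusters$spread_db)
      neurons$ild_width_db <- pmax(neurons$ild_width_db, 8)
    }
    neurons
  })
}
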