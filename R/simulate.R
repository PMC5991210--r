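#' Default fluorescence-simulation parameters
#'
#' GCaMP6m-like transient dynamics (50 ms rise, 600 ms decay), a per-spike
#' fluorescence increment of 0.18 dF/F0, frame-wise white measurement noise,
#' a slow sinusoidal drift removed downstream by the high-pass filter, a
#' field-common per-trial latent that multiplies each neuron's evoked
#' response (weighted by its `noise_share`) to induce trial-level noise
#' correlations, and neuropil contamination mixed in at ratio `r_np`.
#'
#' @param kernel_rise_s,kernel_decay_s calcium transient kernel times (s).
#' @param dff_per_spike fluorescence increment per spike (dF/F0 units).
#' @param white_noise_sd frame-wise measurement noise SD (dF/F0 units).
#' @param drift_amp,drift_period_s slow multiplicative drift amplitude
#'   (fraction of F0) and period (s).
#' @param latent_sd SD of the field-common per-trial latent.
#' @param np_bg_sd SD of the slow AR(1) neuropil background.
#' @param r_np neuropil contamination ratio mixed into measured traces.
#' @param deterministic if TRUE, per-frame spike counts are replaced by
#'   their Poisson expectation; the other noise sources keep their stated
#'   levels. The noise-free limit is `deterministic = TRUE` with
#'   `white_noise_sd`, `drift_amp`, `latent_sd` and `np_bg_sd` all zero.
#' @return a named list of parameters.
#' @export
sim_params <- function(kernel_rise_s = 0.05, kernel_decay_s = 0.6,
                       dff_per_spike = 0.18, white_noise_sd = 0.03,
                       drift_amp = 0.05, drift_period_s = 120,
                       latent_sd = 0.25, np_bg_sd = 0.01, r_np = 0.6,
                       deterministic = FALSE) {
  if (kernel_rise_s <= 0 || kernel_decay_s <= 0)
    stop("kernel times must be positive")
  if (kernel_rise_s >= kernel_decay_s)
    stop("kernel rise time must be shorter than the decay time")
  as.list(environment())
}

#' Noise-free simulation parameters
#'
#' Convenience wrapper for the deterministic, noiseless limit: expected
#' spike counts, no measurement noise, no drift, no shared latent. Useful
#' for exact-recovery checks.
#'
#' @param ... overrides passed to [sim_params()].
#' @return a [sim_params()] list.
#' @export
sim_params_noise_free <- function(...) {
  base <- list(white_noise_sd = 0, drift_amp = 0, latent_sd = 0,
               np_bg_sd = 0, deterministic = TRUE)
  do.call(sim_params, utils::modifyList(base, list(...)))
}

# double-exponential kernel realized as the difference of two recursive
# exponential filters, normalized to unit peak
calcium_convolve <- function(spikes, rise_s, decay_s, frame_rate) {
  ad <- exp(-1 / (decay_s * frame_rate))
  ar <- exp(-1 / (rise_s * frame_rate))
  tpk <- (rise_s * decay_s) / (decay_s - rise_s) * log(decay_s / rise_s)
  peak <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
  ed <- stats::filter(spikes, ad, method = "recursive")
  er <- stats::filter(spikes, ar, method = "recursive")
  as.numeric(ed - er) / peak
}

#' Simulate a complete two-photon imaging experiment
#'
#' Generates the trial schedule, draws (or takes) a ground-truth neuron
#' population with spatial layout, and synthesizes raw fluorescence traces:
#' inhomogeneous Poisson spikes at each neuron's expected rate, convolution
#' with a double-exponential calcium kernel, baseline fluorescence F0,
#' neuropil contamination, slow drift, white noise, and a field-common
#' per-trial latent shared across neurons. Regenerating with the same seed
#' reproduces the experiment bit-identically.
#'
#' @param n_neurons number of neurons (ignored when `neurons` is supplied).
#' @param spec a [stimulus_spec()].
#' @param neurons optional pre-built [synth_neurons()] table (with or
#'   without positions; positions are planted if absent).
#' @param params a [sim_params()] list.
#' @param layout arguments forwarded to [plant_spatial_structure()] when
#'   positions are missing.
#' @param seed root integer seed; all substreams derive from it.
#' @return an object of class `ild_experiment`: `spec`, `trials`,
#'   `neurons` (ground truth), and `recording` (`traces` and `neuropil`
#'   matrices of frames x neurons, `frame_rate_hz`, `positions`).
#' @export
simulate_experiment <- function(n_neurons = 50, spec = stimulus_spec(),
                                neurons = NULL, params = sim_params(),
                                layout = list(), seed = 1L) {
  if (is.null(neurons)) neurons <- synth_neurons(n_neurons, seed = seed)
  if (anyNA(neurons$x_um))
    neurons <- do.call(plant_spatial_structure,
                       c(list(neurons = neurons, seed = seed), layout))
  trials <- build_stimulus_schedule(spec, seed = seed)
  recording <- simulate_fluorescence(neurons, trials, spec, params, seed)
  structure(list(spec = spec, trials = trials, neurons = neurons,
                 recording = recording, seed = seed),
            class = "ild_experiment")
}

#' Synthesize raw fluorescence traces for a neuron population
#'
#' @param neurons ground-truth neuron table (see [synth_neurons()]).
#' @param trials a [build_stimulus_schedule()] table.
#' @param spec the [stimulus_spec()].
#' @param params a [sim_params()] list.
#' @param seed root integer seed.
#' @return a list: `traces` and `neuropil` (frames x neurons matrices, raw
#'   fluorescence units), `frame_rate_hz`, `positions` (data.frame with
#'   `x_um`, `y_um`, `depth_um`).
#' @export
simulate_fluorescence <- function(neurons, trials, spec,
                                  params = sim_params(), seed = 1L) {
  fr <- spec$frame_rate_hz
  fpt <- frames_per_trial(spec)
  n_frames <- max(trials$onset_frame) + fpt
  n_neu <- nrow(neurons)
  stim_frames <- max(1L, as.integer(ceiling(fr * spec$stim_dur_s)))

  latent <- if (params$latent_sd > 0) {
    with_substream(seed, "latent",
                   stats::rnorm(nrow(trials), 0, params$latent_sd))
  } else rep(0, nrow(trials))

  dff_true <- matrix(0, n_frames, n_neu)
  onsets <- trials$onset_frame
  stim_idx <- as.vector(outer(seq_len(stim_frames) - 1L, onsets, `+`))

  with_substream(seed, "spikes", {
    for (j in seq_len(n_neu)) {
      neuron <- neurons[j, ]
      ev <- evoked_rate(neuron, trials, spec)
      ev_mod <- ev * pmax(0, 1 + neuron$noise_share * latent)
      rate <- rep(neuron$baseline_hz, n_frames)
      rate[stim_idx] <- rate[stim_idx] + rep(ev_mod, each = stim_frames)
      lam <- rate / fr
      spk <- if (params$deterministic) lam else stats::rpois(n_frames, lam)
      dff_true[, j] <- params$dff_per_spike *
        calcium_convolve(spk, params$kernel_rise_s, params$kernel_decay_s, fr)
    }
  })

  tvec <- seq_len(n_frames) / fr
  with_substream(seed, "noise", {
    # field-common neuropil signal: shared fraction of the population
    # signal plus a slow AR(1) background
    bg <- if (params$np_bg_sd > 0)
      as.numeric(stats::filter(stats::rnorm(n_frames, 0, params$np_bg_sd),
                               0.97, method = "recursive"))
    else rep(0, n_frames)
    np_common <- 0.7 * rowMeans(dff_true) + bg
    drift_phase <- stats::runif(n_neu, 0, 2 * pi)
    traces <- matrix(0, n_frames, n_neu)
    neuropil <- matrix(0, n_frames, n_neu)
    for (j in seq_len(n_neu)) {
      drift <- if (params$drift_amp > 0)
        params$drift_amp * sin(2 * pi * tvec / params$drift_period_s +
                                 drift_phase[j])
      else 0
      eps <- if (params$white_noise_sd > 0)
        stats::rnorm(n_frames, 0, params$white_noise_sd) else 0
      traces[, j] <- neurons$f0[j] *
        (1 + dff_true[, j] + params$r_np * np_common + drift + eps)
      np_eps <- if (params$white_noise_sd > 0)
        stats::rnorm(n_frames, 0, params$white_noise_sd / 2) else 0
      neuropil[, j] <- 0.8 * neurons$f0[j] * (1 + np_common + np_eps)
    }
    list(traces = traces, neuropil = neuropil, frame_rate_hz = fr,
         positions = neurons[c("x_um", "y_um", "depth_um")])
  })
}
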