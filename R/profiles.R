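#' Per-neuron tuning profiles from a response tensor
#'
#' Runs the per-neuron statistical battery: per-ABL noise responsiveness
#' (paired t-tests across ILDs), ILD sensitivity (one-way ANOVA) with peak
#' ILD, weighted ILD, and steepest slope for sensitive neurons; tone
#' responsiveness, frequency sensitivity (two-way ANOVA) and best
#' frequency with the 3-SD validity rule for tone-responsive neurons.
#'
#' @param tensor a `response_tensor` from [extract_responses()].
#' @param alpha_response significance level of the response t-tests (0.01).
#' @param alpha_anova significance level of the ANOVAs (0.05).
#' @param floor_negative floor negative means in the centroid, see
#'   [ild_curve_summary()].
#' @return list with `noise` (data.frame, one row per neuron x ABL),
#'   `noise_any` (per neuron: responsive/sensitive at any ABL), `tone`
#'   (one row per neuron), and `curves` (list of per-ABL matrices of
#'   trial-averaged ILD responses, neurons x ILDs).
#' @export
profile_neurons <- function(tensor, alpha_response = 0.01,
                            alpha_anova = 0.05, floor_negative = TRUE) {
  tr <- tensor$trials
  n <- nrow(tensor$responses)
  abls <- sort(unique(tr$abl_db[tr$stim_class == "binaural"]))
  ilds <- sort(unique(tr$ild_db[tr$stim_class == "binaural"]))

  noise_rows <- list()
  curves <- list()
  for (abl in abls) {
    idx <- which(tr$stim_class == "binaural" & tr$abl_db == abl)
    ild <- tr$ild_db[idx]
    curve_mat <- matrix(NA_real_, n, length(ilds),
                        dimnames = list(NULL, ilds))
    for (j in seq_len(n)) {
      resp <- tensor$responses[j, idx]
      rt <- test_responsive(tensor$pre_peaks[j, idx],
                            tensor$post_peaks[j, idx], ild, alpha_response)
      st <- test_ild_sensitivity(resp, ild, alpha_anova)
      means <- vapply(ilds, function(v) mean(resp[ild == v]), numeric(1))
      curve_mat[j, ] <- means
      cs <- ild_curve_summary(means, ilds, floor_negative)
      noise_rows[[length(noise_rows) + 1L]] <- data.frame(
        neuron = j, abl_db = abl,
        responsive = rt$responsive, p_min = min(rt$p),
        ild_sensitive = st$sensitive, p_anova = st$p,
        peak_ild_db = cs$peak_ild_db,
        weighted_ild_db = cs$weighted_ild_db,
        steepest_midpoint_db = cs$steepest_midpoint_db,
        max_slope = max(abs(cs$slopes)))
    }
    curves[[as.character(abl)]] <- curve_mat
  }
  noise <- do.call(rbind, noise_rows)
  noise_any <- do.call(rbind, lapply(seq_len(n), function(j) {
    rows <- noise[noise$neuron == j, ]
    data.frame(neuron = j,
               responsive_any = any(rows$responsive),
               ild_sensitive_any = any(rows$ild_sensitive))
  }))

  tone <- NULL
  tidx <- which(tr$stim_class == "tone")
  if (length(tidx)) {
    freq <- tr$freq_hz[tidx]
    lvl <- tr$level_db[tidx]
    tone <- do.call(rbind, lapply(seq_len(n), function(j) {
      resp <- tensor$responses[j, tidx]
      rt <- test_responsive(tensor$pre_peaks[j, tidx],
                            tensor$post_peaks[j, tidx], freq,
                            alpha_response)
      fs <- test_frequency_sensitivity(resp, freq, lvl, alpha_anova)
      bf <- NA_real_; bf_valid <- FALSE
      if (rt$responsive && fs$freq_sensitive) {
        fra <- build_fra(resp, freq, lvl)
        b <- best_frequency(fra$fra, fra$freq_hz,
                            tensor$pre_peaks[j, tidx])
        bf <- b$bf_hz; bf_valid <- b$valid
      }
      data.frame(neuron = j, tone_responsive = rt$responsive,
                 freq_sensitive = fs$freq_sensitive,
                 p_freq = fs$p_freq, p_level = fs$p_level,
                 bf_hz = bf, bf_valid = bf_valid)
    }))
  }
  list(noise = noise, noise_any = noise_any, tone = tone, curves = curves,
       ild_db = ilds, abl_db = abls)
}
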