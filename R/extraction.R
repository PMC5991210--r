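#' High-pass filter a fluorescence trace
#'
#' Removes slow fluctuations by subtracting a zero-phase moving-average
#' low-pass (window = `frame_rate / cutoff` frames, reflective padding) and
#' restoring the trace mean, so transients keep their timing and the
#' baseline level survives for F0 estimation. With the default 0.02 Hz
#' cutoff at 30 Hz sampling, a 1 Hz sinusoid passes with gain > 0.99 while
#' a 0.005 Hz sinusoid is attenuated below 0.5.
#'
#' @param trace numeric vector, raw fluorescence.
#' @param cutoff_hz high-pass cutoff frequency.
#' @param frame_rate_hz sampling rate.
#' @return filtered trace, same length.
#' @export
highpass <- function(trace, cutoff_hz = 0.02, frame_rate_hz = 30) {
  if (cutoff_hz >= frame_rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency")
  w <- max(3L, as.integer(round(frame_rate_hz / cutoff_hz)))
  if (length(trace) < 3L * frame_rate_hz / cutoff_hz) {
    warning("trace shorter than 3 filter time constants; not filtered")
    return(trace)
  }
  trace - running_mean(trace, w) + mean(trace)
}

#' Baseline fluorescence F0
#'
#' The baseline is the median of the samples whose empirical rank
#' percentile lies between 10 and 70 (ranks `floor(0.1 n) + 1` through
#' `floor(0.7 n)` of the sorted trace). The top 30% of values is excluded
#' so calcium transients do not inflate the baseline, and the bottom 10%
#' guards against downward artifacts.
#'
#' @param trace numeric vector of fluorescence values (>= 10 frames).
#' @return scalar baseline.
#' @export
baseline_f0 <- function(trace) {
  n <- length(trace)
  if (n < 10) stop("baseline_f0 needs at least 10 frames")
  s <- sort(trace)
  # rank bounds: smallest i with i/n > 0.10, largest with i/n <= 0.70
  # (guarded against floating-point edge cases at exact multiples)
  lo <- floor(n / 10 + 1e-9) + 1L
  hi <- floor(7 * n / 10 + 1e-9)
  stats::median(s[lo:hi])
}

#' Compute dF/F0
#'
#' @param trace numeric fluorescence trace.
#' @param f0 positive baseline, typically from [baseline_f0()].
#' @return `(trace - f0) / f0`, framewise.
#' @export
compute_dff <- function(trace, f0) {
  if (!is.finite(f0) || f0 <= 0)
    stop("f0 must be positive (corrupt baseline?)")
  (trace - f0) / f0
}

#' Subtract neuropil contamination
#'
#' Applied on dF/F0 traces: `corrected = trace - r * neuropil_trace`.
#'
#' @param trace,neuropil_trace dF/F0 traces of equal length.
#' @param r contamination ratio in \[0, 1).
#' @return corrected trace.
#' @export
neuropil_correct <- function(trace, neuropil_trace, r = 0.6) {
  if (r < 0 || r >= 1) stop("contamination ratio must be in [0, 1)")
  if (length(trace) != length(neuropil_trace))
    stop("trace and neuropil trace differ in length")
  trace - r * neuropil_trace
}

#' Per-trial peak responses
#'
#' For each trial, the pre-stimulus peak is the maximum dF/F0 over the
#' `window_frames` frames immediately before onset (`onset - 14` to
#' `onset - 1` by default, ~500 ms at 30 Hz) and the stimulation peak is
#' the maximum over the `window_frames` frames from onset (`onset` to
#' `onset + 13`). The response is their difference, which controls for
#' local fluctuations in the fluorescence signal. With
#' `statistic = "sum"`, window sums replace window maxima.
#'
#' @param dff matrix of dF/F0 traces, frames x neurons (a vector is
#'   treated as one neuron).
#' @param trials a [build_stimulus_schedule()] table.
#' @param window_frames window length in frames.
#' @param statistic `"max"` (default) or `"sum"`.
#' @return an object of class `response_tensor`: matrices `responses`,
#'   `pre_peaks`, `post_peaks` (neurons x trials), the `trials` table
#'   restricted to usable trials, and `dropped_trials`.
#' @export
extract_responses <- function(dff, trials, window_frames = 14L,
                              statistic = c("max", "sum")) {
  statistic <- match.arg(statistic)
  if (is.null(dim(dff))) dff <- matrix(dff, ncol = 1)
  n_frames <- nrow(dff)
  ok <- trials$onset_frame - window_frames >= 1 &
    trials$onset_frame + window_frames - 1 <= n_frames
  dropped <- trials$trial[!ok]
  if (length(dropped))
    message(length(dropped), " trial(s) dropped: incomplete response window")
  tr <- trials[ok, , drop = FALSE]
  stat_fun <- if (statistic == "max") max else sum
  n_tr <- nrow(tr)
  n_neu <- ncol(dff)
  pre <- post <- matrix(NA_real_, n_neu, n_tr)
  for (t in seq_len(n_tr)) {
    o <- tr$onset_frame[t]
    pre[, t] <- apply(dff[(o - window_frames):(o - 1), , drop = FALSE],
                      2, stat_fun)
    post[, t] <- apply(dff[o:(o + window_frames - 1), , drop = FALSE],
                       2, stat_fun)
  }
  structure(list(responses = post - pre, pre_peaks = pre, post_peaks = post,
                 trials = tr, dropped_trials = dropped,
                 window_frames = window_frames, statistic = statistic),
            class = "response_tensor")
}

#' Full trace-to-response preprocessing
#'
#' Runs the standard preprocessing chain on a recording: high-pass filter
#' raw and neuropil traces, compute F0 and dF/F0 for each, subtract
#' `r_np` x neuropil dF/F0, and extract windowed per-trial responses.
#' Neurons whose traces contain non-finite values are excluded and logged.
#'
#' @param recording list with `traces`, `neuropil` (frames x neurons) and
#'   `frame_rate_hz` (as produced by [simulate_fluorescence()]).
#' @param trials a [build_stimulus_schedule()] table.
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param r_np neuropil contamination ratio.
#' @param window_frames response window (frames).
#' @param statistic response statistic, see [extract_responses()].
#' @return a list: `tensor` (a `response_tensor`), `dff` (frames x neurons
#'   corrected dF/F0), `f0` per neuron, `excluded` (neuron indices with a
#'   reason), `kept` (analyzed neuron indices).
#' @export
process_recording <- function(recording, trials, cutoff_hz = 0.02,
                              r_np = 0.6, window_frames = 14L,
                              statistic = "max") {
  traces <- recording$traces
  npil <- recording$neuropil
  fr <- recording$frame_rate_hz
  if (!all(dim(traces) == dim(npil)))
    stop("traces and neuropil matrices differ in shape")
  bad <- which(!apply(is.finite(traces), 2, all) |
                 !apply(is.finite(npil), 2, all))
  kept <- setdiff(seq_len(ncol(traces)), bad)
  if (!length(kept)) stop("no analyzable neurons in recording")
  dff <- matrix(NA_real_, nrow(traces), ncol(traces))
  f0 <- rep(NA_real_, ncol(traces))
  for (j in kept) {
    hp <- highpass(traces[, j], cutoff_hz, fr)
    f0[j] <- baseline_f0(hp)
    cell <- compute_dff(hp, f0[j])
    hp_np <- highpass(npil[, j], cutoff_hz, fr)
    np <- compute_dff(hp_np, baseline_f0(hp_np))
    dff[, j] <- neuropil_correct(cell, np, r_np)
  }
  tensor <- extract_responses(dff[, kept, drop = FALSE], trials,
                              window_frames, statistic)
  excluded <- if (length(bad))
    data.frame(neuron = bad, reason = "non-finite trace values")
  else data.frame(neuron = integer(), reason = character())
  list(tensor = tensor, dff = dff, f0 = f0, excluded = excluded, kept = kept)
}
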