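#' Stimulus specification for a binaural imaging experiment
#'
#' Defines the stimulus set of one imaging session: broadband noise bursts at
#' a symmetric set of interaural level differences (ILDs) and several average
#' binaural levels (ABLs), the same noise presented monaurally to each ear,
#' and diotic pure tones on a log-spaced frequency grid at several levels.
#' Defaults are 7 ILDs from -30 to +30 dB in 10 dB steps (negative = louder
#' in the contralateral ear), ABLs of 40/60/80 dB SPL, 12 noise repetitions,
#' 18 tone frequencies log-spaced 1.9-50 kHz (0.277-octave steps) at
#' 40/60/80/100 dB SPL with 10 repetitions, 100 ms stimuli presented at
#' 0.65 Hz under a ~30 Hz frame clock.
#'
#' @param ild_db signed ILD values in dB; must be sorted and symmetric about 0.
#' @param abl_db average binaural levels in dB SPL.
#' @param n_noise_reps repetitions of each noise stimulus.
#' @param monaural_sides which single-ear noise stimuli to include.
#' @param tone_freq_hz tone frequencies in Hz; default 18 log-spaced values
#'   spanning `tone_freq_range_hz`.
#' @param n_tone_freqs,tone_freq_range_hz grid size and range used when
#'   `tone_freq_hz` is NULL.
#' @param tone_level_db tone levels in dB SPL.
#' @param n_tone_reps repetitions of each tone stimulus.
#' @param stim_dur_s stimulus duration in seconds.
#' @param presentation_rate_hz stimulus presentation rate in Hz.
#' @param frame_rate_hz imaging frame rate in Hz.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(ild_db = seq(-30, 30, by = 10),
                          abl_db = c(40, 60, 80),
                          n_noise_reps = 12,
                          monaural_sides = c("contra", "ipsi"),
                          tone_freq_hz = NULL,
                          n_tone_freqs = 18,
                          tone_freq_range_hz = c(1900, 50000),
                          tone_level_db = c(40, 60, 80, 100),
                          n_tone_reps = 10,
                          stim_dur_s = 0.1,
                          presentation_rate_hz = 0.65,
                          frame_rate_hz = 30) {
  ild_db <- sort(ild_db)
  if (any(sort(-ild_db) != ild_db))
    stop("ild_db must be symmetric about 0")
  if (n_noise_reps < 1 || n_tone_reps < 1)
    stop("repetition counts must be positive")
  if (1 / presentation_rate_hz < stim_dur_s)
    stop("presentation period must be at least the stimulus duration")
  if (frame_rate_hz * stim_dur_s < 1)
    stop("stimulus must span at least one imaging frame")
  if (is.null(tone_freq_hz))
    tone_freq_hz <- 2 ^ seq(log2(tone_freq_range_hz[1]),
                            log2(tone_freq_range_hz[2]),
                            length.out = n_tone_freqs)
  structure(list(
    ild_db = ild_db, abl_db = sort(abl_db),
    n_noise_reps = as.integer(n_noise_reps),
    monaural_sides = monaural_sides,
    tone_freq_hz = tone_freq_hz,
    tone_level_db = sort(tone_level_db),
    n_tone_reps = as.integer(n_tone_reps),
    stim_dur_s = stim_dur_s,
    presentation_rate_hz = presentation_rate_hz,
    frame_rate_hz = frame_rate_hz
  ), class = "stimulus_spec")
}

#' Frames per trial under a spec's presentation clock
#' @param spec a [stimulus_spec()].
#' @return integer number of imaging frames between stimulus onsets.
#' @export
frames_per_trial <- function(spec) {
  as.integer(round(spec$frame_rate_hz / spec$presentation_rate_hz))
}

# frames into each trial at which the stimulus comes on; leaves >= 14
# pre-stimulus frames inside the trial for the pre-response window
onset_offset_frames <- function(spec) 16L

#' Build a pseudorandom trial schedule
#'
#' Every (stimulus, repetition) combination appears exactly once. Noise
#' stimuli (binaural ILDs and monaural presentations, crossed with ABL) and
#' tones occupy separate contiguous blocks; the order within each block is a
#' seeded permutation. Onset frames are spaced by
#' `round(frame_rate / presentation_rate)` frames.
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed for the within-block permutations.
#' @return a `data.frame` of class `trial_table` with columns `trial`,
#'   `block`, `stim_class` (binaural / monaural_contra / monaural_ipsi /
#'   tone), `ild_db`, `abl_db`, `freq_hz`, `level_db`, `rep`, `onset_frame`.
#' @export
build_stimulus_schedule <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"))
  noise <- expand.grid(ild_db = spec$ild_db, abl_db = spec$abl_db,
                       rep = seq_len(spec$n_noise_reps),
                       KEEP.OUT.ATTRS = FALSE)
  noise$stim_class <- "binaural"
  if (length(spec$monaural_sides)) {
    mon <- expand.grid(side = spec$monaural_sides, abl_db = spec$abl_db,
                       rep = seq_len(spec$n_noise_reps),
                       KEEP.OUT.ATTRS = FALSE)
    mon_df <- data.frame(ild_db = NA_real_, abl_db = mon$abl_db,
                         rep = mon$rep,
                         stim_class = paste0("monaural_", mon$side))
    noise <- rbind(noise[c("ild_db", "abl_db", "rep", "stim_class")], mon_df)
  }
  noise$freq_hz <- NA_real_
  noise$level_db <- NA_real_
  noise$block <- "noise"

  tones <- expand.grid(freq_hz = spec$tone_freq_hz,
                       level_db = spec$tone_level_db,
                       rep = seq_len(spec$n_tone_reps),
                       KEEP.OUT.ATTRS = FALSE)
  tones <- data.frame(ild_db = NA_real_, abl_db = NA_real_, rep = tones$rep,
                      stim_class = "tone", freq_hz = tones$freq_hz,
                      level_db = tones$level_db, block = "tone")

  tab <- with_substream(seed, "schedule", {
    rbind(noise[sample.int(nrow(noise)), ], tones[sample.int(nrow(tones)), ])
  })
  fpt <- frames_per_trial(spec)
  tab$trial <- seq_len(nrow(tab))
  tab$onset_frame <- (tab$trial - 1L) * fpt + onset_offset_frames(spec)
  rownames(tab) <- NULL
  cols <- c("trial", "block", "stim_class", "ild_db", "abl_db",
            "freq_hz", "level_db", "rep", "onset_frame")
  structure(tab[cols], class = c("trial_table", "data.frame"))
}
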