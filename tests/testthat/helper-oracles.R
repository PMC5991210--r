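# Independent brute-force oracles used to cross-check the implementation.
# They deliberately share no code with the package: explicit loops, direct
# formula transcription.

oracle_f0 <- function(x) {
  n <- length(x)
  s <- sort(x)
  keep <- c()
  for (i in seq_len(n)) {
    # exact integer comparison of the rank percentile against 10% and 70%
    if (10 * i > n && 10 * i <= 7 * n) keep <- c(keep, s[i])
  }
  median(keep)
}

oracle_dff <- function(x, f0) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- (x[i] - f0) / f0
  out
}

oracle_neuropil <- function(x, np, r) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- x[i] - r * np[i]
  out
}

# explicit window scan over one trace and one onset
oracle_response <- function(trace, onset, w = 14L) {
  pre <- -Inf
  for (i in (onset - w):(onset - 1)) pre <- max(pre, trace[i])
  post <- -Inf
  for (i in onset:(onset + w - 1)) post <- max(post, trace[i])
  post - pre
}

oracle_centroid <- function(means, ilds, floor_negative = TRUE) {
  num <- 0; den <- 0
  for (i in seq_along(ilds)) {
    r <- means[i]
    if (floor_negative && r < 0) r <- 0
    num <- num + ilds[i] * r
    den <- den + r
  }
  if (den <= 0) NA_real_ else num / den
}

oracle_slopes <- function(means) {
  out <- numeric(length(means) - 1)
  for (i in seq_len(length(means) - 1)) out[i] <- means[i + 1] - means[i]
  out
}

oracle_bii <- function(d, cc, ii) {
  d <- max(d, 0); cc <- max(cc, 0); ii <- max(ii, 0)
  if (cc + ii <= 0) NA_real_ else d / (cc + ii)
}

# direct transcription of the categorization rules
oracle_category <- function(sig_c, sig_i, sig_d, rd, rc, ri) {
  if (sig_c && sig_i) cls <- "EE"
  else if (sig_c) cls <- "EO"
  else if (sig_i) cls <- "OE"
  else if (sig_d) return("OO/F")
  else return("unresponsive")
  bii <- oracle_bii(rd, rc, ri)
  if (!is.finite(bii)) return(paste0(cls, "/undefined"))
  if (cls != "EE") {
    if (bii > 1.2) return(paste0(cls, "/F"))
    if (bii < 0.8) return(paste0(cls, "/I"))
    return(paste0(cls, "/N"))
  }
  if (bii > 1.2) return("EE/F")
  if (bii >= 0.8) return("EE/N")
  if (max(rd, 0) > 0.8 * max(max(rc, 0), max(ri, 0))) "EE/O" else "EE/I"
}

# small deterministic experiment used by several module tests
small_spec <- function(...) {
  stimulus_spec(abl_db = c(60, 80), n_noise_reps = 4, n_tone_freqs = 4,
                tone_level_db = c(60, 80), n_tone_reps = 3, ...)
}

quiet_process <- function(...) suppressWarnings(process_recording(...))
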