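#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a root seed for a named substream.
# All randomness in the package flows from one root seed through these
# substreams (schedule, neurons, layout, spikes, noise, latent, boot).
substream_seed <- function(seed, stream) {
  offsets <- c(schedule = 1L, neurons = 2L, layout = 3L, spikes = 4L,
               noise = 5L, latent = 6L, boot = 7L, decode = 8L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 48271 + off * 7919) %% 2147483647)
}

with_substream <- function(seed, stream, code) {
  withr::with_seed(substream_seed(seed, stream), code)
}

# Centred running mean by cumulative sums, edges handled by reflective
# padding so the output has no phase shift and full length.
running_mean <- function(x, w) {
  n <- length(x)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  if (h == 0L) return(x)
  # reflect (without repeating the edge sample)
  left <- x[pmin(n, seq(h + 1L, 2L))]
  right <- x[pmax(1L, seq(n - 1L, n - h))]
  xp <- c(left, x, right)
  cs <- cumsum(xp)
  (cs[seq(w, length(xp))] - c(0, cs[seq_len(length(xp) - w)])) / w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
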