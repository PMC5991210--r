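#' Population response matrix for PCA
#'
#' Rows are neurons, columns the `n_ILD x n_ABL` binaural noise stimuli;
#' entries are trial-averaged responses, each row normalized by the
#' neuron's maximum average response across all stimuli so high-gain
#' neurons do not dominate the population variance. Rows with a
#' non-positive maximum are excluded and logged.
#'
#' @param tensor a `response_tensor` from [extract_responses()].
#' @param neurons optional neuron indices to include (e.g. the
#'   noise-responsive subset); default all.
#' @return list with `matrix` (neurons x stimuli, rownames = neuron index,
#'   colnames = "ILD/ABL"), `ild_db`, `abl_db`, and `excluded` (neuron
#'   indices dropped for non-positive maxima).
#' @export
population_matrix <- function(tensor, neurons = NULL) {
  tr <- tensor$trials
  bin <- which(tr$stim_class == "binaural")
  ilds <- sort(unique(tr$ild_db[bin]))
  abls <- sort(unique(tr$abl_db[bin]))
  if (is.null(neurons)) neurons <- seq_len(nrow(tensor$responses))
  stim <- expand.grid(ild_db = ilds, abl_db = abls, KEEP.OUT.ATTRS = FALSE)
  m <- vapply(seq_len(nrow(stim)), function(s) {
    idx <- bin[tr$ild_db[bin] == stim$ild_db[s] &
                 tr$abl_db[bin] == stim$abl_db[s]]
    rowMeans(tensor$responses[neurons, idx, drop = FALSE])
  }, numeric(length(neurons)))
  if (length(neurons) == 1L) m <- matrix(m, nrow = 1)
  mx <- apply(m, 1, max)
  keep <- mx > 0
  out <- m[keep, , drop = FALSE] / mx[keep]
  rownames(out) <- neurons[keep]
  colnames(out) <- paste0(stim$ild_db, "/", stim$abl_db)
  list(matrix = out, ild_db = ilds, abl_db = abls,
       excluded = neurons[!keep])
}

#' PCA of the population ILD x ABL response matrix
#'
#' Centred (unscaled) principal components analysis of the normalized
#' population matrix. Components are ordered by variance explained and the
#' eigenvector coefficients are additionally reshaped to ILD x ABL for
#' inspection of the stimulus patterns each component captures.
#'
#' @param pm a [population_matrix()] result (or a plain numeric matrix).
#' @return list with `var_explained` (fractions summing to 1),
#'   `coefficients` (stimuli x components), `coefficients_by_abl` (array
#'   ILD x ABL x components, when the stimulus grid is known), `scores`,
#'   and `constant` (TRUE, with zero variance flagged, for a constant
#'   input matrix).
#' @export
run_pca <- function(pm) {
  m <- if (is.list(pm)) pm$matrix else pm
  if (nrow(m) < 2) stop("PCA needs >= 2 neurons")
  if (all(apply(m, 2, stats::sd) == 0))
    return(list(var_explained = rep(NA_real_, ncol(m)), coefficients = NULL,
                coefficients_by_abl = NULL, scores = NULL, constant = TRUE))
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev ^ 2 / sum(fit$sdev ^ 2)
  by_abl <- NULL
  if (is.list(pm)) {
    ni <- length(pm$ild_db)
    na <- length(pm$abl_db)
    by_abl <- array(fit$rotation, dim = c(ni, na, ncol(fit$rotation)),
                    dimnames = list(pm$ild_db, pm$abl_db, NULL))
  }
  list(var_explained = ve, coefficients = fit$rotation,
       coefficients_by_abl = by_abl, scores = fit$x, constant = FALSE)
}

#' Assign a neuron to an opponent channel
#'
#' Ordinary least-squares regression of single-trial responses (pooled
#' across ABLs) on signed ILD. A negative slope means the neuron prefers
#' contralateral ILDs, a positive slope ipsilateral; the neuron is counted
#' monotonic when the regression is significant.
#'
#' @param responses single-trial responses to binaural noise.
#' @param ild_db signed ILD per trial.
#' @param alpha significance level (default 0.05).
#' @return list with `slope`, `p`, `sign` ("contra"/"ipsi"), `monotonic`.
#' @export
assign_channel <- function(responses, ild_db, alpha = 0.05) {
  if (stats::sd(responses) == 0)
    return(list(slope = NA_real_, p = NA_real_, sign = NA_character_,
                monotonic = FALSE))
  fit <- stats::lm(responses ~ ild_db)
  # summary warns on numerically perfect fits, which are legitimate here
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["ild_db", "Estimate"]
  p <- sm["ild_db", "Pr(>|t|)"]
  list(slope = slope, p = p,
       sign = if (slope < 0) "contra" else "ipsi",
       monotonic = is.finite(p) && p < alpha)
}

# per-neuron normalization for decoding: divide single-trial responses by
# the neuron's maximum trial-averaged per-ILD response
normalize_for_decoding <- function(responses, ild_db) {
  mx <- vapply(split(seq_along(ild_db), ild_db),
               function(i) mean(responses[i]), numeric(1))
  m <- max(mx)
  if (m <= 0) return(NULL)
  responses / m
}

#' Opponent-channel ILD decoding of single trials
#'
#' The opponent value of a trial is the mean normalized response of the
#' contra-preferring neurons minus that of the ipsi-preferring neurons.
#' Each trial's ILD is decoded by comparing its opponent value with the
#' mean opponent value of every ILD computed from all *other* trials
#' (leave-one-out cross-validation) and taking the nearest; ties break
#' toward the smaller absolute ILD. The mean unsigned error (MUE) is the
#' average |true - decoded| in dB, also reported normalized by the maximal
#' possible single-trial error (60 dB for the -30..+30 range).
#'
#' @param responses matrix of single-trial responses, trials x neurons
#'   (binaural noise trials, pooled across ABLs).
#' @param ild_db signed ILD per trial.
#' @param channel "contra"/"ipsi" per neuron.
#' @param loo use leave-one-out reference curves (TRUE, the default);
#'   FALSE deliberately leaks the decoded trial into its own reference and
#'   exists to verify the cross-validation discipline.
#' @param max_error_db maximal possible error used for normalization.
#' @return list with `predicted` (per-trial decoded ILD), `mue_db`,
#'   `mue_normalized`, and `confusion` (percent of trials per true ILD row;
#'   rows sum to 100).
#' @export
opponent_decode <- function(responses, ild_db, channel, loo = TRUE,
                            max_error_db = NULL) {
  stopifnot(ncol(responses) == length(channel))
  if (!any(channel == "contra") || !any(channel == "ipsi"))
    stop("need at least one neuron per opponent channel")
  norm <- vapply(seq_len(ncol(responses)), function(j) {
    v <- normalize_for_decoding(responses[, j], ild_db)
    if (is.null(v)) rep(NA_real_, nrow(responses)) else v
  }, numeric(nrow(responses)))
  ok <- !apply(is.na(norm), 2, any)
  norm <- norm[, ok, drop = FALSE]
  channel <- channel[ok]
  if (!any(channel == "contra") || !any(channel == "ipsi"))
    stop("a channel is empty after dropping non-positive neurons")
  o <- rowMeans(norm[, channel == "contra", drop = FALSE]) -
    rowMeans(norm[, channel == "ipsi", drop = FALSE])

  ilds <- sort(unique(ild_db))
  if (is.null(max_error_db)) max_error_db <- max(ilds) - min(ilds)
  grp <- match(ild_db, ilds)
  sums <- tapply(o, grp, sum)
  ns <- tabulate(grp, length(ilds))
  # reference opponent value per ILD; leave-one-out removes the decoded
  # trial from its own ILD's mean
  refs <- matrix(rep(sums / ns, each = length(o)), ncol = length(ilds))
  if (loo) {
    own <- (sums[grp] - o) / (ns[grp] - 1)
    refs[cbind(seq_along(o), grp)] <- own
  }
  d <- abs(refs - o)
  # tie-break toward the smaller |ILD|: scan candidates in that order
  ord <- order(abs(ilds), ilds)
  pick <- ord[apply(d[, ord, drop = FALSE], 1, which.min)]
  predicted <- ilds[pick]
  err <- abs(predicted - ild_db)
  conf <- 100 * prop.table(table(factor(ild_db, ilds),
                                 factor(predicted, ilds)), 1)
  list(predicted = predicted, mue_db = mean(err),
       mue_normalized = mean(err) / max_error_db, confusion = conf)
}

#' Decoder error as a function of population size
#'
#' At each population size, neurons are repeatedly sampled at random
#' (without replacement) from the monotonic pool, requiring at least one
#' neuron per channel (degenerate draws are redrawn and logged), the
#' opponent decoder is run with leave-one-out cross-validation, and the
#' MUE is averaged across resamples.
#'
#' @param responses matrix of single-trial responses, trials x neurons.
#' @param ild_db signed ILD per trial.
#' @param channel "contra"/"ipsi" per neuron.
#' @param sizes population sizes to test.
#' @param n_rep resamples per size (the reference protocol uses 1000).
#' @param seed integer seed (substream `decode`).
#' @return data.frame: `size`, `mue_db` (mean over resamples), `mue_sd`,
#'   `mue_normalized`, `n_redrawn`.
#' @export
decoder_curve <- function(responses, ild_db, channel, sizes,
                          n_rep = 1000, seed = 1L) {
  pool <- seq_along(channel)
  if (max(sizes) > length(pool))
    stop("population size exceeds the available neuron pool")
  max_err <- max(ild_db) - min(ild_db)
  with_substream(seed, "decode", {
    rows <- lapply(sizes, function(s) {
      redrawn <- 0L
      mues <- vapply(seq_len(n_rep), function(r) {
        repeat {
          idx <- sample(pool, s)
          if (any(channel[idx] == "contra") &&
              any(channel[idx] == "ipsi")) break
          redrawn <<- redrawn + 1L
        }
        opponent_decode(responses[, idx, drop = FALSE], ild_db,
                        channel[idx], max_error_db = max_err)$mue_db
      }, numeric(1))
      data.frame(size = s, mue_db = mean(mues), mue_sd = stats::sd(mues),
                 mue_normalized = mean(mues) / max_err,
                 n_redrawn = redrawn)
    })
    do.call(rbind, rows)
  })
}
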