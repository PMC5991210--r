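#' Paired one-tailed response test for one stimulus condition
#'
#' Tests whether the stimulation-window peak exceeds the pre-stimulus peak
#' across repetitions of one stimulus (paired t-test, one-tailed). When the
#' paired differences have zero variance the t statistic is undefined; a
#' consistent strict increase is then reported as p = 0 and anything else
#' (including identical pre/post values) as p = 1.
#'
#' @param pre,post numeric vectors of pre- and post-window peaks, paired
#'   by repetition.
#' @return the one-tailed p-value.
#' @export
paired_response_p <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2)
    stop("need >= 2 paired repetitions")
  d <- post - pre
  if (stats::sd(d) == 0) return(if (mean(d) > 0) 0 else 1)
  stats::t.test(post, pre, paired = TRUE, alternative = "greater")$p.value
}

#' Identify responsive neurons
#'
#' One paired one-tailed t-test per condition (post-window peak > pre-window
#' peak across repetitions); the neuron is flagged responsive if any
#' condition reaches `p < alpha`.
#'
#' @param pre,post numeric vectors over trials for one neuron.
#' @param groups condition label per trial (e.g. ILD for noise bursts,
#'   frequency for tones).
#' @param alpha significance level (default 0.01).
#' @return list with `p` (named per-condition p-values), `by_condition`
#'   (logical flags) and `responsive` (any condition significant).
#' @export
test_responsive <- function(pre, post, groups, alpha = 0.01) {
  groups <- factor(groups)
  p <- vapply(levels(groups), function(g) {
    idx <- groups == g
    paired_response_p(pre[idx], post[idx])
  }, numeric(1))
  list(p = p, by_condition = p < alpha, responsive = any(p < alpha))
}

#' Test ILD sensitivity at one ABL
#'
#' One-way fixed-effects ANOVA of single-trial responses across the tested
#' ILDs (classic equal-variance F test). Responses with no variance at all
#' yield an undefined F and are reported as not sensitive.
#'
#' @param responses single-trial responses at one ABL.
#' @param ild ILD label per trial.
#' @param alpha significance level (default 0.05).
#' @param expected_ild optional full set of tested ILDs; an absent group
#'   is an error.
#' @return list with `p` and logical `sensitive`.
#' @export
test_ild_sensitivity <- function(responses, ild, alpha = 0.05,
                                 expected_ild = NULL) {
  if (!is.null(expected_ild) && !all(expected_ild %in% ild))
    stop("missing ILD group(s): ",
         paste(setdiff(expected_ild, ild), collapse = ", "))
  g <- factor(ild)
  if (any(table(g) < 2)) stop("every ILD group needs >= 2 repetitions")
  if (stats::sd(responses) == 0)
    return(list(p = NA_real_, sensitive = FALSE))
  p <- stats::oneway.test(responses ~ g, var.equal = TRUE)$p.value
  list(p = p, sensitive = is.finite(p) && p < alpha)
}

#' Summarize an ILD tuning curve
#'
#' From the trial-averaged response at each ILD: the peak ILD (argmax; ties
#' broken toward the most contralateral, i.e. most negative, ILD), the
#' slopes between contiguous ILDs, the midpoint of the steepest (largest
#' absolute) slope, and the weighted ILD preference (centroid)
#' `sum(ILD_i * r_i) / sum(r_i)`. Negative mean responses are floored at 0
#' before the centroid so suppression cannot push the preference outside
#' the tested range (disable with `floor_negative = FALSE`).
#'
#' @param mean_resp trial-averaged response per ILD.
#' @param ild_db the ILD values (sorted ascending).
#' @param floor_negative floor negative means at zero for the centroid.
#' @return list with `peak_ild_db`, `slopes` (length `n - 1`, named by
#'   interval midpoints), `steepest_midpoint_db`, `weighted_ild_db` (NA,
#'   flagged via `weighted_defined`, when the floored responses sum to 0).
#' @export
ild_curve_summary <- function(mean_resp, ild_db, floor_negative = TRUE) {
  stopifnot(length(mean_resp) == length(ild_db), !is.unsorted(ild_db))
  peak <- ild_db[which.max(mean_resp)]  # which.max takes the first tie
  slopes <- diff(mean_resp)
  mids <- (ild_db[-1] + ild_db[-length(ild_db)]) / 2
  names(slopes) <- mids
  steepest <- mids[which.max(abs(slopes))]
  r <- if (floor_negative) pmax(mean_resp, 0) else mean_resp
  if (sum(r) <= 0) {
    weighted <- NA_real_
    defined <- FALSE
  } else {
    weighted <- sum(ild_db * r) / sum(r)
    defined <- TRUE
  }
  list(peak_ild_db = peak, slopes = slopes, steepest_midpoint_db = steepest,
       weighted_ild_db = weighted, weighted_defined = defined)
}

#' Group-averaged normalized ILD response curves
#'
#' Each neuron's tuning curve is divided by its own maximum and the
#' normalized curves are averaged within groups of neurons sharing the same
#' peak ILD. Empty groups are omitted.
#'
#' @param curves matrix of trial-averaged responses, neurons x ILDs.
#' @param peak_ild peak ILD per neuron (the grouping variable).
#' @return matrix of mean normalized curves, one row per occupied group,
#'   rownames = peak ILD.
#' @export
group_average_curves <- function(curves, peak_ild) {
  norm <- curves / apply(curves, 1, max)
  groups <- sort(unique(peak_ild))
  out <- t(vapply(groups, function(g) {
    colMeans(norm[peak_ild == g, , drop = FALSE])
  }, numeric(ncol(curves))))
  rownames(out) <- groups
  out
}

#' Build a frequency response area
#'
#' Cell (i, j) is the trial-mean response to frequency i at level j. A
#' smoothed copy applies a 3-point running average along frequency with
#' truncated-kernel renormalization at the edges (edge cells average 2
#' points); best frequency and statistics always use the unsmoothed matrix.
#'
#' @param responses single-trial tone responses.
#' @param freq_hz,level_db frequency and level label per trial.
#' @return list with `fra`, `fra_smooth` (freq x level matrices), `freq_hz`
#'   and `level_db`.
#' @export
build_fra <- function(responses, freq_hz, level_db) {
  f <- factor(freq_hz, levels = sort(unique(freq_hz)))
  l <- factor(level_db, levels = sort(unique(level_db)))
  if (any(table(f, l) == 0)) stop("missing frequency x level cells")
  fra <- tapply(responses, list(f, l), mean)
  sm <- fra
  nf <- nrow(fra)
  if (nf >= 2) {
    for (i in seq_len(nf)) {
      win <- max(1, i - 1):min(nf, i + 1)
      sm[i, ] <- colMeans(fra[win, , drop = FALSE])
    }
  }
  list(fra = fra, fra_smooth = sm,
       freq_hz = sort(unique(freq_hz)),
       level_db = sort(unique(level_db)))
}

#' Test frequency and level sensitivity
#'
#' Two-way fixed-effects ANOVA of single-trial tone responses on frequency
#' and level (type-II sums of squares, so unbalanced designs are handled;
#' for a balanced grid this equals the classic two-way ANOVA).
#'
#' @param responses single-trial tone responses.
#' @param freq_hz,level_db frequency and level label per trial.
#' @param alpha significance level (default 0.05).
#' @return list with `p_freq`, `p_level`, and flags `freq_sensitive`,
#'   `level_sensitive`.
#' @export
test_frequency_sensitivity <- function(responses, freq_hz, level_db,
                                       alpha = 0.05) {
  f <- factor(freq_hz)
  l <- factor(level_db)
  if (any(table(f, l) < 2)) stop("every cell needs >= 2 repetitions")
  if (stats::sd(responses) == 0)
    return(list(p_freq = NA_real_, p_level = NA_real_,
                freq_sensitive = FALSE, level_sensitive = FALSE))
  fit <- stats::lm(responses ~ f * l)
  a <- car::Anova(fit, type = 2)
  pf <- a["f", "Pr(>F)"]
  pl <- a["l", "Pr(>F)"]
  list(p_freq = pf, p_level = pl,
       freq_sensitive = is.finite(pf) && pf < alpha,
       level_sensitive = is.finite(pl) && pl < alpha)
}

#' Best frequency with the 3-SD validity rule
#'
#' BF is the frequency with the highest mean response averaged across all
#' levels (ties broken toward the lowest frequency). The BF is valid only
#' if the mean response at BF is at least 3 standard deviations above the
#' mean pre-stimulus level, both computed from the neuron's tone trials
#' (pre-window peaks supply the pre-stimulus mean and SD); otherwise the
#' neuron has no clear BF.
#'
#' @param fra unsmoothed frequency x level matrix from [build_fra()].
#' @param freq_hz frequencies corresponding to the FRA rows.
#' @param pre_peaks pre-window peak dF/F0 values across the neuron's tone
#'   trials.
#' @return list with `bf_hz`, `valid`, `tie` (TRUE when the argmax was
#'   tied and broken toward the lowest frequency).
#' @export
best_frequency <- function(fra, freq_hz, pre_peaks) {
  m <- rowMeans(fra)
  tie <- sum(m == max(m)) > 1
  bf <- freq_hz[which.max(m)]
  thr <- mean(pre_peaks) + 3 * stats::sd(pre_peaks)
  list(bf_hz = bf, valid = max(m) >= thr, tie = tie)
}

#' Tonotopic gradient orientation
#'
#' Correlates log2(BF) with each neuron's position projected onto an axis
#' rotated in 1-degree steps through 360 degrees; the rotation producing
#' the strongest negative correlation is the orientation of the tonotopic
#' gradient. The profile satisfies r(theta) = -r(theta + 180) exactly.
#'
#' @param positions data.frame or matrix with x (rostro-caudal) and y
#'   (dorso-ventral) coordinates in um.
#' @param bf_hz best frequency per neuron.
#' @return list with `angle_deg` (argmin of the profile), `r_at_angle`,
#'   and `profile` (data.frame of angle and r). All-equal BFs give an
#'   undefined profile (`defined = FALSE`).
#' @export
tonotopic_gradient <- function(positions, bf_hz) {
  keep <- is.finite(bf_hz)
  if (sum(keep) < 3) stop("need >= 3 neurons with a valid BF")
  x <- positions[keep, 1]
  y <- positions[keep, 2]
  lbf <- log2(bf_hz[keep])
  if (stats::sd(lbf) == 0)
    return(list(angle_deg = NA_real_, r_at_angle = NA_real_,
                profile = NULL, defined = FALSE))
  th <- (0:359) * pi / 180
  proj <- outer(x, cos(th)) + outer(y, sin(th))
  r <- as.numeric(stats::cor(lbf, proj))
  ang <- which.min(r) - 1L
  list(angle_deg = ang, r_at_angle = min(r),
       profile = data.frame(angle_deg = 0:359, r = r), defined = TRUE)
}

#' Best-frequency variation within a field
#'
#' Standard deviation of log2(BF) across neurons of one imaging field, in
#' octaves (the coefficient of BF variation).
#'
#' @param bf_hz best frequencies (>= 2 finite values required).
#' @return SD in octaves.
#' @export
bf_variation <- function(bf_hz) {
  bf <- bf_hz[is.finite(bf_hz)]
  if (length(bf) < 2) return(NA_real_)
  stats::sd(log2(bf))
}
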