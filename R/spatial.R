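#' Noise correlation between two neurons
#'
#' Each single-trial response is normalized for stimulus effects by
#' subtracting the neuron's mean response to that stimulus; the noise
#' correlation is the Pearson correlation of the residual vectors.
#' Defined only for simultaneously recorded neurons (same trials).
#'
#' @param resp_a,resp_b single-trial responses over the same trials.
#' @param cond stimulus condition label per trial.
#' @return Pearson r, or NA when a residual vector has zero variance.
#' @export
noise_correlation <- function(resp_a, resp_b, cond) {
  stopifnot(length(resp_a) == length(resp_b),
            length(cond) == length(resp_a))
  if (any(table(cond) < 2)) stop("need >= 2 repetitions per condition")
  ra <- resp_a - stats::ave(resp_a, cond)
  rb <- resp_b - stats::ave(resp_b, cond)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  stats::cor(ra, rb)
}

#' Signal correlation between two neurons
#'
#' Pearson correlation of the two neurons' trial-averaged (per-condition)
#' responses, minus the pair's noise correlation, so shared trial-to-trial
#' variability does not masquerade as shared tuning. By construction,
#' signal + noise correlation equals the raw correlation of trial-averaged
#' responses.
#'
#' @inheritParams noise_correlation
#' @return the signal correlation, or NA when a condition-mean vector is
#'   constant.
#' @export
signal_correlation <- function(resp_a, resp_b, cond) {
  ma <- tapply(resp_a, cond, mean)
  mb <- tapply(resp_b, cond, mean)
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) return(NA_real_)
  nc <- noise_correlation(resp_a, resp_b, cond)
  if (!is.finite(nc)) return(NA_real_)
  stats::cor(as.numeric(ma), as.numeric(mb)) - nc
}

#' Bootstrap shuffle null for a pair's correlation
#'
#' For the noise mode, each iteration redraws every trial's response (with
#' replacement, independently per neuron) from that neuron's responses to
#' the same stimulus and recomputes the noise correlation. For the signal
#' mode, responses are redrawn from the neuron's responses to all stimuli
#' and the signal correlation is recomputed. Shuffling destroys the
#' between-neuron structure, so the null is centred near zero.
#'
#' @inheritParams noise_correlation
#' @param n_iter bootstrap iterations (reference protocol: 1000).
#' @param mode "noise" or "signal".
#' @param seed integer seed (substream `boot`).
#' @return numeric vector of `n_iter` null correlations.
#' @export
correlation_null <- function(resp_a, resp_b, cond, n_iter = 1000,
                             mode = c("noise", "signal"), seed = 1L) {
  mode <- match.arg(mode)
  n <- length(resp_a)
  cond <- as.character(cond)
  with_substream(seed, "boot", {
    if (mode == "noise") {
      idx_by_cond <- split(seq_len(n), cond)
      vapply(seq_len(n_iter), function(i) {
        ia <- ib <- integer(n)
        for (g in idx_by_cond) {
          ia[g] <- g[sample.int(length(g), length(g), replace = TRUE)]
          ib[g] <- g[sample.int(length(g), length(g), replace = TRUE)]
        }
        r <- noise_correlation(resp_a[ia], resp_b[ib], cond)
        if (is.finite(r)) r else 0
      }, numeric(1))
    } else {
      vapply(seq_len(n_iter), function(i) {
        ia <- sample.int(n, n, replace = TRUE)
        ib <- sample.int(n, n, replace = TRUE)
        r <- signal_correlation(resp_a[ia], resp_b[ib], cond)
        if (is.finite(r)) r else 0
      }, numeric(1))
    }
  })
}

#' Pairwise signal/noise correlations for a field, with shuffle test
#'
#' Computes signal and noise correlations and their bootstrap null means
#' for every pair of the selected (simultaneously imaged) neurons, along
#' with the pair's rostro-caudal and dorso-ventral separations, and tests
#' whether observed correlations exceed the shuffled ones with a paired
#' t-test across pairs.
#'
#' @param responses matrix of single-trial responses, trials x neurons.
#' @param cond stimulus condition label per trial.
#' @param positions data.frame with `x_um` (rostro-caudal) and `y_um`
#'   (dorso-ventral) per neuron.
#' @param n_iter bootstrap iterations per pair.
#' @param alpha significance level of the paired test (default 0.01).
#' @param seed integer seed.
#' @return list with `pairs` (data.frame: indices, axis distances, noise_r,
#'   signal_r, null means) and `tests` (paired-t p-values for noise and
#'   signal, with significance flags).
#' @export
correlation_analysis <- function(responses, cond, positions,
                                 n_iter = 1000, alpha = 0.01, seed = 1L) {
  n <- ncol(responses)
  if (n < 2) stop("need >= 2 neurons")
  pr <- t(utils::combn(n, 2))
  rows <- lapply(seq_len(nrow(pr)), function(k) {
    a <- pr[k, 1]; b <- pr[k, 2]
    nr <- noise_correlation(responses[, a], responses[, b], cond)
    sr <- signal_correlation(responses[, a], responses[, b], cond)
    if (!is.finite(nr) || !is.finite(sr)) return(NULL)
    nn <- mean(correlation_null(responses[, a], responses[, b], cond,
                                n_iter, "noise", seed = seed + k))
    sn <- mean(correlation_null(responses[, a], responses[, b], cond,
                                n_iter, "signal", seed = seed + k))
    data.frame(a = a, b = b,
               dist_rc_um = abs(positions$x_um[a] - positions$x_um[b]),
               dist_dv_um = abs(positions$y_um[a] - positions$y_um[b]),
               noise_r = nr, signal_r = sr,
               noise_null = nn, signal_null = sn)
  })
  pairs <- do.call(rbind, rows)
  tests <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 2) {
    pn <- stats::t.test(pairs$noise_r, pairs$noise_null,
                        paired = TRUE)$p.value
    ps <- stats::t.test(pairs$signal_r, pairs$signal_null,
                        paired = TRUE)$p.value
    tests <- list(p_noise = pn, p_signal = ps,
                  noise_significant = pn < alpha,
                  signal_significant = ps < alpha)
  }
  list(pairs = pairs, tests = tests)
}

#' Correlation versus cortical distance
#'
#' Ordinary least-squares fit of pairwise correlations on inter-neuron
#' distance, separately per cortical axis (rostro-caudal, dorso-ventral)
#' and per metric (signal, noise).
#'
#' @param pairs the `pairs` data.frame from [correlation_analysis()].
#' @return data.frame: `metric`, `axis`, `slope`, `intercept`, `r`, `p`.
#'   Degenerate (constant) distances yield no fit for that axis.
#' @export
correlation_vs_distance <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) < 3) stop("need >= 3 pairs")
  grid <- expand.grid(metric = c("signal", "noise"),
                      axis = c("rc", "dv"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    y <- pairs[[paste0(grid$metric[i], "_r")]]
    x <- pairs[[paste0("dist_", grid$axis[i], "_um")]]
    if (stats::sd(x) == 0) return(NULL)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    data.frame(metric = grid$metric[i], axis = grid$axis[i],
               slope = sm["x", "Estimate"],
               intercept = sm["(Intercept)", "Estimate"],
               r = stats::cor(x, y), p = sm["x", "Pr(>|t|)"])
  })
  do.call(rbind, rows)
}

#' Bootstrapped spatial-clustering test
#'
#' Tests whether nearby neurons have more similar values of a tuning
#' parameter than distant ones. The preference distance of a pair is
#' `|value_a - value_b|`. The observed statistic is the mean preference
#' distance over all local pairs (2D separation <= `threshold_um` in the
#' rostro-caudal x dorso-ventral plane); the null draws, `n_boot` times,
#' the same number of pairs from those separated by more than the
#' threshold (without replacement when enough distant pairs exist, with
#' replacement otherwise) and takes each draw's mean. Clustering is
#' significant when the observed mean falls strictly below the 5th
#' percentile of the bootstrap means.
#'
#' @param values numeric value per neuron (e.g. weighted ILD in dB,
#'   log2 BF in octaves, or a category code); NA values are dropped.
#' @param positions data.frame with `x_um`, `y_um` per neuron.
#' @param threshold_um local/distant separation threshold (default 150).
#' @param n_boot bootstrap draws (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed (substream `boot`).
#' @return an object of class `cluster_test`: `observed`, `boot`
#'   (bootstrap means), `percentile` of the observed value, `significant`,
#'   `n_local`, `n_distant`, `conclusive`.
#' @export
cluster_test <- function(values, positions, threshold_um = 150,
                         n_boot = 1000, alpha = 0.05, seed = 1L) {
  keep <- which(is.finite(values))
  v <- values[keep]
  x <- positions$x_um[keep]
  y <- positions$y_um[keep]
  n <- length(v)
  res <- list(observed = NA_real_, boot = NULL, percentile = NA_real_,
              significant = FALSE, n_local = 0L, n_distant = 0L,
              conclusive = FALSE, threshold_um = threshold_um)
  class(res) <- "cluster_test"
  if (n < 3) return(res)
  pr <- t(utils::combn(n, 2))
  d <- sqrt((x[pr[, 1]] - x[pr[, 2]]) ^ 2 + (y[pr[, 1]] - y[pr[, 2]]) ^ 2)
  pd <- abs(v[pr[, 1]] - v[pr[, 2]])
  local <- d <= threshold_um
  distant <- d > threshold_um
  res$n_local <- sum(local)
  res$n_distant <- sum(distant)
  if (res$n_local < 2 || res$n_distant < 2) return(res)
  res$observed <- mean(pd[local])
  dist_pd <- pd[distant]
  replace <- res$n_distant < res$n_local
  res$boot <- with_substream(seed, "boot", {
    vapply(seq_len(n_boot), function(i) {
      mean(dist_pd[sample.int(res$n_distant, res$n_local,
                              replace = replace)])
    }, numeric(1))
  })
  res$percentile <- mean(res$boot < res$observed) * 100
  q5 <- stats::quantile(res$boot, alpha, names = FALSE)
  res$significant <- res$observed < q5
  res$conclusive <- TRUE
  res
}

#' Clustering of best frequencies
#'
#' Runs [cluster_test()] on log2(BF) so preference distances are octaves.
#' @param bf_hz best frequency per neuron (NA for neurons without one).
#' @param positions,threshold_um,n_boot,alpha,seed see [cluster_test()].
#' @return a `cluster_test` object.
#' @export
cluster_test_bf <- function(bf_hz, positions, threshold_um = 150,
                            n_boot = 1000, alpha = 0.05, seed = 1L) {
  cluster_test(log2(bf_hz), positions, threshold_um, n_boot, alpha, seed)
}

#' Clustering of weighted ILD preferences
#'
#' Restricted to neurons with a valid BF of at least `min_bf_hz` (10 kHz by
#' default), because free-field ILDs generated by lower frequencies are
#' negligible in small-headed rodents.
#'
#' @param weighted_ild_db weighted ILD preference per neuron.
#' @param bf_hz best frequency per neuron (NA excludes the neuron).
#' @param min_bf_hz BF inclusion threshold.
#' @param positions,threshold_um,n_boot,alpha,seed see [cluster_test()].
#' @return a `cluster_test` object.
#' @export
cluster_test_ild <- function(weighted_ild_db, bf_hz, positions,
                             min_bf_hz = 10000, threshold_um = 150,
                             n_boot = 1000, alpha = 0.05, seed = 1L) {
  v <- weighted_ild_db
  v[!is.finite(bf_hz) | bf_hz < min_bf_hz] <- NA_real_
  cluster_test(v, positions, threshold_um, n_boot, alpha, seed)
}

#' Clustering of binaural categories
#'
#' Only the three most common categories enter, coded numerically for the
#' preference-distance statistic: EO/I = -1, EO/F = 0, OO/F = 1. Subject
#' to the same BF >= 10 kHz restriction as the ILD-preference test.
#'
#' @param category binaural category string per neuron.
#' @param bf_hz best frequency per neuron.
#' @param min_bf_hz BF inclusion threshold.
#' @param positions,threshold_um,n_boot,alpha,seed see [cluster_test()].
#' @return a `cluster_test` object.
#' @export
cluster_test_category <- function(category, bf_hz, positions,
                                  min_bf_hz = 10000, threshold_um = 150,
                                  n_boot = 1000, alpha = 0.05, seed = 1L) {
  code <- c("EO/I" = -1, "EO/F" = 0, "OO/F" = 1)[category]
  code[!is.finite(bf_hz) | bf_hz < min_bf_hz] <- NA_real_
  cluster_test(unname(code), positions, threshold_um, n_boot, alpha, seed)
}
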