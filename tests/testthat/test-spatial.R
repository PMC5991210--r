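make_cond_responses <- function(n_cond = 7, n_rep = 12, seed = 51) {
  set.seed(seed)
  cond <- rep(seq_len(n_cond), each = n_rep)
  tuning <- rnorm(n_cond, 0, 1)
  list(cond = cond, tuning = tuning)
}

test_that("noise correlation captures shared residuals exactly", {
  cc <- make_cond_responses()
  z <- rnorm(length(cc$cond))
  a <- cc$tuning[cc$cond] + z
  b <- 2 * cc$tuning[cc$cond] + 3 * z
  expect_equal(noise_correlation(a, b, cc$cond), 1)
  expect_equal(noise_correlation(a, cc$tuning[cc$cond] - z, cc$cond), -1)
  # residual-free neuron: undefined
  expect_true(is.na(noise_correlation(a, cc$tuning[cc$cond], cc$cond)))
  # independent residuals stay small with many trials
  set.seed(52)
  hits <- 0
  for (i in 1:40) {
    x <- rnorm(300); y <- rnorm(300)
    g <- rep(1:25, each = 12)
    if (abs(noise_correlation(x, y, g)) < 0.15) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("signal + noise correlation equals the raw trial-averaged correlation", {
  cc <- make_cond_responses()
  set.seed(53)
  a <- cc$tuning[cc$cond] + rnorm(length(cc$cond), 0, 0.5)
  b <- rev(cc$tuning)[cc$cond] + rnorm(length(cc$cond), 0, 0.5)
  nr <- noise_correlation(a, b, cc$cond)
  sr <- signal_correlation(a, b, cc$cond)
  raw <- cor(as.numeric(tapply(a, cc$cond, mean)),
             as.numeric(tapply(b, cc$cond, mean)))
  expect_equal(sr + nr, raw)
  # identical tuning with shared noise: signal = 1 - noise correlation
  # (residuals centred within condition so the empirical means equal the
  # tuning curve exactly)
  z <- rnorm(length(cc$cond))
  z <- z - ave(z, cc$cond)
  e2 <- rnorm(length(cc$cond))
  e2 <- e2 - ave(e2, cc$cond)
  a2 <- cc$tuning[cc$cond] + z
  b2 <- cc$tuning[cc$cond] + z + e2
  nc2 <- noise_correlation(a2, b2, cc$cond)
  expect_equal(signal_correlation(a2, b2, cc$cond), 1 - nc2)
})

test_that("shuffle nulls are centred near zero and flag real structure", {
  cc <- make_cond_responses(n_cond = 5, n_rep = 10)
  set.seed(54)
  z <- rnorm(length(cc$cond))
  a <- cc$tuning[cc$cond] + z + rnorm(length(cc$cond), 0, 0.2)
  b <- cc$tuning[cc$cond] + z + rnorm(length(cc$cond), 0, 0.2)
  nn <- correlation_null(a, b, cc$cond, n_iter = 300, mode = "noise",
                         seed = 55)
  sn <- correlation_null(a, b, cc$cond, n_iter = 300, mode = "signal",
                         seed = 55)
  expect_lt(abs(mean(nn)), 0.1)
  expect_lt(abs(mean(sn)), 0.15)
  # observed correlations well above their nulls
  expect_gt(noise_correlation(a, b, cc$cond), mean(nn) + 0.5)
})

test_that("field-level correlation analysis flags a strong shared latent", {
  cc <- make_cond_responses(n_cond = 5, n_rep = 10)
  set.seed(56)
  n_neu <- 5
  z <- rnorm(length(cc$cond))
  resp <- sapply(seq_len(n_neu), function(j)
    rnorm(1, 0, 1) * cc$tuning[cc$cond] + z +
      rnorm(length(cc$cond), 0, 0.3))
  pos <- data.frame(x_um = runif(n_neu, 0, 250),
                    y_um = runif(n_neu, 0, 250))
  ca <- correlation_analysis(resp, cc$cond, pos, n_iter = 100, seed = 57)
  expect_equal(nrow(ca$pairs), choose(n_neu, 2))
  expect_true(ca$tests$noise_significant)
  fits <- correlation_vs_distance(ca$pairs)
  expect_setequal(fits$metric, c("signal", "noise"))
  expect_true(all(is.finite(fits$slope)))
})

test_that("cluster test finds planted clusters and respects degeneracy rules", {
  set.seed(58)
  n <- 60
  pos <- data.frame(x_um = runif(n, 0, 500), y_um = runif(n, 0, 250))
  # two planted clusters, 30 dB apart
  v <- ifelse(pos$x_um < 250, -15, 15) + rnorm(n, 0, 2)
  ct <- cluster_test(v, pos, seed = 59)
  expect_true(ct$significant)
  expect_true(ct$conclusive)
  # translation invariance
  ct2 <- cluster_test(v + 100, pos, seed = 59)
  expect_equal(ct$observed, ct2$observed)
  expect_equal(ct$significant, ct2$significant)
  # identical values: observed equals every bootstrap mean, strict rule
  ct3 <- cluster_test(rep(3, n), pos, seed = 59)
  expect_false(ct3$significant)
  expect_equal(ct3$observed, 0)
  # too few neurons: inconclusive, not significant
  ct4 <- cluster_test(v[1:2], pos[1:2, ], seed = 59)
  expect_false(ct4$conclusive)
  expect_false(ct4$significant)
})

test_that("BF and category wrappers apply their filters and codings", {
  set.seed(60)
  n <- 40
  pos <- data.frame(x_um = runif(n, 0, 400), y_um = runif(n, 0, 250))
  bf <- 2 ^ runif(n, log2(4e3), log2(45e3))
  ctb <- cluster_test_bf(bf, pos, seed = 61)
  # octave distances: same result as log2-transformed generic test
  ctg <- cluster_test(log2(bf), pos, seed = 61)
  expect_equal(ctb$observed, ctg$observed)
  # low-BF neurons are excluded from the ILD test
  wild <- runif(n, -30, 30)
  ct_all <- cluster_test_ild(wild, rep(20e3, n), pos, seed = 61)
  ct_cut <- cluster_test_ild(wild, ifelse(seq_len(n) <= 10, 5e3, 20e3),
                             pos, seed = 61)
  expect_gte(ct_all$n_local + ct_all$n_distant,
             ct_cut$n_local + ct_cut$n_distant)
  # category coding keeps only the three major classes
  cats <- sample(c("EO/I", "EO/F", "OO/F", "EE/N", "OE/I"), n, TRUE)
  ctc <- cluster_test_category(cats, rep(20e3, n), pos, seed = 61)
  n_used <- sum(cats %in% c("EO/I", "EO/F", "OO/F"))
  expect_equal(ctc$n_local + ctc$n_distant, choose(n_used, 2))
})
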