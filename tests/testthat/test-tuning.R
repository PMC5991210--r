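test_that("paired response test flags large effects and degenerate inputs", {
  set.seed(21)
  pre <- rnorm(12, 0, 0.01)
  expect_lt(paired_response_p(pre, pre + 10), 0.01)
  expect_equal(paired_response_p(pre, pre), 1)
  g <- rep(seq(-30, 30, 10), each = 12)
  post <- rnorm(length(g), 0, 1)
  rt <- test_responsive(rnorm(length(g)), post, g)
  expect_length(rt$p, 7)
  rt2 <- test_responsive(post, post + 10 + rnorm(length(g), 0, 0.01), g)
  expect_true(rt2$responsive)
  expect_true(all(rt2$by_condition))
})

test_that("ILD ANOVA detects planted differences and handles degeneracy", {
  ild <- rep(seq(-30, 30, 10), each = 12)
  set.seed(22)
  r <- rnorm(length(ild))
  r[ild == 0] <- r[ild == 0] + 10
  expect_true(test_ild_sensitivity(r, ild)$sensitive)
  st <- test_ild_sensitivity(rep(1, length(ild)), ild)
  expect_false(st$sensitive)
  expect_true(is.na(st$p))
  expect_error(test_ild_sensitivity(r[ild != 0], ild[ild != 0],
                                    expected_ild = seq(-30, 30, 10)),
               "missing ILD")
  expect_error(test_ild_sensitivity(r[1:13], ild[1:13]), "2 repetitions")
})

test_that("ILD curve summaries match hand-computed values", {
  ilds <- seq(-30, 30, 10)
  s <- ild_curve_summary(rep(1, 7), ilds)
  expect_equal(s$weighted_ild_db, 0)
  expect_equal(s$peak_ild_db, -30)  # tie toward most contralateral
  s <- ild_curve_summary(c(1, 0, 0, 0, 0, 0, 0), ilds)
  expect_equal(s$weighted_ild_db, -30)
  expect_equal(s$peak_ild_db, -30)
  s <- ild_curve_summary(c(2, 1, 1, 1, 1, 1, 1), ilds)
  expect_equal(s$weighted_ild_db, -30 / 8)
  expect_equal(s$steepest_midpoint_db, -25)
  expect_equal(max(abs(s$slopes)), 1)
  expect_length(s$slopes, 6)
  # all-suppressed neuron: centroid undefined, flagged
  s <- ild_curve_summary(rep(-1, 7), ilds)
  expect_false(s$weighted_defined)
  expect_true(is.na(s$weighted_ild_db))
})

test_that("centroid matches the oracle and shrinks toward 0 under offsets", {
  ilds <- seq(-30, 30, 10)
  set.seed(23)
  for (i in 1:50) {
    m <- rnorm(7)
    s <- ild_curve_summary(m, ilds)
    expect_equal(s$weighted_ild_db, oracle_centroid(m, ilds))
    expect_equal(unname(s$slopes), oracle_slopes(m))
  }
  m <- c(2, 1.5, 1, 0.5, 0.3, 0.2, 0.1)
  w0 <- ild_curve_summary(m, ilds)$weighted_ild_db
  w1 <- ild_curve_summary(m + 2, ilds)$weighted_ild_db
  expect_lt(abs(w1), abs(w0))
})

test_that("group-averaged normalized curves behave under symmetry", {
  ilds <- seq(-30, 30, 10)
  up <- seq(0.1, 1, length.out = 7)
  curves <- rbind(up, rev(up), up * 3, rev(up) * 3)
  g <- group_average_curves(curves, c(30, -30, 30, -30))
  expect_equal(max(g["30", ]), 1)
  expect_equal(unname(g["30", ]), unname(rev(g["-30", ])))
  # single-neuron group is its own normalized curve
  g1 <- group_average_curves(curves[1, , drop = FALSE], 30)
  expect_equal(unname(g1[1, ]), up / max(up))
})

test_that("FRA smoothing uses a truncated 3-point kernel", {
  freq <- rep(2 ^ (1:5) * 1000, each = 6)
  lvl <- rep(rep(c(60, 80), each = 3), 5)
  r <- rep(0, length(freq))
  fra <- build_fra(r, freq, lvl)
  expect_equal(fra$fra_smooth, fra$fra)
  # interior impulse spreads to 1/3 over three frequencies
  r[freq == 8000 & lvl == 60] <- 1
  fra <- build_fra(r, freq, lvl)
  expect_equal(unname(fra$fra_smooth[, "60"]), c(0, 1/3, 1/3, 1/3, 0))
  # edge impulse: truncated kernel averages 2 cells
  r <- rep(0, length(freq))
  r[freq == 2000 & lvl == 60] <- 1
  fra <- build_fra(r, freq, lvl)
  expect_equal(unname(fra$fra_smooth[, "60"]), c(1/2, 1/3, 0, 0, 0))
  expect_no_error(build_fra(r[-1], freq[-1], lvl[-1]))
})

test_that("two-way ANOVA separates frequency and level effects", {
  set.seed(24)
  freq <- rep(rep(2 ^ (1:6) * 1000, each = 4), 3)
  lvl <- rep(c(40, 60, 80), each = 24)
  r <- 0.05 * (lvl - 60) + rnorm(length(freq), 0, 0.5)
  fs <- test_frequency_sensitivity(r, freq, lvl)
  expect_false(fs$freq_sensitive)
  expect_true(fs$level_sensitive)
  r2 <- r + 3 * exp(-(log2(freq / 8000)) ^ 2)
  expect_true(test_frequency_sensitivity(r2, freq, lvl)$freq_sensitive)
})

test_that("best frequency uses the level-averaged peak and the 3-SD rule", {
  freqs <- 2 ^ (1:5) * 1000
  fra <- matrix(0, 5, 3, dimnames = list(freqs, c(40, 60, 80)))
  fra[3, ] <- 1
  pre <- rnorm(30, 0.02, 0.01)
  b <- best_frequency(fra, freqs, pre)
  expect_equal(b$bf_hz, 8000)
  expect_true(b$valid)
  # flat FRA: tie broken toward the lowest frequency, typically invalid
  flat <- matrix(0.01, 5, 3)
  b <- best_frequency(flat, freqs, pre)
  expect_equal(b$bf_hz, 2000)
  expect_true(b$tie)
  expect_false(b$valid)
})

test_that("tonotopic gradient is recovered and rotation-equivariant", {
  set.seed(25)
  x <- runif(60, 0, 500); y <- runif(60, 0, 500)
  bf <- 2 ^ (14 - 0.004 * x)
  g <- tonotopic_gradient(data.frame(x, y), bf)
  expect_equal(g$angle_deg, 0)
  expect_equal(g$r_at_angle, -1)
  # profile antisymmetry r(theta) = -r(theta + 180)
  r <- g$profile$r
  expect_equal(r[1:180], -r[181:360])
  g90 <- tonotopic_gradient(data.frame(x = -y, y = x), bf)
  expect_equal(g90$angle_deg, 90)
  expect_error(tonotopic_gradient(data.frame(x[1:2], y[1:2]), bf[1:2]),
               "3 neurons")
  gd <- tonotopic_gradient(data.frame(x, y), rep(8000, 60))
  expect_false(gd$defined)
})

test_that("BF variation is the SD of log2 frequency, scale invariant", {
  expect_equal(bf_variation(c(10e3, 40e3)), sqrt(2))
  expect_equal(bf_variation(rep(12e3, 5)), 0)
  bf <- c(4, 9, 17, 33) * 1e3
  expect_equal(bf_variation(bf * 2), bf_variation(bf))
  expect_true(is.na(bf_variation(5e3)))
})
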