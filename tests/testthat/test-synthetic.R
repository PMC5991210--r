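test_that("expected rates follow the planted tuning", {
  spec <- stimulus_spec()
  neu <- synth_neurons(4, seed = 1)
  neu$baseline_hz <- 2
  neu$gain_hz <- 40
  tr <- data.frame(stim_class = "binaural",
                   ild_db = spec$ild_db, abl_db = 60,
                   freq_hz = NA_real_, level_db = NA_real_)
  # untuned: flat at baseline + gain x abl_gain
  neu$tuning_type[1] <- "untuned"
  r <- expected_rate(neu[1, ], tr, spec)
  expect_true(all(abs(r - r[1]) < 1e-12))
  expect_equal(r[1], 2 + 40 * 0.8)  # middle of three ABL gains
  # monotonic-contra responds more at -30 than +30
  neu$tuning_type[2] <- "monotonic-contra"
  r <- expected_rate(neu[2, ], tr, spec)
  expect_gt(r[1], r[7])
  # OO/F: monaural rates at baseline, diotic above it
  neu$tuning_type[3] <- "untuned"
  neu$binaural_class[3] <- "OO/F"
  mon <- data.frame(stim_class = c("monaural_contra", "monaural_ipsi",
                                   "binaural"),
                    ild_db = c(NA, NA, 0), abl_db = 60,
                    freq_hz = NA_real_, level_db = NA_real_)
  r <- expected_rate(neu[3, ], mon, spec)
  expect_equal(r[1], neu$baseline_hz[3])
  expect_equal(r[2], neu$baseline_hz[3])
  expect_gt(r[3], neu$baseline_hz[3])
})

test_that("simulation is seed-deterministic and noise-free traces are constant", {
  spec <- small_spec()
  e1 <- simulate_experiment(n_neurons = 5, spec = spec, seed = 9)
  e2 <- simulate_experiment(n_neurons = 5, spec = spec, seed = 9)
  e3 <- simulate_experiment(n_neurons = 5, spec = spec, seed = 10)
  expect_identical(e1$recording$traces, e2$recording$traces)
  expect_false(identical(e1$recording$traces, e3$recording$traces))

  neu <- synth_neurons(2, seed = 1)
  neu$gain_hz <- 0
  neu$tone_gain_hz <- 0
  neu$baseline_hz <- 0
  neu$binaural_class <- "unresponsive"
  p <- sim_params_noise_free()
  e <- simulate_experiment(neurons = neu, spec = spec, params = p, seed = 2)
  for (j in 1:2)
    expect_equal(e$recording$traces[, j],
                 rep(neu$f0[j], nrow(e$recording$traces)))
})

test_that("a fully shared latent makes trial responses perfectly correlated", {
  spec <- stimulus_spec(abl_db = 60, n_noise_reps = 10, n_tone_freqs = 2,
                        n_tone_reps = 2)
  neu <- synth_neurons(2, seed = 3)
  neu$tuning_type <- "untuned"
  neu$binaural_class <- "EE/N"
  neu$gain_hz <- c(40, 60)
  neu$baseline_hz <- 0
  neu$noise_share <- 1
  p <- sim_params_noise_free(latent_sd = 0.2)
  e <- simulate_experiment(neurons = neu, spec = spec, params = p, seed = 4)
  proc <- quiet_process(e$recording, e$trials)
  tr <- proc$tensor$trials
  idx <- which(tr$stim_class == "binaural")
  r <- noise_correlation(proc$tensor$responses[1, idx],
                         proc$tensor$responses[2, idx], tr$ild_db[idx])
  expect_gt(r, 0.99)
})

test_that("doubling the response gain doubles the extracted response", {
  spec <- stimulus_spec(abl_db = 60, n_noise_reps = 3, n_tone_freqs = 2,
                        n_tone_reps = 2)
  p <- sim_params_noise_free()
  resp_for_gain <- function(g) {
    neu <- synth_neurons(1, seed = 5)
    neu$tuning_type <- "untuned"
    neu$binaural_class <- "EE/N"
    neu$baseline_hz <- 0
    neu$tone_gain_hz <- 0
    neu$gain_hz <- g
    e <- simulate_experiment(neurons = neu, spec = spec, params = p,
                             seed = 6)
    proc <- quiet_process(e$recording, e$trials)
    idx <- which(proc$tensor$trials$stim_class == "binaural")
    mean(proc$tensor$responses[1, idx])
  }
  # baseline estimation sits on the transient tails, so linearity holds
  # only up to a small kernel/baseline discretization tolerance
  r1 <- resp_for_gain(30)
  r2 <- resp_for_gain(60)
  expect_equal(r2 / r1, 2, tolerance = 0.1)
})

test_that("planted spatial structure shows up in positions, BFs and ILD maps", {
  neu <- synth_neurons(60, seed = 7)
  g <- plant_spatial_structure(neu, field_um = c(500, 500),
                               gradient = list(angle_deg = 30,
                                               oct_per_um = 0.004,
                                               bf_at_origin_hz = 40000,
                                               jitter_oct = 0),
                               seed = 8)
  th <- 30 * pi / 180
  proj <- g$x_um * cos(th) + g$y_um * sin(th)
  expect_equal(cor(log2(g$bf_hz), proj), -1)

  cl <- plant_spatial_structure(neu, field_um = c(500, 250),
                                clusters = list(
                                  centers = rbind(c(50, 125), c(450, 125)),
                                  values_db = c(-25, 25), spread_db = 2),
                                seed = 8)
  d <- as.matrix(dist(cbind(cl$x_um, cl$y_um)))
  pd <- abs(outer(cl$ild_peak_db, cl$ild_peak_db, "-"))
  up <- upper.tri(d)
  expect_lt(mean(pd[up & d <= 150]), mean(pd[up & d > 150]))

  expect_error(plant_spatial_structure(neu, field_um = c(250, 250),
                                       clusters = list(
                                         centers = rbind(c(400, 100)),
                                         values_db = 0, spread_db = 2)),
               "field extent")
})
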