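make_tuned_population <- function(n, ild, noise_sd = 0.6, seed = 1) {
  set.seed(seed)
  resp <- sapply(seq_len(n), function(j) {
    sgn <- sample(c(-1, 1), 1)
    sgn * ild / 60 + rnorm(length(ild), 0, noise_sd)
  })
  list(responses = resp,
       channel = ifelse(stats::cor(resp, ild)[, 1] < 0, "contra", "ipsi"))
}

test_that("population matrix rows are max-normalized with drops logged", {
  spec <- small_spec()
  e <- simulate_experiment(n_neurons = 8, spec = spec, seed = 13)
  proc <- quiet_process(e$recording, e$trials)
  pm <- population_matrix(proc$tensor)
  expect_equal(ncol(pm$matrix), 7 * 2)
  expect_true(all(abs(apply(pm$matrix, 1, max) - 1) < 1e-12))
  expect_equal(nrow(pm$matrix) + length(pm$excluded), 8)
})

test_that("PCA variance fractions behave and rank-1 populations load on PC1", {
  ild <- seq(-30, 30, 10)
  base <- rep(ild / 30, 3)
  set.seed(32)
  gains <- runif(20, 0.5, 2)
  m <- outer(gains, base)
  pca <- run_pca(m + rnorm(length(m), 0, 1e-9))
  expect_equal(sum(pca$var_explained), 1)
  expect_gt(pca$var_explained[1], 0.999)
  # two orthogonal motifs with equal power split the variance
  m1 <- rep(c(1, -1), length.out = 21)
  m2 <- rep(c(1, 1, -1, -1), length.out = 21)
  m2 <- m2 - mean(m2)
  m2 <- m2 - m1 * sum(m2 * m1) / sum(m1 ^ 2)  # orthogonalize
  m2 <- m2 / sqrt(sum(m2 ^ 2)) * sqrt(sum(m1 ^ 2))
  set.seed(33)
  load <- matrix(rnorm(200), 100, 2)
  pop <- load %*% rbind(m1, m2)
  pca <- run_pca(pop)
  expect_equal(pca$var_explained[1], 0.5, tolerance = 0.15)
  expect_equal(pca$var_explained[2], 0.5, tolerance = 0.15)
  expect_lt(sum(pca$var_explained[3:21]), 1e-12)
  # constant matrix flagged
  expect_true(run_pca(matrix(1, 5, 21))$constant)
})

test_that("channel assignment follows the regression slope sign", {
  ild <- rep(seq(-30, 30, 10), each = 12)
  a <- assign_channel(-ild, ild)
  expect_equal(a$slope, -1)
  expect_equal(a$sign, "contra")
  expect_true(a$monotonic)
  # step function high for contralateral ILDs
  set.seed(34)
  a <- assign_channel(as.numeric(ild <= 0) + rnorm(length(ild), 0, 0.1), ild)
  expect_lt(a$slope, 0)
  expect_equal(a$sign, "contra")
  # flat responses: no channel
  a <- assign_channel(rep(1, length(ild)), ild)
  expect_false(a$monotonic)
})

test_that("noiseless mirrored populations decode perfectly; confusion rows sum to 100", {
  ild <- rep(seq(-30, 30, 10), each = 12)
  A <- (30 - ild) / 60
  B <- (ild + 30) / 60
  res <- opponent_decode(cbind(A, B), ild, c("contra", "ipsi"))
  expect_equal(res$mue_db, 0)
  expect_equal(res$mue_normalized, 0)
  expect_equal(unname(rowSums(res$confusion)), rep(100, 7))
  expect_equal(res$predicted, ild)
})

test_that("decoder is invariant to positive per-neuron rescaling", {
  ild <- rep(seq(-30, 30, 10), each = 12)
  pop <- make_tuned_population(40, ild, seed = 35)
  r1 <- opponent_decode(pop$responses, ild, pop$channel)
  scaled <- sweep(pop$responses, 2, runif(40, 0.5, 5), `*`)
  r2 <- opponent_decode(scaled, ild, pop$channel)
  expect_equal(r1$predicted, r2$predicted)
  expect_equal(r1$mue_db, r2$mue_db)
})

test_that("leave-one-out discipline: leaking the decoded trial changes results", {
  # few repetitions so removing one trial visibly moves its reference
  ild <- rep(seq(-30, 30, 10), each = 4)
  pop <- make_tuned_population(10, ild, noise_sd = 1, seed = 36)
  loo <- opponent_decode(pop$responses, ild, pop$channel, loo = TRUE)
  leak <- opponent_decode(pop$responses, ild, pop$channel, loo = FALSE)
  expect_false(identical(loo$predicted, leak$predicted))
  expect_lte(leak$mue_db, loo$mue_db)  # leakage can only flatter
})

test_that("shuffling channel labels destroys most decodable information", {
  ild <- rep(seq(-30, 30, 10), each = 12)
  pop <- make_tuned_population(200, ild, seed = 37)
  correct <- opponent_decode(pop$responses, ild, pop$channel)$mue_db
  set.seed(38)
  shuffled <- opponent_decode(pop$responses, ild,
                              sample(pop$channel))$mue_db
  chance <- mean(abs(outer(seq(-30, 30, 10), seq(-30, 30, 10), `-`)))
  expect_lt(correct, 0.2 * chance)
  expect_gt(shuffled, 0.5 * chance)
})

test_that("decoder error falls with population size", {
  ild <- rep(seq(-30, 30, 10), each = 12)
  pop <- make_tuned_population(120, ild, noise_sd = 1, seed = 39)
  cur <- decoder_curve(pop$responses, ild, pop$channel,
                       sizes = c(10, 40, 120), n_rep = 40, seed = 40)
  expect_true(all(diff(cur$mue_db) <= cur$mue_sd[-nrow(cur)]))
  expect_lt(cur$mue_db[3], cur$mue_db[1])
  expect_true(all(cur$mue_normalized >= 0 & cur$mue_normalized <= 1))
  expect_error(decoder_curve(pop$responses, ild, pop$channel,
                             sizes = 500, n_rep = 2), "exceeds")
})
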