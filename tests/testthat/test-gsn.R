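test_that("training summary statistics match a brute-force covariance", {
  # hand oracle: two points (0,0), (2,2); deviations +/-1 each axis,
  # divisor n - 1 = 1 gives all covariance entries 4/2... brute force:
  X <- rbind(c(0, 0), c(2, 2))
  brute <- matrix(0, 2, 2)
  xbar <- colMeans(X)
  for (i in 1:2) brute <- brute +
      tcrossprod(X[i, ] - xbar) / (nrow(X) - 1)
  st <- init_hidden_state(X)
  expect_equal(st$x_star, c(1, 1))
  expect_equal(unname(st$M_star), brute)
  expect_equal(unname(brute), matrix(2, 2, 2))

  # identical vectors: zero covariance
  st0 <- init_hidden_state(rbind(c(3, 4), c(3, 4), c(3, 4)))
  expect_equal(unname(st0$M_star), matrix(0, 2, 2))
  expect_equal(st0$x_star, c(3, 4))

  # order invariance
  set.seed(1)
  Y <- matrix(rnorm(40), 10)
  st1 <- init_hidden_state(Y)
  st2 <- init_hidden_state(Y[sample(10), ])
  expect_equal(st1$x_star, st2$x_star)
  expect_equal(st1$M_star, st2$M_star)

  expect_error(init_hidden_state(matrix(1, 1, 3)), "at least 2")
})

test_that("corruption has the configured scale and a zero-scale identity", {
  x <- c(1, -2, 0.5)
  expect_identical(corrupt(x, 0), x)
  expect_error(corrupt(x, -1), "scale")
  set.seed(3)
  draws <- replicate(10000, corrupt(0, 0.7))
  # chi-square interval for the sample sd at n = 10000
  se <- 0.7 / sqrt(2 * (10000 - 1))
  expect_lt(abs(stats::sd(draws) - 0.7), 3 * se)
  # heavy-tailed family has unit-variance scaling too
  set.seed(4)
  tdraws <- replicate(10000, corrupt(0, 0.7, family = "t"))
  expect_lt(abs(stats::sd(tdraws) - 0.7), 0.1)
  # reproducible under seed
  set.seed(9); a <- corrupt(x, 1)
  set.seed(9); b <- corrupt(x, 1)
  expect_identical(a, b)
})

test_that("a DAE with zero corruption learns the identity on a small set", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  fit <- dae_train_layer(X, width = 9, corruption_sd = 0,
                         epochs = 400, learning_rate = 0.05,
                         batch_size = 5, seed = 2)
  expect_lt(fit$loss[length(fit$loss)], 1e-3 * mean(apply(X, 2, var)))
})

test_that("DAE training is seed-deterministic and its loss settles", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  f1 <- dae_train_layer(X, width = 10, epochs = 60, seed = 5)
  f2 <- dae_train_layer(X, width = 10, epochs = 60, seed = 5)
  expect_identical(f1$layer, f2$layer)
  # later epochs do not climb above earlier ones beyond 1% of the
  # initial loss
  tol <- 0.01 * f1$loss[1]
  late <- f1$loss[seq(11, 60)]
  early <- f1$loss[seq(1, 50)]
  expect_true(all(late <= early + tol))
})

test_that("hidden-width draws respect the [2d, 5d] range and config validation", {
  cfg <- gsn_config(d = 10, r = 2, seed = 3)
  expect_gte(cfg$widths[1], 20); expect_lte(cfg$widths[1], 50)
  expect_gte(cfg$widths[2], 2 * cfg$widths[1])
  expect_lte(cfg$widths[2], 5 * cfg$widths[1])
  expect_error(gsn_config(d = 10, r = 1, widths = 5), "2d, 5d")
  expect_error(gsn_config(d = 10, chain_steps = 5, burn_in = 10),
               "burn_in")
})

test_that("the transition operator preserves the moments of a Gaussian target", {
  set.seed(42)
  n <- 2000
  Sig <- matrix(c(1, 0.21, 0.21, 0.49), 2)
  X <- sweep(matrix(rnorm(n * 2), n) %*% chol(Sig), 2, c(1, 2), "+")
  cfg <- gsn_config(d = 2, r = 1, epochs = 200, seed = 7)
  m <- gsn(X, cfg)
  S <- simulate(m, nsim = 24000, seed = 11, n_chains = 48, burn_in = 60)
  # per-chain spread gives the Monte-Carlo s.e. of the chain moments
  chain_id <- rep_len(seq_len(48), nrow(S))
  for (j in 1:2) {
    mu_c <- tapply(S[, j], chain_id, mean)
    se <- sqrt(stats::var(mu_c) / 48 + stats::var(X[, j]) / n)
    expect_lt(abs(mean(S[, j]) - mean(X[, j])), 3 * se)
    v_c <- tapply(S[, j], chain_id, stats::var)
    se_v <- sqrt(stats::var(v_c) / 48 + 2 * stats::var(X[, j])^2 / n)
    expect_lt(abs(stats::var(S[, j]) - stats::var(X[, j])), 3 * se_v)
  }
  # two sampling seeds agree post burn-in (stationarity)
  S2 <- simulate(m, nsim = 24000, seed = 12, n_chains = 48, burn_in = 60)
  expect_lt(max(abs(colMeans(S2) - colMeans(S))), 0.1)

  # burn_in = steps - 1 retains exactly one sample per chain
  set.seed(1)
  one <- run_chain(m, matrix(m$x_star, 1), steps = 5, burn_in = 4)
  expect_identical(nrow(one), 1L)
})

test_that("gsn fitting is deterministic under a fixed seed", {
  ds <- planted_dataset(n = 120)
  cfg <- gsn_config(d = ncol(ds$X), epochs = 15, seed = 4,
                    calibration_rounds = 1, calibration_chains = 16,
                    calibration_keep = 20)
  m1 <- gsn(ds, cfg)
  m2 <- gsn(ds, cfg)
  expect_identical(m1$layers, m2$layers)
  p1 <- predict(m1, ds_subset(ds, 1:10), seed = 6)
  p2 <- predict(m1, ds_subset(ds, 1:10), seed = 6)
  expect_identical(p1, p2)
})

test_that("clamped prediction recovers a constant category and tracks planted effects", {
  # degenerate target: one category constantly +1
  sp <- cohort_spec(300, effect_matrix = matrix(0, 15, 14),
                    intercepts = c(100, rep(0, 13)), noise_sd = 1e-6,
                    thresholds = c(-3.4, -2.6, 2.6, 3.4), seed = 2)
  ds <- make_cohort(sp)
  expect_true(all(ds$X[, ds$blocks$R[1]] == 2))
  cfg <- gsn_config(d = ncol(ds$X), epochs = 40, seed = 3,
                    calibration_rounds = 1, calibration_chains = 16,
                    calibration_keep = 20)
  m <- gsn(ds, cfg)
  pred <- predict(m, ds_subset(ds, 1:20), seed = 5)
  expect_lt(max(abs(pred[, 1] - 2)), 0.35)

  # planted-effect cohort: predictions correlate with the generating
  # latent means
  ds2 <- planted_dataset(n = 1000, strength = 3, noise_sd = 0.3,
                         seed = 5)
  sp2 <- cohort_spec(1000, effect_matrix = example_effect_matrix(3),
                     noise_sd = 0.3, seed = 5)
  cfg2 <- gsn_config(d = ncol(ds2$X), epochs = 60, seed = 2,
                     calibration_rounds = 1, calibration_chains = 32,
                     calibration_keep = 40)
  m2 <- gsn(ds2, cfg2)
  pred2 <- predict(m2, ds2, seed = 3)
  G <- ds2$X[, ds2$blocks$G]
  lat <- G %*% sp2$effect_matrix +
    matrix(sp2$intercepts, nrow(G), 14, byrow = TRUE)
  cors <- vapply(1:14, function(j) stats::cor(pred2[, j], lat[, j]),
                 numeric(1))
  expect_gte(mean(cors), 0.8)
  # ordinal output respects the grade range
  ord <- predict(m2, ds_subset(ds2, 1:50), type = "ordinal", seed = 3)
  expect_true(all(ord >= -2 & ord <= 2))
  expect_true(all(ord == round(ord)))
})

test_that("models serialize to JSON and back without changing predictions", {
  ds <- planted_dataset(n = 120)
  cfg <- gsn_config(d = ncol(ds$X), epochs = 10, seed = 4,
                    calibration_rounds = 0)
  m <- gsn(ds, cfg)
  p <- withr::local_tempfile(fileext = ".json")
  write_gsn(m, p)
  m2 <- read_gsn(p)
  q <- ds_subset(ds, 1:5)
  expect_equal(predict(m2, q, seed = 8), predict(m, q, seed = 8),
               tolerance = 1e-12)
})

test_that("untrained or mismatched inputs produce clear errors", {
  ds <- planted_dataset(n = 50)
  set.seed(1)
  toy <- gsn(matrix(rnorm(100), 50, 2),
             gsn_config(d = 2, epochs = 5, seed = 1,
                        calibration_rounds = 0))
  expect_error(predict(toy, ds), "blocks")
  cfg <- gsn_config(d = 5, epochs = 5, seed = 1)
  expect_error(gsn(ds, cfg), "d = ")
})
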