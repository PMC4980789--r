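test_that("degenerate frequency triples produce constant genotypes", {
  freqs <- lapply(table1_freqs(), function(p) c(wt = 1, het = 0, hom = 0))
  sp <- cohort_spec(25, genotype_freqs = freqs, seed = 2)
  geno <- sample_genotypes(sp)
  for (lc in cyp_loci())
    expect_true(all(geno[[lc]] == genotype_labels()[[lc]][1]))
})

test_that("generator is a pure function of (spec, seed)", {
  sp <- cohort_spec(60, effect_matrix = example_effect_matrix(1),
                    seed = 33)
  c1 <- make_cohort(sp, as = "cohort")
  c2 <- make_cohort(sp, as = "cohort")
  expect_identical(c1, c2)
  c3 <- make_cohort(cohort_spec(60,
                                effect_matrix = example_effect_matrix(1),
                                seed = 34), as = "cohort")
  expect_false(identical(c1, c3))
})

test_that("empirical genotype marginals match the spec frequencies at n = 10000", {
  sp <- cohort_spec(10000, seed = 12)
  geno <- sample_genotypes(sp)
  for (lc in cyp_loci()) {
    p <- sp$genotype_freqs[[lc]]
    labs <- genotype_labels()[[lc]]
    for (s in 1:3) {
      if (p[s] %in% c(0, 1)) next
      phat <- mean(geno[[lc]] == labs[s])
      se <- sqrt(p[s] * (1 - p[s]) / 10000)
      expect_lt(abs(phat - p[s]), 3 * se)
    }
  }
  # the variant-homozygote fraction at CYP2D6*10 specifically
  p_tt <- sp$genotype_freqs[["CYP2D6*10"]]["hom"]
  expect_lt(abs(mean(geno[["CYP2D6*10"]] == "TT") - p_tt),
            3 * sqrt(p_tt * (1 - p_tt) / 10000))
})

test_that("null effect model with tight central bin yields all-zero ADRs", {
  sp <- cohort_spec(30, effect_matrix = matrix(0, 15, 14),
                    intercepts = rep(0, 14), noise_sd = 0,
                    thresholds = c(-2, -1, 1, 2), seed = 3)
  adr <- sample_adrs(sample_genotypes(sp), sp)
  expect_true(all(adr == 0L))
})

test_that("intercepts calibrated by the Gaussian tail oracle hit target prevalences", {
  targets <- as.numeric(table2_counts()) / 83
  thr <- c(-3.4, -2.6, 2.6, 3.4)
  b <- vapply(targets, prevalence_to_intercept, numeric(1),
              thresholds = thr, noise_sd = 1)
  # closed-form check: forward map returns the target
  expect_equal(vapply(b, nonzero_prevalence, numeric(1),
                      thresholds = thr, noise_sd = 1),
               targets, tolerance = 1e-8)
  # empirical check at n = 10000 under the null effect matrix
  sp <- cohort_spec(10000, intercepts = b, thresholds = thr,
                    noise_sd = 1, seed = 21)
  adr <- sample_adrs(sample_genotypes(sp), sp)
  rate <- colMeans(adr != 0)
  for (j in seq_len(14)) {
    se <- sqrt(targets[j] * (1 - targets[j]) / 10000)
    expect_lt(abs(rate[j] - targets[j]), 3 * se)
  }
})

test_that("a strong planted effect saturates the top grade in the noiseless limit", {
  W <- matrix(0, 15, 14)
  W[1, 1] <- 100  # CYP2D6*2 wild-hom dummy -> category 1
  sp <- cohort_spec(200, effect_matrix = W, intercepts = rep(0, 14),
                    noise_sd = 0, seed = 4)
  geno <- sample_genotypes(sp)
  adr <- sample_adrs(geno, sp)
  carriers <- geno[["CYP2D6*2"]] == "CC"
  expect_true(all(adr[carriers, 1] == 2L))
  expect_true(all(adr[!carriers, 1] == 0L))
})

test_that("least-squares on the generating dummies recovers planted effects", {
  W <- example_effect_matrix(2)
  # genotype missingness breaks the per-locus sum-to-one collinearity of
  # the dummy triples, making every informative column identifiable
  sp <- cohort_spec(2000, effect_matrix = W, noise_sd = 0.1,
                    missing_rate_genotype = 0.15, seed = 8)
  ds <- make_cohort(sp)
  G <- ds$X[, ds$blocks$G]
  R <- ds$X[, ds$blocks$R]
  keep <- which(apply(G, 2, stats::sd) > 0)
  agree <- 0; total <- 0
  for (j in seq_len(14)) {
    fit <- stats::lm.fit(cbind(1, G[, keep]), R[, j])
    est <- fit$coefficients[-1]
    big <- abs(W[keep, j]) >= 1
    total <- total + sum(big)
    agree <- agree + sum(sign(est[big]) == sign(W[keep, j][big]))
  }
  expect_gte(agree / total, 0.95)
})

test_that("fixture cohort reproduces the published margins exactly", {
  fx <- fixture_cohort()
  expect_identical(nrow(fx), 83L)
  # per-locus typed counts
  typed <- vapply(cyp_loci(), function(lc) sum(fx[[lc]] != ""),
                  integer(1))
  expect_identical(unname(typed), c(74L, 83L, 0L, 66L, 77L))
  expect_identical(sum(fx[["CYP1A2*1F"]] == "CC"), 33L)
  # ADR margins: 53 reports distributed per category
  nz <- as.integer(colSums(fx[, adr_categories()] != 0))
  expect_identical(nz, unname(table2_counts()))
  expect_identical(sum(nz), 53L)
  # deterministic
  expect_identical(fx, fixture_cohort())
})

test_that("cohort specs with invalid parameters are rejected before sampling", {
  expect_error(cohort_spec(10, genotype_freqs = {
    f <- table1_freqs(); f[["CYP2D6*2"]] <- c(0.5, 0.2, 0.2); f
  }), "summing to 1")
  expect_error(cohort_spec(10, thresholds = c(-1, 1, 0.5, 2)),
               "increasing")
  expect_error(cohort_spec(10, noise_sd = -1), "non-negative")
  expect_error(cohort_spec(10, effect_matrix = matrix(0, 3, 3)),
               "15 x 14")
})

test_that("empty cohorts are valid and round-trip", {
  sp <- cohort_spec(0, seed = 1)
  ds <- make_cohort(sp)
  expect_identical(n_samples(ds), 0L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(make_cohort(sp, as = "cohort"), p)
  expect_identical(nrow(read_cohort(p)), 0L)
})
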