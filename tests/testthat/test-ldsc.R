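test_that("ldsc regression recovers exact lines and degenerate responses", {
  M <- 100
  ell <- seq(1, 50, length.out = M)
  blocks <- rep(1:10, each = 10)

  # noiseless line: slope and intercept recovered exactly
  y <- 1 + 1000 * 0.5 * ell / M
  f <- ldsc_regression(y, ell, n_scale = 1000, M = M, blocks = blocks)
  expect_equal(f$slope, 0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  # every delete-one-block re-estimate sits on the same line
  expect_true(all(abs(f$loo[, "slope"] - 0.5) < 1e-8))
  expect_equal(f$se, 0, tolerance = 1e-8)

  # flat response: slope 0, intercept 1
  f0 <- ldsc_regression(rep(1, M), ell, 1000, M, blocks)
  expect_equal(f0$slope, 0, tolerance = 1e-10)
  expect_equal(f0$intercept, 1, tolerance = 1e-10)

  # fixed intercept variant
  ff <- ldsc_regression(y, ell, 1000, M, blocks, fix_intercept = 1)
  expect_equal(ff$slope, 0.5, tolerance = 1e-10)

  expect_error(ldsc_regression(y, rep(2, M), 1000, M, blocks),
               "rank deficient")
  expect_error(ldsc_regression(y, ell, 1000, M, rep(1, M)), "blocks")
})

test_that("delete-one-block jackknife of a plain mean equals s^2/b exactly", {
  # algebraic identity: with b equal blocks, the delete-one jackknife
  # variance of the grand mean equals var(block means)/b
  set.seed(77)
  b <- 25; per <- 8
  x <- rnorm(b * per)
  g <- rep(seq_len(b), each = per)
  loo <- vapply(seq_len(b), function(i) mean(x[g != i]), 0)
  vjack <- (b - 1) / b * sum((loo - mean(loo))^2)
  bm <- tapply(x, g, mean)
  expect_equal(vjack, stats::var(as.numeric(bm)) / b, tolerance = 1e-12)
})

test_that("liability conversion matches its closed form", {
  # K = P = 0.5: factor is exactly pi/2
  expect_equal(liability_factor(0.5, 0.5), pi / 2, tolerance = 1e-9)
  # against a direct numeric evaluation of the normal density form
  K <- 0.02; P <- 0.5
  expect_equal(liability_factor(K, P),
               K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(qnorm(1 - K))^2),
               tolerance = 1e-12)
  # continuous traits are untouched
  expect_equal(liability_conversion(0.37, NULL, NULL), 0.37)
  # one binary, one continuous: multiply by sqrt(c_binary)
  expect_equal(liability_conversion(0.2, list(K = 0.1, P = 0.5), NULL),
               0.2 * sqrt(liability_factor(0.1, 0.5)))
  expect_error(liability_factor(0, 0.5), "strictly inside")
})

test_that("univariate heritability is recovered across replicates", {
  reps <- 25
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- battery_config(
      list(sim_trait("t", "continuous", h2 = 0.4, n_total = 2000),
           sim_trait("u", "continuous", h2 = 0.4, n_total = 2000)),
      Rg = diag(2), M = 2000, seed = 600 + r)
    sim <- simulate_battery(cfg)
    gc <- multivariable_ldsc(sim$sumstats, sim$ld, meta_from_config(cfg))
    est[r] <- gc$S[1, 1]
  }
  expect_lt(abs(mean(est) - 0.4), 3 * stats::sd(est) / sqrt(reps))
})

test_that("multivariable LDSC produces a PSD sampling covariance and coherent structure", {
  cfg <- preset_battery(n_external = 1, M = 2000, seed = 21)
  sim <- simulate_battery(cfg)
  gc <- multivariable_ldsc(sim$sumstats, sim$ld, meta_from_config(cfg))
  expect_s3_class(gc, "gcov")
  expect_equal(dim(gc$V), c(15, 15))
  expect_true(all(eigen(gc$V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10 * max(abs(gc$V))))
  expect_equal(gc$S, t(gc$S))
  expect_true(all(diag(gc$V) >= 0))
  # vech bookkeeping: replicate archive columns follow lower-triangle
  # column order shared with V
  expect_equal(ncol(gc$replicates), 15)
  expect_equal(unname(gc$S[2, 1]),
               mean(gc$replicates[, vech_index(2, 1, 5)]),
               tolerance = 0.05)
})

test_that("identical input tables give unit genetic correlation", {
  cfg <- battery_config(
    list(sim_trait("t", "continuous", h2 = 0.4, n_total = 5000),
         sim_trait("u", "continuous", h2 = 0.4, n_total = 5000)),
    Rg = diag(2), M = 1000, seed = 3)
  sim <- simulate_battery(cfg)
  tabs <- list(t1 = sim$sumstats$t, t2 = sim$sumstats$t)
  meta <- data.frame(name = c("t1", "t2"), binary = FALSE, K = NA)
  gc <- multivariable_ldsc(tabs, sim$ld, meta)
  expect_equal(gc$S[1, 2], gc$S[1, 1], tolerance = 1e-10)
  gs <- standardize(gc)
  expect_equal(gs$S[1, 2], 1, tolerance = 1e-10)
  # jackknife replicates of a constant ratio are constant: zero variance
  expect_equal(gs$V[vech_index(2, 1, 2), vech_index(2, 1, 2)], 0,
               tolerance = 1e-12)
})

test_that("standardization is idempotent and matches the definition", {
  cfg <- battery_config(
    list(sim_trait("a", "continuous", h2 = 0.3, n_total = 5000),
         sim_trait("b", "continuous", h2 = 0.3, n_total = 5000)),
    Rg = matrix(c(1, .6, .6, 1), 2, 2), M = 1000, seed = 12)
  sim <- simulate_battery(cfg)
  gc <- multivariable_ldsc(sim$sumstats, sim$ld, meta_from_config(cfg))
  gs <- standardize(gc)
  expect_equal(gs$S[2, 1], gc$S[2, 1] / sqrt(gc$S[1, 1] * gc$S[2, 2]),
               tolerance = 1e-12)
  expect_identical(standardize(gs), gs)        # already on correlation scale
  expect_true(all(diag(gs$S) == 1))
  # unit diagonal carries no sampling variance
  dpos <- vech_index(1:2, 1:2, 2)
  expect_true(all(gs$V[dpos, ] == 0) && all(gs$V[, dpos] == 0))
})

test_that("allele coding of an input trait does not move the estimates", {
  cfg <- null_equality_config(seed = 91)
  sim <- simulate_battery(cfg)
  munged <- lapply(sim$sumstats, function(s) munge(s, sim$registry)$sumstats)
  gc1 <- multivariable_ldsc(munged, sim$ld, meta_from_config(cfg))

  flip <- sim$sumstats
  flip$A <- transform(flip$A, A1 = A2, A2 = A1, Z = -Z)
  munged2 <- lapply(flip, function(s) munge(s, sim$registry)$sumstats)
  gc2 <- multivariable_ldsc(munged2, sim$ld, meta_from_config(cfg))
  expect_equal(gc1$S, gc2$S, tolerance = 1e-12)
  expect_equal(gc1$V, gc2$V, tolerance = 1e-12)
})

test_that("jackknife standard errors are calibrated against the empirical spread", {
  # null genetic correlation: over replicates the SD of the standardized
  # estimate should match the mean jackknife SE
  reps <- 100
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- battery_config(
      list(sim_trait("a", "continuous", h2 = 0.3, n_total = 20000),
           sim_trait("b", "continuous", h2 = 0.3, n_total = 20000)),
      Rg = diag(2), M = 2000, seed = 4000 + r)
    sim <- simulate_battery(cfg)
    gs <- standardize(multivariable_ldsc(sim$sumstats, sim$ld,
                                         meta_from_config(cfg)))
    pos <- vech_index(2, 1, 2)
    est[r] <- gs$S[2, 1]
    se[r] <- sqrt(gs$V[pos, pos])
  }
  expect_lt(abs(stats::sd(est) / mean(se) - 1), 0.25)
})
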