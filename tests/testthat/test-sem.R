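# A small well-conditioned correlation structure with a synthetic sampling
# covariance, used where a full simulation is unnecessary.
toy_rv <- function(rho = c(0.5, 0.2, 0.4), d = 0.01, k = 3) {
  R <- diag(k)
  R[lower.tri(R)] <- rho
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  dimnames(R) <- list(LETTERS[1:k], LETTERS[1:k])
  p <- k * (k + 1) / 2
  V <- diag(rep(d, p))
  dpos <- vech_index(1:k, 1:k, k)
  V[dpos, dpos] <- 0
  list(R = R, V = V)
}

test_that("a just-identified model reproduces the observed correlation", {
  tv <- toy_rv()
  spec <- model_spec(c("A", "B"), correlations = list(c("A", "B")))
  fit <- fit_dwls(spec, tv$R[1:2, 1:2], tv$V[c(1, 2, 4), c(1, 2, 4)])
  expect_equal(unname(fit$theta), 0.5, tolerance = 1e-9)
  expect_equal(fit$df, 0L)
  expect_equal(fit$fitval, 0, tolerance = 1e-12)
  expect_equal(fit$chisq, 0)
  expect_equal(fit$p, 1)
  expect_equal(residual_chisq(fit), list(chisq = 0, df = 0L, p = 1))
})

test_that("equality-constrained DWLS with equal weights averages the correlations", {
  # two modeled correlations r(A,C)=0.2, r(B,C)=0.4 constrained equal,
  # equal diagonal weights: the minimizer is their mean 0.3
  tv <- toy_rv(rho = c(0.5, 0.2, 0.4))
  spec <- model_spec(c("A", "B", "C"),
                     correlations = list(c("A", "C"), c("B", "C")),
                     equality = list(c("r_A_C", "r_B_C")))
  fit <- fit_dwls(spec, tv$R, tv$V)
  expect_equal(unname(fit$theta), 0.3, tolerance = 1e-8)
  expect_equal(fit$df, 1L)
  expect_gt(fit$chisq, 0)
})

test_that("one-factor DWLS reproduces the triad closed form", {
  # off-diagonals (0.56, 0.42, 0.48) factor exactly into loadings
  # (0.7, 0.8, 0.6): lambda_1 = sqrt(r12 r13 / r23), cyclically
  r12 <- 0.56; r13 <- 0.42; r23 <- 0.48
  lam_oracle <- c(sqrt(r12 * r13 / r23), sqrt(r12 * r23 / r13),
                  sqrt(r13 * r23 / r12))
  expect_equal(lam_oracle, c(0.7, 0.8, 0.6), tolerance = 1e-12)

  tv <- toy_rv(rho = c(r12, r13, r23))
  spec <- model_spec(c("A", "B", "C"),
                     factor_indicators = c("A", "B", "C"))
  fit <- fit_dwls(spec, tv$R, tv$V)
  expect_equal(unname(fit$theta[c("l_A", "l_B", "l_C")]), lam_oracle,
               tolerance = 1e-6)
  expect_equal(fit$df, 0L)
})

test_that("degrees of freedom account for every modeled element, and nesting is monotone", {
  tv <- toy_rv()
  sat <- model_spec(c("A", "B", "C"),
                    correlations = list(c("A", "B"), c("A", "C"), c("B", "C")))
  con <- model_spec(c("A", "B", "C"),
                    correlations = list(c("A", "B"), c("A", "C"), c("B", "C")),
                    equality = list(c("r_A_C", "r_B_C")))
  f_sat <- fit_dwls(sat, tv$R, tv$V)
  f_con <- fit_dwls(con, tv$R, tv$V)
  expect_equal(nrow(sat$elements), sat$n_free + f_sat$df)
  expect_equal(nrow(con$elements), con$n_free + f_con$df)
  expect_gte(f_con$fitval, f_sat$fitval)       # nested-model monotonicity
  expect_equal(f_sat$fitval, 0, tolerance = 1e-12)

  fac <- model_spec(c("A", "B", "C", "D"),
                    factor_indicators = c("A", "B", "C"),
                    factor_targets = "D")
  tv4 <- toy_rv(rho = c(.56, .42, .21, .48, .24, .18), k = 4)
  f_fac <- fit_dwls(fac, tv4$R, tv4$V)
  expect_equal(nrow(fac$elements), fac$n_free + f_fac$df)
})

test_that("fit statistics are invariant to variable relabeling", {
  tv <- toy_rv(rho = c(0.5, 0.2, 0.4), d = 0.02)
  spec1 <- model_spec(c("A", "B", "C"),
                      correlations = list(c("A", "B"), c("A", "C"), c("B", "C")),
                      equality = list(c("r_A_C", "r_B_C")))
  f1 <- fit_dwls(spec1, tv$R, tv$V)

  perm <- c(2, 1, 3)                           # swap A and B
  Rp <- tv$R[perm, perm]
  k <- 3
  vmap <- outer(seq_len(k), seq_len(k), function(i, j)
    vech_index(perm[i], perm[j], k))
  sel <- which(lower.tri(diag(k), diag = TRUE))
  old <- vmap[sel]
  Vp <- tv$V[old, old]
  spec2 <- model_spec(c("B", "A", "C"),
                      correlations = list(c("B", "A"), c("B", "C"), c("A", "C")),
                      equality = list(c("r_B_C", "r_A_C")))
  f2 <- fit_dwls(spec2, Rp, Vp)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-8)
  expect_equal(f1$fitval, f2$fitval, tolerance = 1e-10)
  expect_equal(f1$df, f2$df)
})

test_that("the Wald equality contrast follows its closed form", {
  tv <- toy_rv(rho = c(0.5, 0.38, 0.12), d = 0.01)
  w <- wald_equality_test(tv$R, tv$V, c("A", "C"), c("B", "C"))
  expect_equal(w$chisq, (0.38 - 0.12)^2 / 0.02, tolerance = 1e-12)
  expect_equal(w$chisq, 3.38, tolerance = 1e-12)
  expect_equal(w$df, 1L)

  # null contrast
  tv0 <- toy_rv(rho = c(0.5, 0.3, 0.3))
  w0 <- wald_equality_test(tv0$R, tv0$V, c("A", "C"), c("B", "C"))
  expect_equal(w0$chisq, 0)
  expect_equal(w0$p, 1)

  # scale invariance: doubling correlations, quadrupling V
  tv2 <- toy_rv(rho = c(0.5, 0.76, 0.24), d = 0.04)
  w2 <- wald_equality_test(tv2$R, tv2$V, c("A", "C"), c("B", "C"))
  expect_equal(w2$chisq, w$chisq, tolerance = 1e-12)

  # degenerate contrast refused
  Vbad <- tv$V
  Vbad[3, 3] <- Vbad[5, 5] <- 0     # the two stratum-trait vech positions
  expect_error(wald_equality_test(tv$R, Vbad, c("A", "C"), c("B", "C")),
               "degenerate")
})

test_that("Wald and residual chi-square agree on 1-df constraints from simulation", {
  cfg <- null_equality_config(seed = 130, r_ext = 0.25)
  gs <- run_to_correlations(cfg)
  cmp <- battery_compare(gs, "A", "B", "T1")
  expect_equal(cmp$df, 1L)
  rel <- abs(cmp$chisq_diff - cmp$chisq_wald) /
    max(cmp$chisq_wald, .Machine$double.eps)
  expect_lt(rel, 0.10)
})

test_that("genetic multiple regression matches the direct linear solve", {
  tv <- toy_rv(rho = c(0.5, 0.3, 0.4))  # r(A,B)=.5, rxy=(.3,.4)
  g <- genetic_multiple_regression(tv$R, tv$V, outcome = "C",
                                   predictors = c("A", "B"))
  # hand-computed 2x2 solve: beta1=(r1y - r12 r2y)/(1-r12^2)
  expect_equal(unname(g$beta),
               c((0.3 - 0.5 * 0.4) / 0.75, (0.4 - 0.5 * 0.3) / 0.75),
               tolerance = 1e-10)
  expect_equal(unname(g$beta), c(0.13333333, 0.33333333), tolerance = 1e-7)
  expect_true(all(g$se > 0))

  # orthogonal predictors: partial effects equal the marginals
  tv0 <- toy_rv(rho = c(0, 0.3, 0.4))
  g0 <- genetic_multiple_regression(tv0$R, tv0$V, "C", c("A", "B"))
  expect_equal(unname(g0$beta), c(0.3, 0.4), tolerance = 1e-10)

  # near-collinear predictors refused with the pair named
  tvc <- toy_rv(rho = c(0.99, 0.3, 0.31))
  expect_error(genetic_multiple_regression(tvc$R, tvc$V, "C", c("A", "B")),
               "collinear.*A.*B")
})

test_that("factor residualization leaves unrelated targets untouched", {
  # indicators load on a factor; the two targets are uncorrelated with all
  # indicators, so the factor paths vanish and the residual association
  # equals the raw correlation
  lam <- c(0.7, 0.8, 0.6)
  k <- 5
  R <- diag(k)
  R[1:3, 1:3] <- outer(lam, lam); diag(R) <- 1
  R[4, 5] <- R[5, 4] <- 0.35
  dimnames(R) <- list(c("I1", "I2", "I3", "T1", "T2"),
                      c("I1", "I2", "I3", "T1", "T2"))
  p <- k * (k + 1) / 2
  V <- diag(rep(0.005, p))
  dpos <- vech_index(1:k, 1:k, k)
  V[dpos, dpos] <- 0
  fit <- factor_residual_model(R, V, indicators = c("I1", "I2", "I3"),
                               targets = c("T1", "T2"))
  expect_lt(max(abs(fit$paths$beta)), 1e-6)
  ra <- fit$residual_assoc
  expect_equal(ra$std[ra$t1 == "T1" & ra$t2 == "T2"], 0.35,
               tolerance = 1e-6)
  expect_equal(unname(fit$theta[c("l_I1", "l_I2", "l_I3")]), lam,
               tolerance = 1e-6)
})

test_that("fully factor-mediated target correlations vanish after adjustment", {
  # generating model: both targets correlate only through the factor, so
  # the residual covariance is 0 and the paths match the generating values
  lam <- c(0.7, 0.8, 0.6)
  b <- c(0.57, 0.13)
  f <- c(lam, b)
  R <- outer(f, f); diag(R) <- 1
  nm <- c("I1", "I2", "I3", "T1", "T2")
  dimnames(R) <- list(nm, nm)
  p <- 15
  V <- diag(rep(0.004, p))
  dpos <- vech_index(1:5, 1:5, 5)
  V[dpos, dpos] <- 0
  fit <- factor_residual_model(R, V, indicators = c("I1", "I2", "I3"),
                               targets = c("T1", "T2"))
  expect_equal(fit$paths$beta, b, tolerance = 1e-6)
  expect_lt(abs(fit$residual_assoc$std), 1e-6)
  expect_equal(fit$df, nrow(fit$spec$elements) - fit$spec$n_free)
})
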