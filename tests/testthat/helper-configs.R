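# Shared simulation configurations for the test suite.  All generator
# settings mirror the package's documented study conditions; tests only
# vary the seed.

# Two strata plus one external trait with identical generating
# correlations to both strata: the null of the equality test.
null_equality_config <- function(seed, r_ab = 0.8, r_ext = 0.3) {
  traits <- list(
    sim_trait("A", "binary", h2 = 0.2, K = 0.01,
              n_cases = 15000, n_controls = 20000),
    sim_trait("B", "binary", h2 = 0.2, K = 0.01,
              n_cases = 5000, n_controls = 19000),
    sim_trait("T1", "continuous", h2 = 0.3, n_total = 50000))
  Rg <- matrix(c(1, r_ab, r_ext,
                 r_ab, 1, r_ext,
                 r_ext, r_ext, 1), 3, 3)
  battery_config(traits, Rg, M = 2000, seed = seed)
}

# Complete-null battery: two strata with identical generating correlations
# to every external trait.
null_battery_config <- function(seed, n_external = 20) {
  traits <- c(
    list(sim_trait("A", "binary", h2 = 0.2, K = 0.01,
                   n_cases = 15000, n_controls = 20000),
         sim_trait("B", "binary", h2 = 0.2, K = 0.01,
                   n_cases = 5000, n_controls = 19000)),
    lapply(seq_len(n_external), function(i)
      sim_trait(sprintf("ext_%d", i), "continuous", h2 = 0.3,
                n_total = 50000)))
  k <- 2 + n_external
  Rg <- matrix(0.3, k, k)
  Rg[1, 2] <- Rg[2, 1] <- 0.8
  diag(Rg) <- 1
  battery_config(traits, Rg, M = 2000, seed = seed)
}

# Battery in which every stratum-external correlation difference is
# generated purely through differential loading on a common internalizing
# factor: loadings for three indicator disorders, factor->stratum paths
# 0.13 (early) and 0.57 (late), factor->external 0.7, plus a residual
# stratum-stratum covariance bringing r(early, late) to 0.42.
factor_mediated_config <- function(seed, n_external = 8,
                                   b_early = 0.13, b_late = 0.57,
                                   r_ext_factor = 0.7) {
  lam <- c(MDD = 0.80, ANX = 0.75, PTSD = 0.70)
  traits <- c(
    list(sim_trait("MDD", "binary", h2 = 0.09, K = 0.15,
                   n_cases = 50000, n_controls = 50000),
         sim_trait("ANX", "binary", h2 = 0.10, K = 0.10,
                   n_cases = 25000, n_controls = 25000),
         sim_trait("PTSD", "binary", h2 = 0.08, K = 0.07,
                   n_cases = 20000, n_controls = 20000),
         sim_trait("ASD_early", "binary", h2 = 0.2, K = 0.01,
                   n_cases = 16804, n_controls = 16804),
         sim_trait("ASD_late", "binary", h2 = 0.2, K = 0.01,
                   n_cases = 10888, n_controls = 10887)),
    lapply(seq_len(n_external), function(i)
      sim_trait(sprintf("ext_%d", i), "continuous", h2 = 0.3,
                n_total = 50000)))
  f <- c(lam, b_early, b_late, rep(r_ext_factor, n_external))
  Rg <- outer(f, f)
  diag(Rg) <- 1
  Rg[4, 5] <- Rg[5, 4] <- 0.42       # residual covariance 0.42 - b1*b2
  battery_config(traits, Rg, M = 2000, seed = seed)
}

# simulate -> munge -> multivariable LDSC -> standardized correlations
run_to_correlations <- function(cfg, n_blocks = 200) {
  sim <- simulate_battery(cfg)
  munged <- lapply(sim$sumstats, function(s) munge(s, sim$registry)$sumstats)
  standardize(multivariable_ldsc(munged, sim$ld, meta_from_config(cfg),
                                 n_blocks = n_blocks))
}

# Small handmade registry for munge unit tests.
toy_registry <- function() {
  data.frame(SNP = sprintf("rs%d", 1:8),
             A1 = c("A", "A", "T", "T", "A", "A", "T", "A"),
             A2 = c("G", "C", "G", "C", "G", "C", "G", "G"),
             CHR = c(1, 1, 1, 6, 6, 2, 2, 2),
             BP = c(100, 200, 300, 27e6, 100, 50, 60, 70),
             stringsAsFactors = FALSE)
}
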