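# Synthetic GWAS summary statistics under the LD-score regression
# generative model.  Simulation happens at the z-score level: for SNP j the
# vector of z-statistics across traits is multivariate normal with
#   Sigma_j[k,l] = sqrt(N_k N_l) * covg[k,l] * l_j / M + I[k,l]
# where covg is the observed-scale genetic covariance, l_j the LD score and
# I the intercept matrix (unit diagonal; off-diagonal terms induced by
# participant sample overlap).  This is exactly the estimand of cross-trait
# LDSC, so the generator doubles as the reference model for every
# downstream recovery test.

#' Declare one simulated trait
#'
#' @param name trait label.
#' @param measurement `"binary"` or `"continuous"`.
#' @param h2 SNP heritability in \[0,1\] (liability scale for binary traits).
#' @param K population prevalence in (0,1); binary traits only.
#' @param n_cases,n_controls case/control counts; binary traits only.
#' @param n_total total sample size; continuous traits only.
#' @return object of class `sim_trait`.
#' @export
sim_trait <- function(name, measurement = c("binary", "continuous"),
                      h2, K = NULL, n_cases = NULL, n_controls = NULL,
                      n_total = NULL) {
  measurement <- match.arg(measurement)
  if (!is.numeric(h2) || h2 < 0 || h2 > 1)
    stopf("h2 must lie in [0,1] (trait '%s')", name)
  if (measurement == "binary") {
    if (is.null(K) || is.null(n_cases) || is.null(n_controls))
      stopf("binary trait '%s' needs K, n_cases and n_controls", name)
    if (K <= 0 || K >= 1) stopf("K must lie in (0,1) (trait '%s')", name)
    if (n_cases <= 0 || n_controls <= 0)
      stopf("case/control counts must be positive (trait '%s')", name)
  } else {
    if (is.null(n_total) || n_total <= 0)
      stopf("continuous trait '%s' needs a positive n_total", name)
  }
  structure(list(name = name, measurement = measurement, h2 = h2, K = K,
                 n_cases = n_cases, n_controls = n_controls,
                 n_total = n_total),
            class = "sim_trait")
}

# Regression sample size: effective N for case-control, total N otherwise.
trait_n <- function(tr) {
  if (tr$measurement == "binary")
    effective_sample_size(tr$n_cases, tr$n_controls)
  else tr$n_total
}

# Observed-scale h2 under the effective-N convention: the liability
# conversion is evaluated at sample prevalence 0.5, so dividing by the same
# factor here makes the simulate -> estimate -> convert round trip exact.
trait_h2_obs <- function(tr) {
  if (tr$measurement == "binary")
    tr$h2 / liability_factor(tr$K, 0.5)
  else tr$h2
}

#' Configure a simulated GWAS battery
#'
#' @param traits list of [sim_trait()] objects.
#' @param Rg symmetric genetic correlation matrix with unit diagonal
#'   (positive semidefinite; entries in \[-1,1\]).
#' @param overlap symmetric matrix whose (k,l) entry is the product of the
#'   shared-participant count and the phenotypic correlation for the pair;
#'   drives nonzero cross-trait LDSC intercepts.  Defaults to no overlap.
#' @param M number of SNPs (at least 200).
#' @param n_chromosome_blocks contiguous SNP blocks (synthetic chromosomes);
#'   matches the block jackknife granularity downstream.
#' @param seed integer seed.
#' @param ld_shape LD-score distribution: `list(mean=, shape=)` for a gamma
#'   shifted to a floor of 1; `mean <= 1` collapses to all-ones.
#' @return object of class `battery_config`.
#' @export
battery_config <- function(traits, Rg, overlap = NULL, M = 2000,
                           n_chromosome_blocks = 200, seed = 1,
                           ld_shape = list(mean = 40, shape = 2)) {
  k <- length(traits)
  if (k < 1L) stopf("need at least one trait")
  Rg <- as.matrix(Rg)
  if (!all(dim(Rg) == k)) stopf("Rg must be %d x %d", k, k)
  if (max(abs(Rg - t(Rg))) > 1e-10) stopf("Rg must be symmetric")
  if (max(abs(diag(Rg) - 1)) > 1e-10) stopf("Rg must have a unit diagonal")
  if (any(abs(Rg) > 1 + 1e-10)) stopf("Rg entries must lie in [-1,1]")
  chk <- psd_check(Rg)
  if (!chk$ok)
    stopf("Rg is not positive semidefinite (min eigenvalue %.3g)",
          chk$min_eigen)
  if (is.null(overlap)) overlap <- matrix(0, k, k)
  overlap <- as.matrix(overlap)
  if (!all(dim(overlap) == k)) stopf("overlap must be %d x %d", k, k)
  if (max(abs(overlap - t(overlap))) > 1e-8)
    stopf("overlap must be symmetric")
  if (M < 200) stopf("M must be at least 200")
  if (n_chromosome_blocks < 2 || n_chromosome_blocks > M)
    stopf("n_chromosome_blocks must lie in [2, M]")
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("trait names must be unique")
  dimnames(Rg) <- list(nm, nm)
  structure(list(traits = traits, Rg = Rg, overlap = overlap, M = M,
                 n_chromosome_blocks = n_chromosome_blocks, seed = seed,
                 ld_shape = ld_shape),
            class = "battery_config")
}

#' Simulate an LD-score table
#'
#' LD scores are drawn i.i.d. from a gamma distribution shifted to a floor
#' of 1 (positive and right-skewed, like real L2 values).  SNPs receive
#' contiguous 1-based positions on synthetic chromosomes, one chromosome
#' per block.
#'
#' @param M number of SNPs (positive).
#' @param seed integer seed; output is deterministic given the seed.
#' @param ld_shape `list(mean=, shape=)`; `mean` is the target mean of L2
#'   including the +1 shift, `shape` the gamma shape.  `mean <= 1` gives the
#'   degenerate all-ones table.
#' @param n_blocks number of synthetic chromosomes.
#' @return data.frame with columns CHR, SNP, BP, L2.
#' @export
make_ld_scores <- function(M, seed = 1,
                           ld_shape = list(mean = 40, shape = 2),
                           n_blocks = min(200, M)) {
  if (!is.numeric(M) || M < 1) stopf("M must be a positive count")
  M <- as.integer(M)
  mu <- ld_shape$mean
  shp <- if (is.null(ld_shape$shape)) 2 else ld_shape$shape
  l2 <- if (is.null(mu) || mu <= 1) rep(1, M) else
    with_seed(seed, 1 + stats::rgamma(M, shape = shp,
                                      scale = (mu - 1) / shp))
  chr <- block_ids(M, n_blocks)
  bp <- stats::ave(seq_len(M), chr, FUN = seq_along)
  data.frame(CHR = chr, SNP = sprintf("rs%d", seq_len(M)),
             BP = as.integer(bp), L2 = l2, stringsAsFactors = FALSE)
}

# Contiguous near-equal block assignment in SNP order.
block_ids <- function(M, n_blocks) {
  as.integer(cut(seq_len(M), breaks = n_blocks, labels = FALSE))
}

# Non-ambiguous allele pairs keep the munge stage from discarding synthetic
# records as strand-ambiguous.
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                        ncol = 2, byrow = TRUE)

#' Simulate a battery of stratified GWAS summary statistics
#'
#' Draws per-SNP z-score vectors from the cross-trait LDSC generative model
#' with known genetic correlations, heritabilities, sample sizes and
#' participant overlap.  Writing `Sigma_j = B + l_j A` with
#' `A = sqrt(NN') * covg / M` (genetic part) and `B` the intercept matrix,
#' z-scores are drawn as `L_B u + sqrt(l_j) L_A v` with independent standard
#' normal u, v; both components must be positive semidefinite for the
#' configuration to be feasible.
#'
#' @param config a [battery_config()].
#' @return list with `sumstats` (named list of data.frames in the munged
#'   dialect SNP A1 A2 Z N), `ld` (LD-score table), `registry` (allele
#'   registry SNP A1 A2 CHR BP) and `truth` (generating values: Rg, h2 on
#'   both scales, effective N, intercept matrix, seed).
#' @export
simulate_battery <- function(config) {
  stopifnot(inherits(config, "battery_config"))
  k <- length(config$traits)
  M <- config$M
  nm <- vapply(config$traits, `[[`, "", "name")
  h2o <- vapply(config$traits, trait_h2_obs, 0)
  h2l <- vapply(config$traits, `[[`, 0, "h2")
  N <- vapply(config$traits, trait_n, 0)

  covg <- config$Rg * outer(sqrt(h2o), sqrt(h2o))
  A <- outer(sqrt(N), sqrt(N)) * covg / M
  B <- config$overlap / outer(sqrt(N), sqrt(N))
  diag(B) <- 1

  chkA <- psd_check(A)
  if (!chkA$ok)
    stopf("infeasible configuration: genetic covariance component is not PSD for trait pair (%s, %s)",
          nm[chkA$pair[1]], nm[chkA$pair[2]])
  chkB <- psd_check(B)
  if (!chkB$ok)
    stopf("infeasible configuration: intercept matrix is not PSD for trait pair (%s, %s)",
          nm[chkB$pair[1]], nm[chkB$pair[2]])

  ld <- make_ld_scores(M, seed = config$seed, ld_shape = config$ld_shape,
                       n_blocks = config$n_chromosome_blocks)

  LA <- psd_sqrt(A)
  LB <- psd_sqrt(B)
  out <- with_seed(config$seed + 1L, {
    U <- matrix(stats::rnorm(M * k), M, k)
    V <- matrix(stats::rnorm(M * k), M, k)
    ai <- sample.int(nrow(.allele_pairs), M, replace = TRUE)
    list(Z = U %*% t(LB) + sqrt(ld$L2) * (V %*% t(LA)), ai = ai)
  })
  Z <- out$Z
  a1 <- .allele_pairs[out$ai, 1]
  a2 <- .allele_pairs[out$ai, 2]

  sumstats <- lapply(seq_len(k), function(t) {
    data.frame(SNP = ld$SNP, A1 = a1, A2 = a2, Z = Z[, t], N = N[t],
               stringsAsFactors = FALSE)
  })
  names(sumstats) <- nm

  registry <- data.frame(SNP = ld$SNP, A1 = a1, A2 = a2,
                         CHR = ld$CHR, BP = ld$BP, stringsAsFactors = FALSE)

  truth <- list(traits = nm, Rg = config$Rg,
                h2_liability = stats::setNames(h2l, nm),
                h2_observed = stats::setNames(h2o, nm),
                n_effective = stats::setNames(N, nm), intercepts = B,
                seed = config$seed)
  list(sumstats = sumstats, ld = ld, registry = registry, truth = truth)
}

#' Default stratified-autism-like battery preset
#'
#' Four focal strata mimicking sex- and age-at-diagnosis-stratified autism
#' GWAS: generating genetic correlations r_g(male,female)=0.81,
#' r_g(early,late)=0.42, r_g(late,male)=0.99, r_g(late,female)=0.91, with
#' the remaining pairs set to values consistent with that structure
#' (early-male 0.45, early-female 0.40).  The raw matrix is projected to the
#' nearest positive semidefinite correlation matrix; the maximum entry-wise
#' projection delta is recorded in the returned config as
#' `attr(config$Rg, "projection_delta")` and the projected values are the
#' generating truth.  Optional external traits are continuous with genetic
#' correlation `r_external` to every focal stratum.
#'
#' @param n_external number of additional continuous external traits.
#' @param r_external genetic correlation of each external trait with each
#'   stratum (and with other externals).
#' @param M,n_blocks,seed,ld_shape passed to [battery_config()].
#' @param overlap optional overlap matrix (defaults to none).
#' @return a [battery_config()].
#' @export
preset_battery <- function(n_external = 0, r_external = 0.3, M = 2000,
                           n_blocks = 200, seed = 1,
                           ld_shape = list(mean = 40, shape = 2),
                           overlap = NULL) {
  strata <- list(
    sim_trait("ASD_male", "binary", h2 = 0.20, K = 0.02,
              n_cases = 15025, n_controls = 19763),
    sim_trait("ASD_female", "binary", h2 = 0.20, K = 0.005,
              n_cases = 4845, n_controls = 19315),
    sim_trait("ASD_early", "binary", h2 = 0.20, K = 0.01,
              n_cases = 16804, n_controls = 16804),
    sim_trait("ASD_late", "binary", h2 = 0.20, K = 0.01,
              n_cases = 10888, n_controls = 10887))
  R4 <- matrix(c(1, .81, .45, .99,
                 .81, 1, .40, .91,
                 .45, .40, 1, .42,
                 .99, .91, .42, 1), 4, 4)
  k <- 4 + n_external
  Rg <- matrix(r_external, k, k)
  Rg[1:4, 1:4] <- R4
  diag(Rg) <- 1
  Rp <- nearest_psd_corr(Rg)
  attr(Rp, "projection_delta") <- max(abs(Rp - Rg))
  traits <- strata
  if (n_external > 0) {
    traits <- c(traits, lapply(seq_len(n_external), function(i) {
      sim_trait(sprintf("external_%d", i), "continuous", h2 = 0.30,
                n_total = 50000)
    }))
  }
  battery_config(traits, Rp, overlap = overlap, M = M,
                 n_chromosome_blocks = n_blocks, seed = seed,
                 ld_shape = ld_shape)
}

#' Write a simulated battery to disk
#'
#' Sumstats go out tab-delimited with header SNP A1 A2 Z N (one file per
#' trait), LD scores as CHR SNP BP L2 with an M-count sidecar, the registry
#' as SNP A1 A2 CHR BP, and the truth record as YAML-like key: value text.
#'
#' @param sim result of [simulate_battery()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_battery <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(sim$sumstats)) {
    f <- file.path(dir, paste0(nm, ".sumstats"))
    utils::write.table(sim$sumstats[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "ldscores.l2.ldscore")
  utils::write.table(sim$ld, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(as.character(nrow(sim$ld)), file.path(dir, "ldscores.l2.M"))
  utils::write.table(sim$registry, file.path(dir, "registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  lines <- c(sprintf("seed: %d", tr$seed),
             sprintf("traits: %s", paste(tr$traits, collapse = ",")),
             sprintf("h2_liability: %s", paste(tr$h2_liability, collapse = ",")),
             sprintf("h2_observed: %s", paste(tr$h2_observed, collapse = ",")),
             sprintf("n_effective: %s", paste(tr$n_effective, collapse = ",")),
             sprintf("Rg: %s", paste(vech(tr$Rg), collapse = ",")),
             sprintf("intercepts: %s", paste(vech(tr$intercepts), collapse = ",")))
  writeLines(lines, file.path(dir, "truth.yml"))
  invisible(c(files, f))
}
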