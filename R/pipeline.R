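# Battery-level orchestration: inclusion screening, per-trait constrained
# vs free model comparisons, FDR correction, and the factor-adjusted vs
# unadjusted comparison tables.

#' Screen traits by heritability z-statistic
#'
#' A trait enters the battery only when its SNP-heritability z-statistic
#' exceeds `z_min` (strict), the conventional power screen for LDSC-based
#' structural modeling.
#'
#' @param gc a `gcov` object.
#' @param z_min inclusion threshold, default 4.
#' @return list with `included`, `excluded` (names) and a data.frame `log`
#'   of the excluded traits with their z-statistics.
#' @export
screen_traits <- function(gc, z_min = 4) {
  stopifnot(inherits(gc, "gcov"))
  z <- gc$h2_z
  inc <- names(z)[z > z_min]
  exc <- setdiff(names(z), inc)
  list(included = inc, excluded = exc,
       log = data.frame(trait = exc, h2_z = unname(z[exc]),
                        stringsAsFactors = FALSE))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values with rejection at `adjusted <= q`.
#'
#' @param pvals p-values in \[0,1\].
#' @param q FDR level, default 0.05.
#' @return list(adjusted, reject).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0,1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

# Constrained-equality comparison for one external trait against two focal
# strata: r(A, T) and r(B, T) constrained equal, r(A, B) free; df = 1.
constrained_comparison <- function(gc, a, b, trait, seed = 1) {
  sub <- gcov_subset(gc, c(a, b, trait))
  chk <- psd_check(sub$V, tol = 1e-10 * max(1, max(abs(sub$V))))
  if (!chk$ok) return(NULL)
  spec <- model_spec(variables = c(a, b, trait),
                     correlations = list(c(a, b), c(a, trait), c(b, trait)),
                     equality = list(c(
                       sprintf("r_%s_%s", a, trait),
                       sprintf("r_%s_%s", b, trait))))
  fit <- fit_dwls(spec, sub$S, sub$V, seed = seed)
  wald <- wald_equality_test(sub$S, sub$V, c(a, trait), c(b, trait))
  k <- 3
  i1 <- vech_index(match(a, sub$traits), 3, k)
  i2 <- vech_index(match(b, sub$traits), 3, k)
  list(fit = fit, wald = wald,
       r1 = sub$S[a, trait], se1 = sqrt(sub$V[i1, i1]),
       r2 = sub$S[b, trait], se2 = sqrt(sub$V[i2, i2]))
}

#' Compare two focal strata across a battery of external traits
#'
#' For every external trait, fits the model in which the genetic
#' correlations of the two strata with the trait are constrained to be
#' equal (1 degree of freedom); the model chi-square measures the misfit of
#' the equality constraint.  A Wald contrast is computed alongside as an
#' independent check.  Difference p-values and per-stratum correlation
#' p-values are FDR-corrected across the battery, as separate families.
#'
#' @param gc a `gcov` object (standardized to the correlation scale if
#'   needed).
#' @param stratumA,stratumB the two focal strata.
#' @param externals external trait names (disjoint from the strata).
#' @param q FDR level.
#' @param seed passed to the model fits.
#' @return data.frame of class `battery_table`, one row per external
#'   trait: r1, se1, r2, se2, chisq_diff, df, p_diff, chisq_wald, p_fdr,
#'   sig_diff, sig1, sig2.  Traits whose extracted sampling covariance is
#'   not PSD are skipped; their names are kept in `attr(, "skipped")`.
#' @export
battery_compare <- function(gc, stratumA, stratumB, externals, q = 0.05,
                            seed = 1) {
  stopifnot(inherits(gc, "gcov"))
  if (gc$scale != "correlation") gc <- standardize(gc)
  if (length(intersect(c(stratumA, stratumB), externals)))
    stopf("externals must be disjoint from the strata")
  rows <- list()
  skipped <- character(0)
  for (tr in externals) {
    cmp <- constrained_comparison(gc, stratumA, stratumB, tr, seed = seed)
    if (is.null(cmp)) { skipped <- c(skipped, tr); next }
    rows[[tr]] <- data.frame(
      trait = tr, r1 = cmp$r1, se1 = cmp$se1, r2 = cmp$r2, se2 = cmp$se2,
      chisq_diff = cmp$fit$chisq, df = cmp$fit$df, p_diff = cmp$fit$p,
      chisq_wald = cmp$wald$chisq, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no external trait survived extraction")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fdr <- bh_fdr(tab$p_diff, q)
  tab$p_fdr <- fdr$adjusted
  tab$sig_diff <- fdr$reject
  p1 <- 2 * stats::pnorm(-abs(tab$r1 / tab$se1))
  p2 <- 2 * stats::pnorm(-abs(tab$r2 / tab$se2))
  tab$sig1 <- bh_fdr(p1, q)$reject
  tab$sig2 <- bh_fdr(p2, q)$reject
  attr(tab, "skipped") <- skipped
  attr(tab, "strata") <- c(stratumA, stratumB)
  attr(tab, "q") <- q
  class(tab) <- c("battery_table", "data.frame")
  tab
}

# Factor-adjusted equality comparison for one external trait: residual
# associations of the two strata with the trait after removing the common
# factor, tested for equality by a Wald contrast on the sandwich
# covariance of the standardized residual associations.
adjusted_comparison <- function(gc, indicators, a, b, trait, seed = 1) {
  sub <- gcov_subset(gc, c(indicators, a, b, trait))
  fit <- factor_residual_model(sub$S, sub$V, indicators,
                               targets = c(a, b, trait), seed = seed)
  ra <- fit$residual_assoc
  q1 <- which(ra$t1 == a & ra$t2 == trait | ra$t1 == trait & ra$t2 == a)
  q2 <- which(ra$t1 == b & ra$t2 == trait | ra$t1 == trait & ra$t2 == b)
  a1 <- ra$std[q1]; a2 <- ra$std[q2]
  v1 <- fit$residual_vcov[q1, q1]; v2 <- fit$residual_vcov[q2, q2]
  c12 <- fit$residual_vcov[q1, q2]
  den <- v1 + v2 - 2 * c12
  if (!is.finite(den) || den <= 0) return(NULL)
  chisq <- (a1 - a2)^2 / den
  list(fit = fit, beta1 = a1, se1 = sqrt(v1), beta2 = a2, se2 = sqrt(v2),
       chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Factor-adjusted versus unadjusted battery comparison
#'
#' Runs the constrained-equality battery on the raw genetic correlations
#' and on the residual associations after removing a common factor defined
#' by the indicator traits (for each external trait the factor model spans
#' the indicators, both strata and the trait).  Each external trait is
#' classified by the transition of its FDR-corrected difference flag:
#' `persists`, `attenuated-to-ns`, `newly-significant` or `stable-ns`.
#'
#' @param gc a `gcov` object.
#' @param indicators factor indicator traits (>= 3).
#' @param strata the two focal strata.
#' @param externals external trait names.
#' @param q FDR level.
#' @param seed passed to the model fits.
#' @return list with `unadjusted` (a `battery_table`), `adjusted`
#'   (data.frame with residual associations and their equality test) and
#'   `comparison` (per-trait transition classes).
#' @export
adjustment_comparison <- function(gc, indicators, strata, externals,
                                  q = 0.05, seed = 1) {
  stopifnot(inherits(gc, "gcov"), length(strata) == 2)
  if (gc$scale != "correlation") gc <- standardize(gc)
  unadj <- battery_compare(gc, strata[1], strata[2], externals, q = q,
                           seed = seed)
  rows <- list()
  skipped <- character(0)
  for (tr in externals) {
    cmp <- tryCatch(
      adjusted_comparison(gc, indicators, strata[1], strata[2], tr,
                          seed = seed),
      error = function(e) NULL)
    if (is.null(cmp)) { skipped <- c(skipped, tr); next }
    rows[[tr]] <- data.frame(
      trait = tr, beta1 = cmp$beta1, se1 = cmp$se1,
      beta2 = cmp$beta2, se2 = cmp$se2,
      chisq_diff = cmp$chisq, df = 1L, p_diff = cmp$p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no external trait survived factor adjustment")
  adj <- do.call(rbind, rows)
  rownames(adj) <- NULL
  fdr <- bh_fdr(adj$p_diff, q)
  adj$p_fdr <- fdr$adjusted
  adj$sig_diff <- fdr$reject

  common <- intersect(unadj$trait, adj$trait)
  u <- unadj$sig_diff[match(common, unadj$trait)]
  a <- adj$sig_diff[match(common, adj$trait)]
  cls <- ifelse(u & a, "persists",
         ifelse(u & !a, "attenuated-to-ns",
         ifelse(!u & a, "newly-significant", "stable-ns")))
  comparison <- data.frame(
    trait = common,
    beta1_unadjusted = unadj$r1[match(common, unadj$trait)],
    beta1_adjusted = adj$beta1[match(common, adj$trait)],
    beta2_unadjusted = unadj$r2[match(common, unadj$trait)],
    beta2_adjusted = adj$beta2[match(common, adj$trait)],
    p_diff_unadjusted = unadj$p_diff[match(common, unadj$trait)],
    p_diff_adjusted = adj$p_diff[match(common, adj$trait)],
    transition = cls, stringsAsFactors = FALSE)
  list(unadjusted = unadj, adjusted = adj, comparison = comparison,
       skipped = skipped)
}

#' @export
print.battery_table <- function(x, ...) {
  st <- attr(x, "strata")
  cat(sprintf("Battery comparison: %s vs %s across %d external trait(s)\n",
              st[1], st[2], nrow(x)))
  cat(sprintf("Significantly divergent (FDR %.2g): %d\n",
              attr(x, "q"), sum(x$sig_diff)))
  print.data.frame(cbind(x[, c("trait", "r1", "r2")],
                         chisq = round(x$chisq_diff, 2),
                         p_diff = signif(x$p_diff, 3),
                         sig = x$sig_diff))
  invisible(x)
}

#' Write a battery table as tab-delimited text
#' @param tab a `battery_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_battery_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a battery table written by [write_battery_table()]
#' @param path input file.
#' @return data.frame of class `battery_table`.
#' @export
read_battery_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(tab) <- c("battery_table", "data.frame")
  tab
}

#' Trait metadata table from a simulation configuration
#'
#' Convenience bridge from the generator's trait specifications to the
#' metadata [multivariable_ldsc()] needs (name, binary flag, population
#' prevalence).
#'
#' @param config a [battery_config()].
#' @return data.frame with columns name, binary, K.
#' @export
meta_from_config <- function(config) {
  stopifnot(inherits(config, "battery_config"))
  data.frame(
    name = vapply(config$traits, `[[`, "", "name"),
    binary = vapply(config$traits, function(t) t$measurement == "binary",
                    TRUE),
    K = vapply(config$traits, function(t) if (is.null(t$K)) NA_real_ else t$K,
               0),
    stringsAsFactors = FALSE)
}

#' Run the full stratified-comparison pipeline on a simulated battery
#'
#' simulate -> munge -> multivariable LDSC -> screen -> standardize ->
#' constrained-vs-free battery comparison, optionally followed by the
#' factor-adjusted comparison.
#'
#' @param config a [battery_config()].
#' @param strata the two focal strata to compare.
#' @param externals external trait names.
#' @param indicators optional factor indicators; when given the adjusted
#'   comparison is run as well.
#' @param q FDR level.
#' @param z_min heritability z screen.
#' @param n_blocks jackknife blocks.
#' @return list with `sim`, `gcov` (correlation scale), `screen`,
#'   `battery` and (optionally) `adjustment`.
#' @export
run_pipeline <- function(config, strata, externals, indicators = NULL,
                         q = 0.05, z_min = 4, n_blocks = 200) {
  sim <- simulate_battery(config)
  munged <- lapply(sim$sumstats, function(s)
    munge(s, sim$registry)$sumstats)
  gc <- multivariable_ldsc(munged, sim$ld, meta_from_config(config),
                           n_blocks = n_blocks)
  sc <- screen_traits(gc, z_min = z_min)
  keep_ext <- intersect(externals, sc$included)
  gcs <- standardize(gc)
  out <- list(sim = sim, gcov = gcs, screen = sc)
  out$battery <- battery_compare(gcs, strata[1], strata[2], keep_ext,
                                 q = q, seed = config$seed)
  if (!is.null(indicators)) {
    out$adjustment <- adjustment_comparison(gcs, indicators, strata,
                                            keep_ext, q = q,
                                            seed = config$seed)
  }
  out
}
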