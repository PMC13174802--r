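# Multivariable LD-score regression: heritabilities, genetic covariances,
# intercepts, delete-one-block jackknife sampling covariance, liability
# conversion and standardization to the correlation scale.

#' Liability-scale conversion factor
#'
#' c = K^2 (1-K)^2 / (P (1-P) * phi(Phi^-1(1-K))^2) for population
#' prevalence K and sample prevalence P.  Observed-scale estimates from a
#' case-control GWAS are multiplied by this factor (or by sqrt(c1 c2) for a
#' cross-trait covariance) to undo ascertainment.
#'
#' @param K population prevalence in (0,1).
#' @param P sample prevalence in (0,1); 0.5 under the summed effective
#'   sample size convention.
#' @return numeric conversion factor.
#' @export
liability_factor <- function(K, P = 0.5) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stopf("prevalences must lie strictly inside (0,1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' Convert an observed-scale estimate to the liability scale
#'
#' Univariate heritabilities are multiplied by c1; cross-trait covariances
#' by sqrt(c1 c2).  A continuous trait contributes a factor of 1 (pass
#' `NULL` for its parameters).
#'
#' @param x observed-scale h2 or genetic covariance.
#' @param p1,p2 `list(K=, P=)` per trait, or `NULL` for a continuous trait.
#'   The univariate case passes the same parameters twice (or omits `p2`).
#' @return converted value.
#' @export
liability_conversion <- function(x, p1 = NULL, p2 = p1) {
  c1 <- if (is.null(p1)) 1 else liability_factor(p1$K, p1$P)
  c2 <- if (is.null(p2)) 1 else liability_factor(p2$K, p2$P)
  x * sqrt(c1 * c2)
}

#' Single LD-score regression with block jackknife
#'
#' Two-step weighted least squares of a per-SNP response (chi-square or a
#' z-score product) on LD scores.  Weights are inverse variances under the
#' generative model: for a univariate chi-square response
#' Var(y_j) = 2 v_j^2 with v_j = intercept + n h2 ell_j / M, and for a
#' cross-trait product Var(y_j) = v1_j v2_j + v12_j^2 where v1, v2 are the
#' univariate expected chi-squares of the two traits (supplied via
#' `aux_var`; the response's own v is used when absent).  Step 1 evaluates
#' the weights at intercept 1 and unit slope guess; step 2 re-evaluates
#' them at the step-1 estimates, with the slope clamped to
#' `[0, (M/n_scale) * max(ell)]` for weighting only.  The fitted slope is
#' on the h2 / genetic-covariance scale (the regressor is `n * ell / M`).
#' Delete-one-block re-estimates use the final weights.
#'
#' @param y per-SNP response.
#' @param ell per-SNP LD scores (non-negative).
#' @param n_scale scalar sample-size factor (N, or sqrt(N1 N2) cross-trait).
#' @param M number of SNPs the heritability is spread over.
#' @param blocks integer block assignment (contiguous in SNP order).
#' @param fix_intercept optional fixed intercept (e.g. 1 for no confounding).
#' @param n optional per-SNP sample sizes; defaults to `n_scale`.
#' @param aux_var optional list of two per-SNP vectors holding the
#'   univariate expected chi-squares of the traits whose z-score product is
#'   being regressed (cross-trait fits only).
#' @return list with `slope`, `intercept`, `loo` (b x 2 matrix of
#'   delete-one-block slope and intercept), `se` (jackknife SE of the
#'   slope) and `weights`.
#' @export
ldsc_regression <- function(y, ell, n_scale, M, blocks,
                            fix_intercept = NULL, n = NULL,
                            aux_var = NULL) {
  m <- length(y)
  if (length(ell) != m || length(blocks) != m)
    stopf("y, ell and blocks must be aligned")
  if (any(ell < 0)) stopf("LD scores must be non-negative")
  b <- length(unique(blocks))
  if (b < 2) stopf("need at least 2 jackknife blocks")
  if (stats::sd(ell) == 0)
    stopf("constant LD scores: regression is rank deficient")
  if (is.null(n)) n <- rep(n_scale, m)

  x <- n * ell / M                      # slope is h2 / covg directly
  w_at <- function(int, slope) {
    slope_w <- min(max(slope, 0), (M / n_scale) * max(ell))
    v <- int + n_scale * slope_w * ell / M
    if (is.null(aux_var)) {
      1 / pmax(2 * v^2, 1e-3)
    } else {
      1 / pmax(aux_var[[1]] * aux_var[[2]] + v^2, 1e-3)
    }
  }

  fit_wls <- function(w) {
    if (is.null(fix_intercept)) {
      sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
      sy <- sum(w * y); sxy <- sum(w * x * y)
      den <- sw * sxx - sx^2
      slope <- (sw * sxy - sx * sy) / den
      int <- (sy - slope * sx) / sw
    } else {
      yc <- y - fix_intercept
      slope <- sum(w * x * yc) / sum(w * x^2)
      int <- fix_intercept
    }
    c(slope = slope, intercept = int)
  }

  f1 <- fit_wls(w_at(1, 1))
  w <- w_at(f1["intercept"], f1["slope"])
  if (!is.null(fix_intercept)) w <- w_at(fix_intercept, f1["slope"])
  fit <- fit_wls(w)

  # delete-one-block refits from per-block sufficient statistics
  gb <- factor(blocks, levels = unique(blocks))
  S <- cbind(w, w * x, w * x^2, w * y, w * x * y)
  Sb <- rowsum(S, gb)
  tot <- colSums(S)
  if (is.null(fix_intercept)) {
    swd <- tot[1] - Sb[, 1]; sxd <- tot[2] - Sb[, 2]
    sxxd <- tot[3] - Sb[, 3]; syd <- tot[4] - Sb[, 4]
    sxyd <- tot[5] - Sb[, 5]
    dend <- swd * sxxd - sxd^2
    slo <- (swd * sxyd - sxd * syd) / dend
    into <- (syd - slo * sxd) / swd
  } else {
    Syc <- cbind(w * x * (y - fix_intercept))
    Sycb <- rowsum(Syc, gb)
    slo <- (sum(Syc) - Sycb[, 1]) / (tot[3] - Sb[, 3])
    into <- rep(fix_intercept, b)
  }
  loo <- cbind(slope = slo, intercept = into)
  th <- colMeans(loo)
  se <- sqrt((b - 1) / b * sum((loo[, 1] - th[1])^2))

  list(slope = unname(fit["slope"]), intercept = unname(fit["intercept"]),
       loo = loo, se = se, weights = w)
}

#' Multivariable LD-score regression
#'
#' Assembles the k x k genetic covariance matrix S (univariate fits on the
#' diagonal, pairwise fits off the diagonal) on the common SNP set of all
#' traits, converts binary traits to the liability scale (inside every
#' jackknife replicate), and computes the full sampling covariance V of
#' vech(S) by the delete-one-block jackknife,
#' V = ((b-1)/b) * sum_i (theta_(i) - theta_bar)(theta_(i) - theta_bar)'.
#' Cross-trait intercepts are retained as sample-overlap diagnostics.
#'
#' @param tables named list of munged sumstats data.frames (SNP A1 A2 Z N).
#' @param ld LD-score table (CHR SNP BP L2).
#' @param meta data.frame with columns `name`, `binary` (logical) and `K`
#'   (population prevalence, NA for continuous traits).  Sample prevalence
#'   is fixed at 0.5 under the summed effective-N convention.
#' @param n_blocks jackknife blocks (contiguous in genome order).
#' @return object of class `gcov`: S, V (with vech in lower-triangle column
#'   order), intercepts, M, h2_z, jackknife replicates, trait names.
#' @export
multivariable_ldsc <- function(tables, ld, meta, n_blocks = 200) {
  k <- length(tables)
  if (k < 2) stopf("need at least two traits")
  nm <- names(tables)
  if (is.null(nm) || any(nm == "")) stopf("tables must be named")
  if (!all(nm %in% meta$name)) stopf("metadata missing for some traits")
  meta <- meta[match(nm, meta$name), , drop = FALSE]

  snps <- Reduce(intersect, c(lapply(tables, `[[`, "SNP"), list(ld$SNP)))
  if (length(snps) < 200)
    stopf("only %d SNPs shared across traits and LD scores (need >= 200)",
          length(snps))
  ld <- ld[match(snps, ld$SNP), , drop = FALSE]
  ord <- order(ld$CHR, ld$BP)
  ld <- ld[ord, , drop = FALSE]
  snps <- ld$SNP
  m <- length(snps)

  Z <- matrix(0, m, k)
  Nm <- matrix(0, m, k)
  for (t in seq_len(k)) {
    tab <- tables[[t]]
    idx <- match(snps, tab$SNP)
    Z[, t] <- tab$Z[idx]
    Nm[, t] <- tab$N[idx]
  }
  blocks <- block_ids(m, n_blocks)
  b <- length(unique(blocks))

  # liability conversion factors under P = 0.5
  cf <- vapply(seq_len(k), function(t)
    if (isTRUE(meta$binary[t])) liability_factor(meta$K[t], 0.5) else 1, 0)

  p_star <- k * (k + 1) / 2
  theta <- numeric(p_star)
  reps <- matrix(0, b, p_star)
  intercepts <- diag(1, k)
  h2_z <- numeric(k)

  # preliminary univariate fits: their predicted chi-square means feed the
  # variance model of every final regression (diagonal included, so that a
  # trait paired with itself reproduces its own heritability fit exactly)
  vhat <- matrix(0, m, k)
  for (t in seq_len(k)) {
    pre <- ldsc_regression(Z[, t]^2, ld$L2, mean(Nm[, t]), m, blocks,
                           n = Nm[, t])
    vhat[, t] <- pmax(pre$intercept +
                        Nm[, t] * max(pre$slope, 0) * ld$L2 / m, 0.1)
  }

  for (jj in seq_len(k)) for (ii in jj:k) {
    pos <- vech_index(ii, jj, k)
    npair <- sqrt(Nm[, ii] * Nm[, jj])
    ns <- mean(npair)
    f <- ldsc_regression(Z[, ii] * Z[, jj], ld$L2, ns, m, blocks,
                         n = npair,
                         aux_var = list(vhat[, ii], vhat[, jj]))
    cc <- sqrt(cf[ii] * cf[jj])
    theta[pos] <- f$slope * cc
    reps[, pos] <- f$loo[, "slope"] * cc
    intercepts[ii, jj] <- intercepts[jj, ii] <- f$intercept
    if (ii == jj) h2_z[ii] <- f$slope / max(f$se, .Machine$double.eps)
  }

  tb <- colMeans(reps)
  V <- (b - 1) / b * crossprod(sweep(reps, 2, tb))
  S <- unvech(theta, k)
  dimnames(S) <- list(nm, nm)
  dimnames(intercepts) <- list(nm, nm)
  names(h2_z) <- nm

  structure(list(S = S, V = V, intercepts = intercepts, M = m,
                 h2_z = h2_z, replicates = reps, n_blocks = b,
                 traits = nm, scale = "covariance",
                 liability = meta$binary),
            class = "gcov")
}

#' Standardize a genetic covariance object to the correlation scale
#'
#' R[k,l] = S[k,l] / sqrt(S[k,k] S[l,l]); the sampling covariance of
#' vech(R) is obtained by standardizing inside each jackknife replicate and
#' re-applying the jackknife formula, so sampling dependencies propagate
#' exactly.  Unit-diagonal elements carry zero sampling variance.
#'
#' @param gc object of class `gcov` on the covariance scale.
#' @return object of class `gcov` with `scale = "correlation"`.
#' @export
standardize <- function(gc) {
  stopifnot(inherits(gc, "gcov"))
  if (gc$scale == "correlation") return(gc)
  k <- length(gc$traits)
  d <- diag(gc$S)
  if (any(d <= 0))
    stopf("non-positive heritability for trait(s): %s",
          paste(gc$traits[d <= 0], collapse = ", "))
  R <- gc$S / outer(sqrt(d), sqrt(d))
  diag(R) <- 1

  diag_pos <- vech_index(seq_len(k), seq_len(k), k)
  std_rep <- function(v) {
    dd <- v[diag_pos]
    Sv <- unvech(v, k)
    Rv <- Sv / outer(sqrt(pmax(dd, .Machine$double.eps)),
                     sqrt(pmax(dd, .Machine$double.eps)))
    diag(Rv) <- 1
    vech(Rv)
  }
  reps <- t(apply(gc$replicates, 1, std_rep))
  b <- nrow(reps)
  tb <- colMeans(reps)
  V <- (b - 1) / b * crossprod(sweep(reps, 2, tb))
  V[diag_pos, ] <- 0
  V[, diag_pos] <- 0

  out <- gc
  out$S <- R
  out$V <- V
  out$replicates <- reps
  out$scale <- "correlation"
  out
}

#' @export
print.gcov <- function(x, ...) {
  cat(sprintf("Genetic %s matrix (%d traits, %d SNPs, %d jackknife blocks)\n",
              x$scale, length(x$traits), x$M, x$n_blocks))
  print(round(x$S, 4))
  invisible(x)
}

#' @export
summary.gcov <- function(object, ...) {
  k <- length(object$traits)
  se <- sqrt(pmax(diag(object$V), 0))
  Sse <- unvech(se, k)
  cat(sprintf("Genetic %s matrix\n", object$scale))
  cat("\nEstimates:\n"); print(round(object$S, 4))
  cat("\nJackknife SEs:\n"); print(round(Sse, 4))
  cat("\nIntercepts:\n"); print(round(object$intercepts, 4))
  cat("\nh2 z-statistics:\n"); print(round(object$h2_z, 2))
  invisible(object)
}

#' @export
coef.gcov <- function(object, ...) object$S

# Sub-block of V for a subset of traits, with matching vech re-indexing.
gcov_subset <- function(gc, traits) {
  idx <- match(traits, gc$traits)
  if (anyNA(idx)) stopf("unknown trait(s): %s",
                        paste(traits[is.na(idx)], collapse = ", "))
  k <- length(gc$traits)
  ks <- length(idx)
  pairs <- cbind(rep(idx, times = ks), rep(idx, each = ks))
  sel <- which(upper.tri(diag(ks), diag = TRUE))
  # vech positions of the subset pairs in the full matrix, subset vech order
  vpos <- integer(ks * (ks + 1) / 2)
  p <- 0L
  for (jj in seq_len(ks)) for (ii in jj:ks) {
    p <- p + 1L
    vpos[p] <- vech_index(idx[ii], idx[jj], k)
  }
  out <- gc
  out$S <- gc$S[idx, idx, drop = FALSE]
  out$V <- gc$V[vpos, vpos, drop = FALSE]
  out$replicates <- gc$replicates[, vpos, drop = FALSE]
  out$intercepts <- gc$intercepts[idx, idx, drop = FALSE]
  out$h2_z <- gc$h2_z[idx]
  out$traits <- gc$traits[idx]
  out$liability <- gc$liability[idx]
  out
}
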