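# Structural models on a genetic correlation matrix R with sampling
# covariance V_R: diagonally weighted least squares with sandwich standard
# errors.  The unit diagonal is treated as fixed, so only structured
# off-diagonal elements are modeled; the discrepancy is
#   F(theta) = (s - sigma(theta))' D^-1 (s - sigma(theta)),
# D = diag(V_R) restricted to the modeled elements.

#' Declare a structural model
#'
#' Supports the model families used in stratified-GWAS comparisons: free
#' correlations with optional equality constraints, and a single common
#' factor (unit variance, free loadings) with regression paths to target
#' variables and free residual covariances among targets.  Parameter labels
#' are `r_<v1>_<v2>` (correlations), `l_<ind>` (loadings), `b_<tgt>`
#' (factor paths) and `c_<t1>_<t2>` (target residual covariances); equality
#' sets refer to these labels.  Off-diagonal pairs not covered by any model
#' component are left out of the fit (fixed).
#'
#' @param variables character vector naming the observed variables, in the
#'   order of the correlation matrix the model will be fitted to.
#' @param correlations list of character pairs with a free correlation.
#' @param equality list of character vectors; parameters within a vector
#'   are constrained equal (a label may appear in at most one set).
#' @param factor_indicators indicators of the common factor (>= 3 for an
#'   identified factor unless paths add information).
#' @param factor_targets variables regressed on the factor.
#' @param residual_cov list of target pairs with a free residual
#'   covariance; defaults to all target pairs when a factor is present.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(variables, correlations = NULL, equality = NULL,
                       factor_indicators = NULL, factor_targets = NULL,
                       residual_cov = NULL) {
  k <- length(variables)
  vid <- function(v) {
    i <- match(v, variables)
    if (anyNA(i)) stopf("unknown variable(s): %s",
                        paste(v[is.na(i)], collapse = ", "))
    i
  }
  pars <- list()
  add_par <- function(label, type, i, j = NA_integer_) {
    pars[[length(pars) + 1L]] <<- list(label = label, type = type,
                                       i = i, j = j)
  }
  pair_label <- function(pfx, i, j)
    sprintf("%s_%s_%s", pfx, variables[min(i, j)], variables[max(i, j)])

  for (p in correlations) {
    ij <- vid(p)
    if (ij[1] == ij[2]) stopf("correlation pair must involve two variables")
    add_par(pair_label("r", ij[1], ij[2]), "corr", max(ij), min(ij))
  }
  ind <- tgt <- integer(0)
  if (!is.null(factor_indicators)) {
    ind <- vid(factor_indicators)
    tgt <- if (is.null(factor_targets)) integer(0) else vid(factor_targets)
    if (length(intersect(ind, tgt)))
      stopf("factor targets must be disjoint from indicators")
    for (i in ind) add_par(sprintf("l_%s", variables[i]), "loading", i)
    for (t in tgt) add_par(sprintf("b_%s", variables[t]), "path", t)
    if (is.null(residual_cov) && length(tgt) >= 2) {
      residual_cov <- utils::combn(variables[tgt], 2, simplify = FALSE)
    }
    for (p in residual_cov %||% list()) {
      ij <- vid(p)
      if (!all(ij %in% tgt))
        stopf("residual covariances are only defined among factor targets")
      add_par(pair_label("c", ij[1], ij[2]), "rescov", max(ij), min(ij))
    }
  } else if (!is.null(residual_cov)) {
    stopf("residual covariances require a factor model")
  }
  if (!length(pars)) stopf("model has no parameters")
  labels <- vapply(pars, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("duplicated parameter label")

  # equality sets -> free-parameter mapping
  free_of <- stats::setNames(seq_along(labels), labels)
  for (grp in equality %||% list()) {
    miss <- setdiff(grp, labels)
    if (length(miss)) stopf("equality set names unknown parameter(s): %s",
                            paste(miss, collapse = ", "))
    free_of[grp] <- free_of[grp[1]]
  }
  free_ids <- match(free_of, sort(unique(free_of)))
  n_free <- length(unique(free_ids))

  # modeled off-diagonal pairs: listed correlations + all pairs spanned by
  # the factor structure
  pm <- matrix(FALSE, k, k)
  for (p in pars) if (p$type %in% c("corr", "rescov")) pm[p$i, p$j] <- TRUE
  span <- c(ind, tgt)
  if (length(span) >= 2) {
    cmb <- utils::combn(span, 2)
    pm[cbind(pmax(cmb[1, ], cmb[2, ]), pmin(cmb[1, ], cmb[2, ]))] <- TRUE
  }
  el <- which(pm, arr.ind = TRUE)            # i > j
  el <- el[order(el[, 2], el[, 1]), , drop = FALSE]

  structure(list(variables = variables, pars = pars, labels = labels,
                 free_ids = free_ids, n_free = n_free,
                 indicators = ind, targets = tgt,
                 elements = el),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Model-implied correlation matrix from the full (per-parameter) vector.
implied_matrix <- function(spec, full) {
  k <- length(spec$variables)
  m <- diag(1, k)
  lam <- numeric(k); bet <- numeric(k)
  for (ii in seq_along(spec$pars)) {
    p <- spec$pars[[ii]]
    v <- full[ii]
    switch(p$type,
           corr = { m[p$i, p$j] <- m[p$j, p$i] <- v },
           loading = lam[p$i] <- v,
           path = bet[p$i] <- v,
           rescov = { m[p$i, p$j] <- m[p$i, p$j] + v
                      m[p$j, p$i] <- m[p$i, p$j] })
  }
  span <- c(spec$indicators, spec$targets)
  if (length(span) >= 2) {
    f <- lam + bet                      # each variable loads via one path
    for (a in seq_along(span)) for (b in seq_len(a - 1L)) {
      i <- span[a]; j <- span[b]
      m[i, j] <- m[i, j] + f[i] * f[j]
      m[j, i] <- m[i, j]
    }
  }
  m
}

sigma_of <- function(spec, theta) {
  full <- theta[spec$free_ids]
  m <- implied_matrix(spec, full)
  m[spec$elements]
}

start_values <- function(spec, R) {
  full <- numeric(length(spec$pars))
  ind <- spec$indicators; tgt <- spec$targets
  lam0 <- numeric(0)
  if (length(ind) >= 2) {
    lam0 <- vapply(ind, function(i) {
      r <- abs(R[i, setdiff(ind, i)])
      sqrt(max(mean(r), 0.04))
    }, 0)
    names(lam0) <- as.character(ind)
  }
  for (ii in seq_along(spec$pars)) {
    p <- spec$pars[[ii]]
    full[ii] <- switch(p$type,
      corr = R[p$i, p$j],
      loading = lam0[as.character(p$i)],
      path = {
        num <- mean(R[p$i, ind] / pmax(lam0, 0.2))
        max(min(num, 0.95), -0.95)
      },
      rescov = 0)
  }
  # average within equality sets
  theta <- vapply(seq_len(spec$n_free), function(f)
    mean(full[spec$free_ids == f]), 0)
  theta
}

#' Fit a structural model by diagonally weighted least squares
#'
#' Minimizes the DWLS discrepancy over the modeled elements with a damped
#' Gauss-Newton iteration (finite-difference Jacobian), three jittered
#' starts, and convergence declared when the gradient infinity-norm falls
#' below `tol`.  Standard errors are sandwich estimates
#' (D'WD)^-1 D'W V W D (D'WD)^-1 using the full sampling covariance of the
#' modeled elements.
#'
#' @param spec a [model_spec()].
#' @param R genetic correlation matrix (dimnames must cover the spec's
#'   variables).
#' @param V_R sampling covariance of vech(R) (full-matrix vech order).
#' @param seed seed for the jittered extra starts.
#' @param tol gradient convergence tolerance.
#' @param n_starts number of starts (first is data-derived).
#' @return object of class `dwls_fit`: theta (named), se, fitval,
#'   residuals, df, chisq, p, convergence and admissibility flags.
#' @export
fit_dwls <- function(spec, R, V_R, seed = 1, tol = 1e-8, n_starts = 3) {
  vn <- rownames(R)
  if (is.null(vn)) stopf("R must carry variable names")
  ord <- match(spec$variables, vn)
  if (anyNA(ord)) stopf("R lacks variable(s): %s",
                        paste(spec$variables[is.na(ord)], collapse = ", "))
  k0 <- nrow(R)
  idx_full <- vech_index(pmax(ord[spec$elements[, 1]], ord[spec$elements[, 2]]),
                         pmin(ord[spec$elements[, 1]], ord[spec$elements[, 2]]),
                         k0)
  Rs <- R[ord, ord, drop = FALSE]
  s <- R[cbind(ord[spec$elements[, 1]], ord[spec$elements[, 2]])]
  D <- diag(V_R)[idx_full]
  if (any(D <= 0)) stopf("zero sampling variance for a modeled element")
  Vsub <- V_R[idx_full, idx_full, drop = FALSE]
  w <- 1 / D

  obj <- function(th) { e <- s - sigma_of(spec, th); sum(w * e^2) }
  jac <- function(th) {
    h <- 1e-6
    J <- matrix(0, length(s), length(th))
    for (p in seq_along(th)) {
      tp <- th; tm <- th
      tp[p] <- tp[p] + h; tm[p] <- tm[p] - h
      J[, p] <- (sigma_of(spec, tp) - sigma_of(spec, tm)) / (2 * h)
    }
    J
  }

  gauss_newton <- function(th) {
    lambda <- 1e-6
    conv <- FALSE
    for (it in seq_len(300)) {
      e <- s - sigma_of(spec, th)
      J <- jac(th)
      g <- -2 * crossprod(J, w * e)
      if (max(abs(g)) < tol) { conv <- TRUE; break }
      H <- crossprod(J, w * J)
      repeat {
        step <- tryCatch(solve(H + lambda * diag(nrow(H)), crossprod(J, w * e)),
                         error = function(e) NULL)
        if (!is.null(step)) break
        lambda <- lambda * 10
        if (lambda > 1e8) return(list(theta = th, conv = FALSE))
      }
      thn <- th + as.numeric(step)
      if (obj(thn) <= obj(th) + 1e-14) {
        th <- thn
        lambda <- max(lambda / 3, 1e-10)
      } else {
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
    }
    list(theta = th, conv = conv)
  }

  th0 <- start_values(spec, Rs)
  best <- NULL
  for (st in seq_len(n_starts)) {
    thstart <- if (st == 1) th0 else
      with_seed(seed + st, th0 + stats::rnorm(length(th0), sd = 0.05))
    res <- gauss_newton(thstart)
    f <- obj(res$theta)
    if (is.null(best) || (res$conv && !best$conv) ||
        (res$conv == best$conv && f < best$f - 1e-12)) {
      best <- list(theta = res$theta, conv = res$conv, f = f)
    }
  }
  if (!best$conv)
    warning("DWLS fit did not reach the gradient tolerance; ",
            "returning the best iterate")
  th <- best$theta

  # sign convention: first factor loading positive
  lab <- vapply(spec$pars, `[[`, "", "label")
  type <- vapply(spec$pars, `[[`, "", "type")
  if (any(type == "loading")) {
    first_l <- spec$free_ids[which(type == "loading")[1]]
    if (th[first_l] < 0) {
      flip <- unique(spec$free_ids[type %in% c("loading", "path")])
      th[flip] <- -th[flip]
    }
  }

  e <- s - sigma_of(spec, th)
  Delta <- jac(th)
  bread <- tryCatch(solve(crossprod(Delta, w * Delta)),
                    error = function(err) NULL)
  if (is.null(bread)) stopf("model is not identified (singular D'WD)")
  meat <- crossprod(w * Delta, Vsub %*% (w * Delta))
  covth <- bread %*% meat %*% bread
  se <- sqrt(pmax(diag(covth), 0))

  # free-parameter names: label of the first parameter in each set
  free_names <- vapply(seq_len(spec$n_free), function(f)
    lab[which(spec$free_ids == f)[1]], "")
  names(th) <- names(se) <- free_names

  full <- th[spec$free_ids]
  heywood <- any(type == "loading" & abs(full) > 1.01)
  inadmissible <- FALSE
  if (length(spec$targets)) {
    bfull <- full[type == "path"]
    inadmissible <- any(1 - bfull^2 < -1e-6)
  }
  if (any(type == "loading"))
    inadmissible <- inadmissible || any(1 - full[type == "loading"]^2 < -1e-6)

  df <- length(s) - spec$n_free
  fit <- structure(list(theta = th, se = se, vcov = covth,
                        fitval = best$f, residuals = e, df = df,
                        spec = spec, s = s, D = D, Vsub = Vsub,
                        Delta = Delta, converged = best$conv,
                        heywood = heywood, inadmissible = inadmissible),
                   class = "dwls_fit")
  rc <- residual_chisq(fit)
  fit$chisq <- rc$chisq
  fit$p <- rc$p
  if (heywood) warning("Heywood case: a factor loading exceeds 1 in magnitude")
  fit
}

#' Residual-based model chi-square
#'
#' T = e' Gamma^+ e with e the DWLS residuals and Gamma the sampling
#' covariance of the residuals: the modeled-element block of V projected
#' onto the residual space (rank = df, Moore-Penrose inverse).  A
#' just-identified model returns (0, 0, p = 1).
#'
#' @param fit a [fit_dwls()] result.
#' @param V_R optional override of the sampling covariance (defaults to the
#'   block stored in the fit).
#' @return list(chisq, df, p).
#' @export
residual_chisq <- function(fit, V_R = NULL) {
  stopifnot(inherits(fit, "dwls_fit"))
  df <- fit$df
  if (df == 0) return(list(chisq = 0, df = 0L, p = 1))
  Vsub <- if (is.null(V_R)) fit$Vsub else V_R
  w <- 1 / fit$D
  Delta <- fit$Delta
  B <- solve(crossprod(Delta, w * Delta))
  P <- diag(length(fit$s)) - Delta %*% B %*% t(w * Delta)
  G <- P %*% Vsub %*% t(P)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- seq_len(min(df, sum(eg$values > 1e-12 * max(eg$values, 0))))
  Ginv <- eg$vectors[, keep, drop = FALSE] %*%
    ((1 / eg$values[keep]) * t(eg$vectors[, keep, drop = FALSE]))
  T <- drop(crossprod(fit$residuals, Ginv %*% fit$residuals))
  list(chisq = max(T, 0), df = df,
       p = stats::pchisq(max(T, 0), df, lower.tail = FALSE))
}

#' One-degree-of-freedom Wald test for equality of two correlations
#'
#' chi^2 = (r1 - r2)^2 / (var1 + var2 - 2 cov12) with variances and the
#' covariance read from the sampling covariance of vech(R); asymptotically
#' equivalent to the equality-constrained model chi-square and kept as an
#' independent cross-check.
#'
#' @param R correlation matrix (named).
#' @param V_R sampling covariance of vech(R).
#' @param pair1,pair2 character or integer pairs indexing the two
#'   correlations.
#' @return list(chisq, df = 1, p, r1, r2).
#' @export
wald_equality_test <- function(R, V_R, pair1, pair2) {
  k <- nrow(R)
  as_idx <- function(p) {
    if (is.character(p)) p <- match(p, rownames(R))
    if (anyNA(p)) stopf("unknown variable in pair")
    p
  }
  p1 <- as_idx(pair1); p2 <- as_idx(pair2)
  i1 <- vech_index(p1[1], p1[2], k)
  i2 <- vech_index(p2[1], p2[2], k)
  r1 <- R[p1[1], p1[2]]; r2 <- R[p2[1], p2[2]]
  den <- V_R[i1, i1] + V_R[i2, i2] - 2 * V_R[i1, i2]
  if (den <= 0) stopf("degenerate contrast: non-positive variance of r1 - r2")
  chisq <- (r1 - r2)^2 / den
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE), r1 = r1, r2 = r2)
}

#' Genetic multiple regression with correlated predictors
#'
#' Standardized partial effects beta = Rxx^-1 rxy, with delta-method
#' standard errors propagating the sampling covariance of the involved
#' correlations.  Refuses to fit when the predictors are nearly collinear
#' (|r| >= 0.95), where partial effects lose interpretability.
#'
#' @param R correlation matrix (named).
#' @param V_R sampling covariance of vech(R).
#' @param outcome outcome variable name.
#' @param predictors character vector of predictor names (two in the
#'   canonical stratified-GWAS use).
#' @param collinearity_limit refusal threshold on |r| between predictors.
#' @return object of class `gmr`: beta, se, z, p, predictor correlation.
#' @export
genetic_multiple_regression <- function(R, V_R, outcome, predictors,
                                        collinearity_limit = 0.95) {
  iy <- match(outcome, rownames(R))
  ix <- match(predictors, rownames(R))
  if (anyNA(c(iy, ix))) stopf("unknown outcome or predictor name")
  k <- nrow(R)
  np <- length(ix)
  if (np < 2) stopf("need at least two predictors")
  Rxx <- R[ix, ix, drop = FALSE]
  off <- Rxx[upper.tri(Rxx)]
  if (any(abs(off) >= collinearity_limit)) {
    cmb <- utils::combn(np, 2)
    bad <- which(abs(off) >= collinearity_limit)[1]
    stopf("collinear predictors (%s, %s): |r| = %.3f >= %.2f; excluded for limited interpretability",
          predictors[cmb[1, bad]], predictors[cmb[2, bad]],
          abs(off[bad]), collinearity_limit)
  }
  rxy <- R[ix, iy]
  beta <- solve(Rxx, rxy)

  # delta method over the involved correlations (predictor pairs first,
  # then predictor-outcome), in vech positions of the full matrix
  cmb <- utils::combn(ix, 2)
  upairs <- rbind(t(cmb), cbind(ix, iy))
  uidx <- vech_index(pmax(upairs[, 1], upairs[, 2]),
                     pmin(upairs[, 1], upairs[, 2]), k)
  beta_of <- function(u) {
    Rx <- diag(np)
    for (q in seq_len(ncol(cmb))) {
      Rx[cmb[1, q] == ix, cmb[2, q] == ix] <- u[q]
      Rx[cmb[2, q] == ix, cmb[1, q] == ix] <- u[q]
    }
    ry <- u[ncol(cmb) + seq_len(np)]
    solve(Rx, ry)
  }
  u0 <- c(R[cbind(cmb[1, ], cmb[2, ])], rxy)
  h <- 1e-7
  J <- matrix(0, np, length(u0))
  for (q in seq_along(u0)) {
    up <- u0; um <- u0
    up[q] <- up[q] + h; um[q] <- um[q] - h
    J[, q] <- (beta_of(up) - beta_of(um)) / (2 * h)
  }
  Vu <- V_R[uidx, uidx, drop = FALSE]
  covb <- J %*% Vu %*% t(J)
  se <- sqrt(pmax(diag(covb), 0))
  z <- beta / se
  structure(list(outcome = outcome, predictors = predictors,
                 beta = stats::setNames(as.numeric(beta), predictors),
                 se = stats::setNames(se, predictors),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 r_predictors = Rxx, vcov = covb),
            class = "gmr")
}

#' @export
print.gmr <- function(x, ...) {
  cat(sprintf("Genetic multiple regression: %s ~ %s\n", x$outcome,
              paste(x$predictors, collapse = " + ")))
  print(data.frame(beta = round(x$beta, 4), se = round(x$se, 4),
                   p = signif(x$p, 3)))
  invisible(x)
}

#' Common-factor residualization model
#'
#' Fits one common genetic factor (unit variance, free loadings) over the
#' indicator traits, with regression paths from the factor to each target
#' and free residual covariances among the targets.  The standardized
#' residual covariances are the factor-adjusted associations between
#' targets: what remains of each pairwise genetic correlation after the
#' shared factor variance is removed.
#'
#' @param R correlation matrix (named).
#' @param V_R sampling covariance of vech(R).
#' @param indicators at least three factor indicator traits.
#' @param targets traits regressed on the factor (disjoint from the
#'   indicators).
#' @param ... passed to [fit_dwls()].
#' @return a `dwls_fit` augmented with `paths` (factor -> target, with SE)
#'   and `residual_assoc` (per target pair: raw and standardized residual
#'   association, SE, and the covariance matrix of the standardized
#'   values).
#' @export
factor_residual_model <- function(R, V_R, indicators, targets, ...) {
  if (length(indicators) < 3) stopf("need at least 3 factor indicators")
  if (length(intersect(indicators, targets)))
    stopf("targets must be disjoint from indicators")
  spec <- model_spec(variables = c(indicators, targets),
                     factor_indicators = indicators,
                     factor_targets = targets)
  fit <- fit_dwls(spec, R, V_R, ...)

  bn <- sprintf("b_%s", targets)
  fit$paths <- data.frame(target = targets,
                          beta = as.numeric(fit$theta[bn]),
                          se = as.numeric(fit$se[bn]),
                          stringsAsFactors = FALSE)
  if (length(targets) >= 2) {
    cmb <- utils::combn(targets, 2)
    std_of <- function(th) {
      apply(cmb, 2, function(pr) {
        b1 <- th[sprintf("b_%s", pr[1])]
        b2 <- th[sprintf("b_%s", pr[2])]
        cc <- th[sprintf("c_%s_%s",
                         spec$variables[min(match(pr, spec$variables))],
                         spec$variables[max(match(pr, spec$variables))])]
        cc / sqrt(max(1 - b1^2, 1e-8) * max(1 - b2^2, 1e-8))
      })
    }
    a0 <- std_of(fit$theta)
    h <- 1e-6
    J <- matrix(0, length(a0), length(fit$theta))
    for (q in seq_along(fit$theta)) {
      tp <- fit$theta; tm <- fit$theta
      tp[q] <- tp[q] + h; tm[q] <- tm[q] - h
      J[, q] <- (std_of(tp) - std_of(tm)) / (2 * h)
    }
    cova <- J %*% fit$vcov %*% t(J)
    raw <- vapply(seq_len(ncol(cmb)), function(q) {
      pr <- cmb[, q]
      cn <- sprintf("c_%s_%s",
                    spec$variables[min(match(pr, spec$variables))],
                    spec$variables[max(match(pr, spec$variables))])
      as.numeric(fit$theta[cn])
    }, 0)
    fit$residual_assoc <- data.frame(t1 = cmb[1, ], t2 = cmb[2, ],
                                     raw = raw, std = as.numeric(a0),
                                     se_std = sqrt(pmax(diag(cova), 0)),
                                     stringsAsFactors = FALSE)
    fit$residual_vcov <- cova
  }
  fit
}

#' @export
print.dwls_fit <- function(x, ...) {
  cat(sprintf("DWLS fit: %d free parameter(s), df = %d, chisq = %.4g, p = %.3g\n",
              x$spec$n_free, x$df, x$chisq, x$p))
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
summary.dwls_fit <- function(object, ...) {
  cat(sprintf("DWLS fit (%s)\n",
              if (object$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = round(object$theta, 4),
                    se = round(object$se, 4),
                    z = round(object$theta / object$se, 2))
  print(tab)
  cat(sprintf("\nfitval = %.6g, df = %d, chisq = %.4g, p = %.3g\n",
              object$fitval, object$df, object$chisq, object$p))
  if (object$heywood) cat("warning: Heywood case\n")
  if (object$inadmissible) cat("warning: inadmissible solution\n")
  invisible(object)
}

#' @export
coef.dwls_fit <- function(object, ...) object$theta

#' @export
residuals.dwls_fit <- function(object, ...) object$residuals

#' @export
vcov.dwls_fit <- function(object, ...) object$vcov

#' @export
fitted.dwls_fit <- function(object, ...) object$s - object$residuals
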