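# Internal helpers shared across the estimator and model-fitting code.

#' Half-vectorization index
#'
#' Position of element (i, j), i >= j, of a symmetric k x k matrix in its
#' half-vectorization vech(S): columns of the lower triangle including the
#' diagonal, traversed left to right.  This ordering is shared by the
#' sampling covariance matrix, model Jacobians and residual vectors.
#'
#' @param i,j row and column index (order-insensitive).
#' @param k matrix dimension.
#' @return integer position in 1..k(k+1)/2.
#' @export
vech_index <- function(i, j, k) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  as.integer((lo - 1L) * k - (lo - 1L) * lo / 2 + hi)
}

#' Half-vectorize a symmetric matrix
#' @param S symmetric matrix.
#' @return numeric vector of length k(k+1)/2 in lower-triangle column order.
#' @export
vech <- function(S) S[lower.tri(S, diag = TRUE)]

#' Rebuild a symmetric matrix from its half-vectorization
#' @param v vech vector.
#' @param k matrix dimension.
#' @return symmetric k x k matrix.
#' @export
unvech <- function(v, k) {
  S <- matrix(0, k, k)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

# Pairs (i > j) in vech order restricted to off-diagonal elements.
offdiag_pairs <- function(k) {
  j <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  i <- unlist(lapply(seq_len(k - 1L), function(c) (c + 1L):k))
  cbind(i = i, j = j)
}

# Evaluate expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Symmetric matrix square root via eigen decomposition; tolerates a PSD
# matrix with tiny negative eigenvalues (clamped at zero).
psd_sqrt <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

# Smallest eigenvalue and, when negative, the off-diagonal pair carrying the
# largest weight in the offending eigenvector (for error messages).
psd_check <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  mine <- min(e$values)
  pair <- NULL
  if (mine < -tol && nrow(S) > 1L) {
    v <- e$vectors[, which.min(e$values)]
    w <- abs(outer(v, v))
    diag(w) <- -Inf
    ij <- arrayInd(which.max(w), dim(w))
    pair <- sort(ij[1, ])
  }
  list(min_eigen = mine, pair = pair, ok = mine >= -tol)
}

# Nearest positive semidefinite correlation matrix (eigenvalue clipping with
# unit-diagonal restoration, iterated a few times; Higham-style light).
nearest_psd_corr <- function(R, tol = 1e-10, iter = 50) {
  X <- R
  for (it in seq_len(iter)) {
    e <- eigen(X, symmetric = TRUE)
    if (min(e$values) >= -tol) break
    X <- e$vectors %*% (pmax(e$values, tol) * t(e$vectors))
    d <- sqrt(diag(X))
    X <- X / outer(d, d)
    diag(X) <- 1
  }
  X <- (X + t(X)) / 2
  diag(X) <- 1
  X
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
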