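# Internal numerical helpers shared across modules.

# Round half away from zero (symmetric rounding), unlike base round()'s
# round-half-even. Used for epoch start placement.
.round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library internals never perturb user-level streams.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Rank-truncated singular value decomposition.
#
# For small problems this is plain LAPACK svd().  For the large delay-embedded
# matrices produced by stacked DMD (~900 x 950) the full dgesdd call dominates
# the whole pipeline, so the factorization is computed instead from the
# symmetric eigendecomposition of the smaller Gram matrix (method of
# snapshots).  The Gram route squares the condition number, so its numerical
# rank cut is sqrt-scaled relative to the direct route.
.tsvd <- function(X, rank) {
  m <- nrow(X)
  n <- ncol(X)
  empty <- list(u = matrix(0, m, 0), d = numeric(0), v = matrix(0, n, 0))
  if (m == 0L || n == 0L || !any(X != 0)) {
    return(empty)
  }
  if (min(m, n) <= 300L) {
    s <- svd(X)
    r <- sum(s$d >= 1e-10 * s$d[1L])
    r <- min(r, rank)
    if (r == 0L) return(empty)
    return(list(u = s$u[, seq_len(r), drop = FALSE],
                d = s$d[seq_len(r)],
                v = s$v[, seq_len(r), drop = FALSE]))
  }
  if (m <= n) {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    r <- min(sum(d >= 1e-7 * d[1L]), rank)
    if (r == 0L) return(empty)
    u <- e$vectors[, seq_len(r), drop = FALSE]
    d <- d[seq_len(r)]
    v <- sweep(crossprod(X, u), 2L, d, "/")
    list(u = u, d = d, v = v)
  } else {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    r <- min(sum(d >= 1e-7 * d[1L]), rank)
    if (r == 0L) return(empty)
    v <- e$vectors[, seq_len(r), drop = FALSE]
    d <- d[seq_len(r)]
    u <- sweep(X %*% v, 2L, d, "/")
    list(u = u, d = d, v = v)
  }
}

# Minimum-norm complex least squares via SVD, tolerant of rank deficiency.
.lstsq_complex <- function(A, b, tol = 1e-12) {
  if (ncol(A) == 0L) return(complex(0))
  s <- svd(A)
  keep <- s$d >= tol * max(s$d, 0)
  if (!any(keep)) return(rep(0 + 0i, ncol(A)))
  u <- s$u[, keep, drop = FALSE]
  v <- s$v[, keep, drop = FALSE]
  d <- s$d[keep]
  v %*% ((Conj(t(u)) %*% b) / d)
}
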