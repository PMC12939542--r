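#' Fit a 95%-variance PCA projection on training vectors
#'
#' Mean-centers on the training columns and retains the minimal number of
#' principal components whose cumulative explained-variance fraction
#' reaches `var_target`. Component signs are fixed by forcing the
#' largest-magnitude loading of each component to be positive.
#'
#' @param Z_train Matrix with training vectors in columns (>= 2 columns).
#' @param var_target Cumulative explained-variance threshold (default 0.95).
#' @return Object of class `pca_projection` with fields `mean`, `rotation`
#'   (p x q), `q`, `var_fraction` (full spectrum), `cum_fraction`.
#' @export
fit_pca_95 <- function(Z_train, var_target = 0.95) {
  stopifnot(is.matrix(Z_train), ncol(Z_train) >= 2L)
  mu <- rowMeans(Z_train)
  Xc <- Z_train - mu
  s <- svd(Xc)
  ev <- s$d^2 / (ncol(Z_train) - 1)
  total <- sum(ev)
  if (total <= 0) stop("rank-0 training data: no variance to project")
  frac <- ev / total
  cum <- cumsum(frac)
  q <- which(cum >= var_target)[1L]
  rot <- s$u[, seq_len(q), drop = FALSE]
  for (j in seq_len(q)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(mean = mu, rotation = rot, q = q,
                 var_fraction = frac, cum_fraction = cum),
            class = "pca_projection")
}

#' Apply a fitted PCA projection
#'
#' Centers with the training mean and projects onto the retained
#' components.
#'
#' @param proj A `pca_projection`.
#' @param Z Matrix with vectors in columns (same dimension as training).
#' @return Matrix with one row per input column and `q` coordinate columns
#'   (ready for [standardize()]).
#' @export
apply_pca <- function(proj, Z) {
  stopifnot(inherits(proj, "pca_projection"))
  if (nrow(Z) != length(proj$mean)) {
    stop(sprintf("dimension mismatch: projection expects %d rows, got %d",
                 length(proj$mean), nrow(Z)))
  }
  out <- crossprod(Z - proj$mean, proj$rotation)
  colnames(out) <- paste0("PC", seq_len(proj$q))
  out
}
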