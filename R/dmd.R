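#' DMD parameters
#'
#' @param stack_size Delay-embedding depth S (number of consecutive samples
#'   concatenated per snapshot column; default 48).
#' @param rank SVD truncation rank R (default 100).
#' @param fs Sampling rate in Hz.
#' @return Object of class `dmd_params`.
#' @export
dmd_params <- function(stack_size = 48L, rank = 100L, fs) {
  stopifnot(stack_size >= 1L, rank >= 1L, fs > 0)
  structure(list(stack_size = as.integer(stack_size),
                 rank = as.integer(rank), fs = fs),
            class = "dmd_params")
}

#' Delay embedding of a multichannel segment
#'
#' Builds the stacked snapshot pair (X, X') with channel-major stacking:
#' column t of X concatenates x(t), x(t+1), ..., x(t+S-1) over all channels
#' (channel index fastest), and X' is X advanced by one sample.
#'
#' @param segment Numeric matrix, M channels x N samples.
#' @param S Stack size; requires `N > S`.
#' @return List with matrices `X` and `Xp`, each (M*S) x (N-S).
#' @export
delay_embed <- function(segment, S) {
  stopifnot(is.matrix(segment))
  m <- nrow(segment)
  n <- ncol(segment)
  if (n <= S) {
    stop(sprintf("insufficient samples: need more than S = %d, got %d", S, n))
  }
  ns <- n - S
  X <- matrix(0, m * S, ns)
  Xp <- matrix(0, m * S, ns)
  for (s in seq_len(S)) {
    rows <- (s - 1L) * m + seq_len(m)
    X[rows, ] <- segment[, s:(s + ns - 1L), drop = FALSE]
    Xp[rows, ] <- segment[, (s + 1L):(s + ns), drop = FALSE]
  }
  list(X = X, Xp = Xp)
}

.new_modeset <- function(modes, modes_aug, eigvals, omegas, freqs_hz,
                         amplitudes, fs, rectified = FALSE) {
  structure(list(modes = modes, modes_aug = modes_aug, eigvals = eigvals,
                 omegas = omegas, freqs_hz = freqs_hz,
                 amplitudes = amplitudes, fs = fs, rectified = rectified),
            class = "dmd_modeset")
}

#' @export
print.dmd_modeset <- function(x, ...) {
  cat(sprintf("<dmd_modeset> %d modes x %d channels (%srectified), fs = %g Hz\n",
              length(x$eigvals), nrow(x$modes),
              if (x$rectified) "" else "not ", x$fs))
  invisible(x)
}

#' Fit exact DMD on a snapshot pair
#'
#' Rank-truncated SVD `X = U S V^T` (rank `min(R, numerical rank)`), reduced
#' operator `A~ = U^T X' V S^-1`, eigenpairs `(lambda_j, w_j)`, exact-DMD
#' augmented modes `phi_j = X' V S^-1 w_j`, continuous-time eigenvalues
#' `omega_j = fs log(lambda_j)` (principal branch), and amplitudes `c_j`
#' solving least squares against the first snapshot. Channel-space modes are
#' the first M rows of the augmented modes; eigenvalues at zero are
#' discarded.
#'
#' @param X,Xp Snapshot matrices from [delay_embed()].
#' @param params [dmd_params()]; `n_channels` defaults to
#'   `nrow(X) / stack_size`.
#' @param n_channels Number of physical channels M.
#' @return A `dmd_modeset` (empty, not an error, for an all-zero input).
#' @export
fit_dmd <- function(X, Xp, params, n_channels = NULL) {
  stopifnot(inherits(params, "dmd_params"),
            all(dim(X) == dim(Xp)))
  if (is.null(n_channels)) {
    n_channels <- nrow(X) %/% params$stack_size
  }
  m <- as.integer(n_channels)
  fs <- params$fs
  sv <- .tsvd(X, params$rank)
  if (length(sv$d) == 0L) {
    return(.new_modeset(matrix(0 + 0i, m, 0), matrix(0 + 0i, nrow(X), 0),
                        complex(0), complex(0), numeric(0), complex(0), fs))
  }
  XpVSi <- sweep(Xp %*% sv$v, 2L, sv$d, "/")
  Atilde <- crossprod(sv$u, XpVSi)
  eg <- eigen(Atilde)
  lambda <- eg$values
  keep <- Mod(lambda) > 1e-14
  lambda <- lambda[keep]
  W <- eg$vectors[, keep, drop = FALSE]
  phi_aug <- XpVSi %*% W
  omega <- fs * log(lambda)
  freqs <- abs(Im(omega)) / (2 * pi)
  amps <- as.complex(.lstsq_complex(phi_aug, X[, 1L]))
  .new_modeset(phi_aug[seq_len(m), , drop = FALSE], phi_aug,
               lambda, omega, freqs, amps, fs)
}

#' Rectify channel-space modes (common-mode removal)
#'
#' Subtracts the across-channel complex mean from every mode column,
#' removing sensor-uniform components while leaving pairwise inter-channel
#' phase differences of the residual unchanged. Idempotent and linear.
#'
#' @param ms A `dmd_modeset`, or a bare complex M x J mode matrix.
#' @return Same type as the input, with rectified channel-space modes.
#' @export
rectify_modes <- function(ms) {
  if (is.matrix(ms)) {
    if (ncol(ms) == 0L) return(ms)
    return(sweep(ms, 2L, colMeans(ms), "-"))
  }
  stopifnot(inherits(ms, "dmd_modeset"))
  ms$modes <- rectify_modes(ms$modes)
  ms$rectified <- TRUE
  ms
}

#' Per-segment stacked DMD with rectification
#'
#' Convenience wrapper: [delay_embed()], [fit_dmd()], [rectify_modes()].
#'
#' @param segment M x N numeric matrix (one 2 s segment).
#' @param params [dmd_params()].
#' @return A rectified `dmd_modeset`.
#' @export
segment_modes <- function(segment, params) {
  emb <- delay_embed(segment, params$stack_size)
  rectify_modes(fit_dmd(emb$X, emb$Xp, params, n_channels = nrow(segment)))
}
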