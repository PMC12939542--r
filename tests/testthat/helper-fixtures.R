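# Shared fixtures, all built in code.

# Linear system with known complex eigenvalues: block-diagonal 2x2
# rotation-decay blocks mixed into M channels by a well-conditioned matrix.
# Returns the trajectory (M x N) and the analytic eigen content.
make_linear_system <- function(freqs_hz, decays, fs, M, N, seed = 1) {
  stopifnot(length(freqs_hz) == length(decays))
  r <- 2L * length(freqs_hz)
  stopifnot(M >= r)
  blocks <- mapply(function(f, d) {
    th <- 2 * pi * f / fs
    rho <- exp(d / fs)
    rho * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  }, freqs_hz, decays, SIMPLIFY = FALSE)
  A <- matrix(0, r, r)
  for (i in seq_along(blocks)) {
    idx <- (2L * i - 1L):(2L * i)
    A[idx, idx] <- blocks[[i]]
  }
  withr::with_seed(seed, {
    C <- matrix(rnorm(M * r), M, r) + diag(1, M, r)
    z0 <- rnorm(r)
  })
  Z <- matrix(0, r, N)
  Z[, 1L] <- z0
  for (t in 2:N) Z[, t] <- A %*% Z[, t - 1L]
  list(x = C %*% Z, A = A,
       eig = eigen(A, only.values = TRUE)$values,
       freqs = freqs_hz, decays = decays)
}

# Hand-built mode set (bypasses fit_dmd) for descriptor-level tests.
make_modeset <- function(modes, freqs_hz, fs = 500, amplitudes = NULL) {
  omegas <- complex(real = 0, imaginary = 2 * pi * freqs_hz)
  if (is.null(amplitudes)) amplitudes <- rep(1 + 0i, length(freqs_hz))
  structure(list(modes = modes, modes_aug = modes,
                 eigvals = exp(omegas / fs), omegas = omegas,
                 freqs_hz = freqs_hz, amplitudes = amplitudes,
                 fs = fs, rectified = TRUE),
            class = "dmd_modeset")
}

# Two bundles of `each` nearly identical positive vectors on disjoint
# supports (between-bundle cosine dissimilarity = 1).
make_two_bundles <- function(each = 12L, p = 24L, jitter = 1e-3, seed = 5) {
  withr::with_seed(seed, {
    b1 <- c(rep(1, p / 2), rep(0, p / 2))
    b2 <- c(rep(0, p / 2), rep(1, p / 2))
    Z1 <- sapply(seq_len(each), function(i) b1 + jitter * abs(rnorm(p)) * b1)
    Z2 <- sapply(seq_len(each), function(i) b2 + jitter * abs(rnorm(p)) * b2)
    cbind(Z1, Z2)
  })
}

# Minimal recording whose samples encode their own index, for segmentation
# coverage checks.
make_index_recording <- function(n_seg = 19L, fs = 50, onset = 0,
                                 extra_samples = 0L, M = 2L) {
  n <- round(2 * fs)
  total <- round(onset * fs) + n_seg * n + extra_samples
  sig <- (rbind(seq_len(total), -seq_len(total)) * 1.0)[seq_len(M), , drop = FALSE]
  new_recording("S1", "CN", sig, fs, stim_onset = onset,
                stim_offset = onset + n_seg * 2 + 0.5,
                channel_names = paste0("Ch", seq_len(M)))
}

# Fake loso_result for metric aggregation tests.
make_fake_folds <- function(spec_rows, task_name = "AD_vs_CN") {
  task <- task_spec(task_name)
  folds <- lapply(spec_rows, function(r) {
    list(subject = r$subject, true_label = r$true,
         pred = r$pred, margins = r$margins)
  })
  structure(folds, class = "loso_result", task = task, features = "cpp")
}

# Tiny synthetic cohort + descriptor settings used by pipeline tests.
tiny_config <- function(...) {
  args <- list(n_ad = 2L, n_cn = 2L, duration = 42, seed = 9L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# Brute-force medoid oracle (independent of cosine_dissimilarity); the
# self-dissimilarity is exactly zero so ties break like the implementation.
brute_medoid <- function(Z, group) {
  nrm <- sqrt(colSums(Z^2))
  tot <- sapply(group, function(i) {
    sum(sapply(group, function(j) {
      if (i == j) 0 else
        1 - sum(Z[, i] * Z[, j]) / (nrm[i] * nrm[j])
    }))
  })
  group[which.min(tot)]
}

tiny_descriptors <- function(co) {
  compute_descriptors(co$recordings, stack_size = 8L, rank = 24L, P = 20L)
}
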