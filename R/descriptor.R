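#' Band-filter a mode set and collapse conjugate pairs
#'
#' Keeps modes with eigenfrequency in the closed interval `[lo, hi]` Hz and
#' retains one representative per complex-conjugate pair (the member with
#' non-negative imaginary continuous-time eigenvalue).
#'
#' @param ms A `dmd_modeset`.
#' @param lo,hi Band edges in Hz (defaults 4 and 40).
#' @return A filtered `dmd_modeset` (possibly with zero modes).
#' @export
band_filter_modes <- function(ms, lo = 4, hi = 40) {
  stopifnot(inherits(ms, "dmd_modeset"))
  keep <- ms$freqs_hz >= lo & ms$freqs_hz <= hi & Im(ms$omegas) >= 0
  ms$modes <- ms$modes[, keep, drop = FALSE]
  ms$modes_aug <- ms$modes_aug[, keep, drop = FALSE]
  ms$eigvals <- ms$eigvals[keep]
  ms$omegas <- ms$omegas[keep]
  ms$freqs_hz <- ms$freqs_hz[keep]
  ms$amplitudes <- ms$amplitudes[keep]
  ms
}

# Piecewise-linear resampling weights from a J-point to a P-point
# normalized index grid, j -> (j-1)/(J-1).
.interp_weights <- function(J, P) {
  if (J == 1L) return(matrix(1, 1L, P))
  xin <- (seq_len(J) - 1) / (J - 1)
  xout <- (seq_len(P) - 1) / (P - 1)
  idx <- findInterval(xout, xin, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), J - 1L)
  tt <- (xout - xin[idx]) / (xin[idx + 1L] - xin[idx])
  W <- matrix(0, J, P)
  W[cbind(idx, seq_len(P))] <- 1 - tt
  W[cbind(idx + 1L, seq_len(P))] <- W[cbind(idx + 1L, seq_len(P))] + tt
  W
}

#' Fixed-width mode image of one segment
#'
#' Sorts the retained modes by ascending eigenfrequency (ties broken by
#' descending magnitude l2 norm), takes channel-wise mode magnitudes, and
#' linearly interpolates each channel row from the J-point to a fixed
#' P-point normalized index grid. With `weight = "amplitude"` (the
#' default) each mode's channel magnitudes are scaled by its modal
#' amplitude `|c_j|`, so the image reflects each mode's energy
#' contribution to the modal expansion of the segment (raw exact-DMD mode
#' columns are unit-normalized eigenvector images and carry no energy);
#' this is what the subsequent epoch-level min-max rescale cancels when
#' the input signal is globally rescaled.
#'
#' @param ms A band-filtered `dmd_modeset`.
#' @param P Mode-axis resolution (default 50).
#' @param weight `"amplitude"` (scale mode j by `|c_j|`) or `"none"`.
#' @return Non-negative M x P matrix; all-zero (with a warning) if the mode
#'   set is empty.
#' @export
mode_image <- function(ms, P = 50L, weight = c("amplitude", "none")) {
  stopifnot(inherits(ms, "dmd_modeset"))
  weight <- match.arg(weight)
  m <- nrow(ms$modes)
  J <- length(ms$freqs_hz)
  if (J == 0L) {
    warning("no retained modes; returning an all-zero mode image")
    return(matrix(0, m, P))
  }
  mags <- abs(ms$modes)
  if (weight == "amplitude") {
    mags <- sweep(mags, 2L, abs(ms$amplitudes), "*")
  }
  ord <- order(ms$freqs_hz, -sqrt(colSums(mags^2)))
  mags <- mags[, ord, drop = FALSE]
  mags %*% .interp_weights(J, as.integer(P))
}

#' Epoch-level descriptor
#'
#' Elementwise mean of the segment mode images within one epoch, followed by
#' a global min-max rescale of the mean matrix to `[0, 1]` and column-wise
#' vectorization (channel index fastest). A constant mean matrix maps to the
#' all-zero descriptor with a warning.
#'
#' @param images List of T mode images (M x P each).
#' @param subject_id,label,epoch_index Optional metadata carried along.
#' @return Object of class `epoch_descriptor` with fields `image` (M x P in
#'   `[0,1]`), `vector` (length M*P), and the metadata.
#' @export
epoch_descriptor <- function(images, subject_id = NA_character_,
                             label = NA_character_, epoch_index = NA_integer_) {
  stopifnot(length(images) >= 1L)
  dims <- dim(images[[1L]])
  stopifnot(all(vapply(images, function(x) identical(dim(x), dims), logical(1))))
  mean_img <- Reduce(`+`, images) / length(images)
  rng <- range(mean_img)
  if (rng[2L] > rng[1L]) {
    img <- (mean_img - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    warning("degenerate (constant) epoch mean; descriptor set to all zeros")
    img <- matrix(0, dims[1L], dims[2L])
  }
  structure(
    list(image = img, vector = as.vector(img), subject_id = subject_id,
         label = label, epoch_index = as.integer(epoch_index)),
    class = "epoch_descriptor"
  )
}

#' Stage 1: compute epoch descriptors for a set of recordings
#'
#' For each recording: eligibility screening and epoch placement, one
#' stacked DMD per non-overlapping segment, band filtering, segment mode
#' images, and epoch-level aggregation. DMD is computed once per segment
#' even when epochs overlap.
#'
#' @param recordings List of `eeg_recording` objects.
#' @param stack_size,rank DMD settings (defaults 48 and 100).
#' @param P Mode-axis resolution (default 50).
#' @param band Frequency band in Hz kept for descriptors (default `c(4, 40)`).
#' @param seg_len Segment length in seconds (default 2).
#' @param n_epochs,segs_per_epoch Epoch layout (defaults 10 and 10).
#' @param verbose Print one line per subject.
#' @return Object of class `descriptor_set`: `Z` (epochs x M*P matrix of
#'   vectorized descriptors), `meta` (data frame with `subject_id`,
#'   `label`, `epoch_index`), and `col_freq` (epochs x P matrix giving the
#'   mean eigenfrequency in Hz represented by each descriptor column; the
#'   mode axis is a frequency-quantile axis, so this mapping differs across
#'   epochs).
#' @export
compute_descriptors <- function(recordings, stack_size = 48L, rank = 100L,
                                P = 50L, band = c(4, 40), seg_len = 2.0,
                                n_epochs = 10L, segs_per_epoch = 10L,
                                verbose = FALSE) {
  rows <- list()
  meta <- list()
  cfreq <- list()
  for (rec in recordings) {
    params <- dmd_params(stack_size, rank, rec$fs)
    plan <- epoch_plan(rec, seg_len, n_epochs, segs_per_epoch)
    segs <- segment_matrices(rec, plan)
    modesets <- lapply(segs, function(seg) {
      band_filter_modes(segment_modes(seg, params), band[1L], band[2L])
    })
    images <- lapply(modesets, function(ms) {
      if (length(ms$freqs_hz) == 0L) {
        matrix(0, nrow(ms$modes), P)
      } else {
        mode_image(ms, P)
      }
    })
    seg_cf <- lapply(modesets, .column_freqs, P = P)
    for (i in seq_along(plan$start_indices)) {
      s <- plan$start_indices[i]
      span <- s + seq_len(plan$segs_per_epoch) - 1L
      d <- epoch_descriptor(images[span],
                            subject_id = rec$subject_id, label = rec$label,
                            epoch_index = i)
      rows[[length(rows) + 1L]] <- d$vector
      cfreq[[length(cfreq) + 1L]] <- colMeans(do.call(rbind, seg_cf[span]),
                                              na.rm = TRUE)
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, label = rec$label, epoch_index = i,
        stringsAsFactors = FALSE)
    }
    if (verbose) {
      message(sprintf("descriptors: subject %s (%s), %d segments",
                      rec$subject_id, rec$label, plan$n_segments_usable))
    }
  }
  structure(list(Z = do.call(rbind, rows), meta = do.call(rbind, meta),
                 col_freq = do.call(rbind, cfreq)),
            class = "descriptor_set")
}

# Mean eigenfrequency represented by each of the P descriptor columns for
# one segment's retained modes (the same interpolation as mode_image applied
# to the sorted frequencies themselves).
.column_freqs <- function(ms, P) {
  J <- length(ms$freqs_hz)
  if (J == 0L) return(rep(NA_real_, P))
  mags <- abs(ms$modes)
  if (length(ms$amplitudes) == J) {
    mags <- sweep(mags, 2L, abs(ms$amplitudes), "*")
  }
  ord <- order(ms$freqs_hz, -sqrt(colSums(mags^2)))
  as.vector(crossprod(.interp_weights(J, as.integer(P)), ms$freqs_hz[ord]))
}

#' Low-frequency mass fraction of dictionary atoms
#'
#' For each atom, the fraction of its descriptor mass lying in columns
#' whose represented eigenfrequency (the medoid source epoch's
#' column-frequency map) is below `below` Hz. Requires the dictionary to
#' have been learned with `ids` equal to row indices into `dset`.
#'
#' @param dset The `descriptor_set` the dictionary was learned from.
#' @param B A `cpp_dictionary` with numeric row-index provenance ids.
#' @param below Frequency bound in Hz (default 12).
#' @return Numeric vector, one mass fraction per atom.
#' @export
atom_low_freq_mass <- function(dset, B, below = 12) {
  stopifnot(inherits(dset, "descriptor_set"), inherits(B, "cpp_dictionary"))
  rows <- as.integer(B$medoid_source_ids)
  stopifnot(!anyNA(rows), all(rows >= 1L), all(rows <= nrow(dset$Z)))
  P <- ncol(dset$col_freq)
  vapply(seq_len(ncol(B$atoms)), function(k) {
    a <- B$atoms[, k]
    img <- matrix(a, length(a) %/% P, P)
    low <- which(dset$col_freq[rows[k], ] < below)
    sum(img[, low]) / sum(img)
  }, numeric(1))
}

#' Write / read a descriptor set as tab-separated text
#'
#' One row per epoch: `subject_id`, `label`, `epoch_index`, then the M*P
#' feature columns.
#'
#' @param dset A `descriptor_set`.
#' @param path File path.
#' @return `path` invisibly (writer); a `descriptor_set` (reader).
#' @export
write_descriptors <- function(dset, path) {
  stopifnot(inherits(dset, "descriptor_set"))
  tab <- cbind(dset$meta, as.data.frame(dset$Z))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  meta <- tab[, c("subject_id", "label", "epoch_index")]
  meta$subject_id <- as.character(meta$subject_id)
  Z <- as.matrix(tab[, -(1:3), drop = FALSE])
  dimnames(Z) <- NULL
  structure(list(Z = Z, meta = meta), class = "descriptor_set")
}
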