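#' Count usable non-overlapping segments in a stimulus interval
#'
#' The segment grid is anchored at the interval onset; a partial trailing
#' segment is discarded.
#'
#' @param onset,offset Stimulus interval bounds in seconds.
#' @param seg_len Segment length in seconds (default 2 s).
#' @return Integer segment count, `floor((offset - onset) / seg_len)`.
#' @examples
#' count_usable_segments(15.08, 93.16) # 39
#' @export
count_usable_segments <- function(onset, offset, seg_len = 2.0) {
  if (!is.numeric(seg_len) || seg_len <= 0) stop("`seg_len` must be positive")
  if (offset <= onset) {
    stop("invalid interval: non-positive stimulus duration")
  }
  as.integer(floor((offset - onset) / seg_len))
}

#' Evenly spaced epoch start indices
#'
#' Places `n_epochs` epochs of `segs_per_epoch` consecutive segments at
#' evenly spaced 1-based start indices over `[1, n_seg - segs_per_epoch + 1]`:
#' `s_i = 1 + (i - 1) (n_seg - segs_per_epoch) / (n_epochs - 1)`, rounded
#' half away from zero. Eligibility requires
#' `n_seg >= n_epochs + segs_per_epoch - 1` (19 under defaults), which also
#' guarantees the rounded starts are strictly increasing.
#'
#' @param n_seg Number of usable segments.
#' @param n_epochs Number of epochs to place (default 10).
#' @param segs_per_epoch Segments per epoch (default 10).
#' @return Integer vector of `n_epochs` strictly increasing start indices.
#' @export
epoch_start_indices <- function(n_seg, n_epochs = 10L, segs_per_epoch = 10L) {
  n_seg <- as.integer(n_seg)
  min_seg <- n_epochs + segs_per_epoch - 1L
  if (n_seg < min_seg) {
    stop(sprintf(
      "ineligible recording: %d usable segments, but at least %d are required for %d epochs of %d segments",
      n_seg, min_seg, n_epochs, segs_per_epoch))
  }
  if (n_epochs == 1L) return(1L)
  i <- seq_len(n_epochs)
  s <- 1 + (i - 1) * (n_seg - segs_per_epoch) / (n_epochs - 1)
  s <- as.integer(.round_half_away(s))
  stopifnot(all(diff(s) > 0L), s[1L] >= 1L,
            s[n_epochs] <= n_seg - segs_per_epoch + 1L)
  s
}

#' Build an epoch plan for a recording
#'
#' Screens the recording for eligibility and fixes the epoch placement.
#'
#' @param rec An [new_recording()] object.
#' @param seg_len Segment length in seconds.
#' @param n_epochs,segs_per_epoch Epoch layout (defaults 10 and 10).
#' @return Object of class `epoch_plan` with fields `n_segments_usable`,
#'   `segment_len_samples`, `n_epochs`, `segs_per_epoch`, `start_indices`.
#' @export
epoch_plan <- function(rec, seg_len = 2.0, n_epochs = 10L,
                       segs_per_epoch = 10L) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_seg <- count_usable_segments(rec$stim_onset, rec$stim_offset, seg_len)
  starts <- epoch_start_indices(n_seg, n_epochs, segs_per_epoch)
  structure(
    list(n_segments_usable = n_seg,
         segment_len_samples = as.integer(round(seg_len * rec$fs)),
         n_epochs = as.integer(n_epochs),
         segs_per_epoch = as.integer(segs_per_epoch),
         start_indices = starts),
    class = "epoch_plan"
  )
}

#' Segment matrices of the stimulus interval
#'
#' Cuts the stimulus interval into its non-overlapping segments. Segment k
#' (1-based) covers samples `onset_sample + (k-1)*N + 1 : onset_sample + k*N`
#' where N is the segment length in samples and the grid is anchored at the
#' stimulus onset.
#'
#' @param rec An `eeg_recording`.
#' @param plan An `epoch_plan` for `rec`.
#' @return List of `n_segments_usable` matrices, each M x N.
#' @export
segment_matrices <- function(rec, plan) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(plan, "epoch_plan"))
  n <- plan$segment_len_samples
  o <- as.integer(floor(rec$stim_onset * rec$fs))
  need <- o + plan$n_segments_usable * n
  if (ncol(rec$signal) < need) {
    stop(sprintf(
      "truncated signal: %d samples present but %d required to cover the stimulus interval",
      ncol(rec$signal), need))
  }
  lapply(seq_len(plan$n_segments_usable), function(k) {
    rec$signal[, o + (k - 1L) * n + seq_len(n), drop = FALSE]
  })
}

#' Extract epochs as lists of segment matrices
#'
#' Epochs are an indexing layer over the shared segment grid: epoch i holds
#' segments `s_i, ..., s_i + segs_per_epoch - 1`, and the same segment may
#' appear in several epochs. Per-segment computations (DMD) are therefore
#' done once on [segment_matrices()] and only referenced here.
#'
#' @inheritParams segment_matrices
#' @return List of `n_epochs` lists, each containing `segs_per_epoch`
#'   M x N segment matrices.
#' @export
extract_epochs <- function(rec, plan) {
  segs <- segment_matrices(rec, plan)
  lapply(plan$start_indices, function(s) {
    segs[s + seq_len(plan$segs_per_epoch) - 1L]
  })
}
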