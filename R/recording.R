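#' Standard 19-channel 10-20 montage
#'
#' Channel order used throughout the package for study-conformant 19-channel
#' recordings. Inputs whose channel names are a permutation of this list are
#' reordered to match it.
#'
#' @format Character vector of 19 electrode names.
#' @export
montage_1020 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                  "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                  "Fz", "Cz", "Pz")

#' Construct an EEG recording
#'
#' Bundles one subject's multichannel signal with its stimulus interval and
#' diagnostic label. Signals are stored channels-by-samples in microvolts.
#' If the channel names are a permutation of [montage_1020], rows are
#' reordered to the montage order so that downstream mode descriptors are
#' channel-aligned across subjects.
#'
#' @param subject_id Subject identifier (string).
#' @param label Diagnostic label, one of `"AD"`, `"FTD"`, `"CN"`.
#' @param signal Numeric matrix, M channels x samples (microvolts), M >= 2.
#' @param fs Sampling rate in Hz (positive).
#' @param stim_onset,stim_offset Stimulus interval bounds in seconds,
#'   `stim_offset > stim_onset`.
#' @param channel_names Optional character vector of M channel names.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(subject_id, label, signal, fs,
                          stim_onset, stim_offset, channel_names = NULL) {
  label <- match.arg(label, c("AD", "FTD", "CN"))
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix (channels x samples)")
  }
  if (nrow(signal) < 2L) stop("at least 2 channels are required")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  if (stim_offset <= stim_onset) {
    stop("invalid interval: stim_offset must exceed stim_onset")
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(signal) == length(montage_1020)) {
      montage_1020
    } else {
      paste0("Ch", seq_len(nrow(signal)))
    }
  }
  if (length(channel_names) != nrow(signal)) {
    stop("`channel_names` length must match the number of channels")
  }
  if (setequal(channel_names, montage_1020) &&
      !identical(channel_names, montage_1020)) {
    ord <- match(montage_1020, channel_names)
    signal <- signal[ord, , drop = FALSE]
    channel_names <- montage_1020
  }
  rownames(signal) <- channel_names
  structure(
    list(subject_id = as.character(subject_id), label = label,
         signal = signal, fs = fs,
         stim_onset = stim_onset, stim_offset = stim_offset,
         channel_names = channel_names),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s [%s]: %d ch x %d samples @ %g Hz, stim [%.2f, %.2f] s\n",
              x$subject_id, x$label, nrow(x$signal), ncol(x$signal), x$fs,
              x$stim_onset, x$stim_offset))
  invisible(x)
}

#' Read a BIDS-style events table
#'
#' Reads a tab-separated events file with columns `onset`, `duration`, and
#' `trial_type` (additional columns are kept).
#'
#' @param path Path to the events.tsv file.
#' @return A data frame of events.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("events table not found: %s", path))
  }
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop(sprintf("events table %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  ev
}

#' Stimulus interval from an events table
#'
#' The stimulus interval is the tightest window covering all events whose
#' `trial_type` matches `pattern` (case-insensitive regular expression).
#'
#' @param events Data frame as returned by [read_events_tsv()].
#' @param pattern Regular expression selecting stimulation events.
#' @return Numeric vector `c(onset, offset)` in seconds.
#' @export
stim_interval_from_events <- function(events, pattern = "stim") {
  sel <- grepl(pattern, events$trial_type, ignore.case = TRUE)
  if (!any(sel)) stop("no events matching pattern: ", pattern)
  c(onset = min(events$onset[sel]),
    offset = max(events$onset[sel] + events$duration[sel]))
}

#' Write / read a recording as a portable text container
#'
#' Plain-text serialization used for synthetic data: `#`-prefixed header
#' lines carry the metadata, followed by a tab-separated channels-in-columns
#' signal block. Lossless up to the stated number of significant digits.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param digits Significant digits for the signal block.
#' @return `path`, invisibly (writer); an `eeg_recording` (reader).
#' @export
write_recording_tsv <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  hdr <- c(
    sprintf("# subject_id=%s", rec$subject_id),
    sprintf("# label=%s", rec$label),
    sprintf("# fs=%.10g", rec$fs),
    sprintf("# stim_onset=%.10g", rec$stim_onset),
    sprintf("# stim_offset=%.10g", rec$stim_offset)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(rec$channel_names, collapse = "\t"), con)
  utils::write.table(signif(t(rec$signal), digits), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path))
  lines <- readLines(path, n = 64L)
  hdr_idx <- grep("^#", lines)
  kv <- sub("^#\\s*", "", lines[hdr_idx])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  skip <- max(hdr_idx)
  ch <- strsplit(lines[skip + 1L], "\t")[[1L]]
  sig <- as.matrix(utils::read.table(path, sep = "\t", skip = skip + 1L))
  dimnames(sig) <- NULL
  new_recording(meta$subject_id, meta$label, t(sig),
                fs = as.numeric(meta$fs),
                stim_onset = as.numeric(meta$stim_onset),
                stim_offset = as.numeric(meta$stim_offset),
                channel_names = ch)
}

#' Stimulus interval annotations for the 88-subject photic-stimulation cohort
#'
#' Per-subject visual-stimulation onset/offset times (seconds) for the
#' 88-subject AD/FTD/CN photic-stimulation EEG cohort analysed by the
#' pipeline, as published with the study data. Used for eligibility
#' screening worked examples and tests.
#'
#' @return Data frame with columns `id`, `group`, `onset`, `offset`,
#'   `duration`.
#' @export
stimulus_intervals <- function() {
  path <- system.file("extdata", "stim_intervals.tsv", package = "dmdcpp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tab$duration <- tab$offset - tab$onset
  tab
}
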