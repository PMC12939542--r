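#' Synthetic photic-stimulation EEG configuration
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a photic-entrainment sinusoid whose frequency cycles through the
#' stimulation set in blocks, a background alpha component, pink (1/f)
#' noise, and a class-dependent attenuation plus fragmentation of
#' low-frequency (4-12 Hz) structure. Class labels affect only
#' `low_freq_gain` and `fragmentation_rate`; all other machinery is shared,
#' so there is no leakage channel besides the stated effects.
#'
#' @param n_ad,n_ftd,n_cn Subjects per class.
#' @param n_channels Number of channels (default 19; uses [montage_1020]).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration Stimulated span in seconds (default 90).
#' @param stim_freqs Stimulation frequencies in Hz cycled over blocks.
#' @param block_len Stimulation block length in seconds (default 15).
#' @param seed Cohort master seed; per-subject seeds are derived as
#'   `seed + 104729 * subject_counter`.
#' @param low_freq_gain Named per-class multiplier applied to components in
#'   `low_band` (defaults CN 1.0, FTD 0.6, AD 0.35).
#' @param fragmentation_rate Named per-class probability that a 2 s segment
#'   contains a phase reset of the alpha component (defaults CN 0.05,
#'   FTD 0.3, AD 0.6).
#' @param noise_sd Pink-noise standard deviation in microvolts.
#' @param alpha_amp,alpha_freq Alpha component amplitude (microvolts) and
#'   frequency (Hz).
#' @param stim_amp Entrainment amplitude in microvolts (before topography
#'   and class gain).
#' @param stim_onset Onset of the stimulated span in seconds.
#' @param low_band Frequency band in Hz subject to the class gain.
#' @param seg_len Segment length used for the fragmentation grid.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_ad = 8L, n_ftd = 0L, n_cn = 8L,
                         n_channels = 19L, fs = 500, duration = 90,
                         stim_freqs = c(5, 10, 15, 20, 30),
                         block_len = 15, seed = 1L,
                         low_freq_gain = c(AD = 0.35, FTD = 0.6, CN = 1.0),
                         fragmentation_rate = c(AD = 0.6, FTD = 0.3, CN = 0.05),
                         noise_sd = 10, alpha_amp = 20, alpha_freq = 10,
                         stim_amp = 15, stim_onset = 1.0,
                         low_band = c(4, 12), seg_len = 2.0) {
  stopifnot(all(low_freq_gain >= 0), all(fragmentation_rate >= 0),
            all(fragmentation_rate <= 1), duration > 0, fs > 0)
  structure(as.list(environment()), class = "synth_config")
}

# Posterior-dominant amplitude topography; fixed, hence identical across
# classes and subjects.
.channel_topography <- function(channel_names) {
  w <- c(Fp1 = 0.4, Fp2 = 0.4, F3 = 0.6, F4 = 0.6, C3 = 0.9, C4 = 0.9,
         P3 = 1.3, P4 = 1.3, O1 = 1.5, O2 = 1.5, F7 = 0.5, F8 = 0.5,
         T3 = 0.8, T4 = 0.8, T5 = 1.2, T6 = 1.2, Fz = 0.7, Cz = 1.0,
         Pz = 1.4)
  if (all(channel_names %in% names(w))) {
    unname(w[channel_names])
  } else {
    seq(0.5, 1.5, length.out = length(channel_names))
  }
}

# Pink (1/f) noise by FFT spectral shaping, rescaled to unit sd.
.pink_noise <- function(n) {
  W <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  m <- pmin(k, n - k)
  s <- ifelse(m == 0, 0, 1 / sqrt(m))
  x <- Re(stats::fft(W * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited stochastic rhythm (unit sd): white noise spectrally masked to
# [lo, hi] Hz with a Gaussian emphasis around the alpha peak.
.band_rhythm <- function(n, fs, lo, hi, peak_f, peak_w = 1.5, peak_gain = 3) {
  W <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  mask <- as.numeric(f >= lo & f <= hi) *
    (1 + peak_gain * exp(-(f - peak_f)^2 / (2 * peak_w^2)))
  x <- Re(stats::fft(W * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Generate one synthetic subject
#'
#' Deterministic given `(label, cfg, subject_seed)`; the caller's RNG state
#' is untouched. The signal is the sum of (i) a photic-entrainment
#' sinusoid whose frequency cycles through `stim_freqs` in blocks, (ii) a
#' band-limited (4-12 Hz, alpha-peaked) background rhythm, built
#' independently per 2 s segment and shared across channels through the
#' posterior topography plus a channel-specific part, and (iii) pink
#' noise. The class gain multiplies every component inside `low_band`
#' (the rhythm, and entrainment blocks at low stimulation frequencies).
#' Fragmentation erases the rhythm over a random contiguous half of a
#' segment with per-segment probability `fragmentation_rate`, emulating
#' the within-segment collapse of low-frequency structure.
#'
#' @param label Class label (`"AD"`, `"FTD"`, `"CN"`).
#' @param cfg A [synth_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier (defaults to `label` + seed).
#' @return An `eeg_recording`.
#' @export
generate_subject <- function(label, cfg, subject_seed,
                             subject_id = paste0(label, "_", subject_seed)) {
  stopifnot(inherits(cfg, "synth_config"))
  label <- match.arg(label, c("AD", "FTD", "CN"))
  gain <- cfg$low_freq_gain[[label]]
  frag <- cfg$fragmentation_rate[[label]]
  fs <- cfg$fs
  m <- cfg$n_channels
  channel_names <- if (m == 19L) montage_1020 else paste0("Ch", seq_len(m))
  topo <- .channel_topography(channel_names)
  n_total <- round((cfg$stim_onset + cfg$duration + 1.0) * fs)
  tt <- (seq_len(n_total) - 1) / fs
  in_low <- function(f) f >= cfg$low_band[1L] & f <= cfg$low_band[2L]
  .with_seed(subject_seed, {
    # photic entrainment: blocks cycling through the stimulation set
    stim <- numeric(n_total)
    b_start <- cfg$stim_onset
    b_idx <- 0L
    offset <- cfg$stim_onset + cfg$duration
    while (b_start < offset) {
      f <- cfg$stim_freqs[(b_idx %% length(cfg$stim_freqs)) + 1L]
      b_end <- min(b_start + cfg$block_len, offset)
      sel <- tt >= b_start & tt < b_end
      amp <- cfg$stim_amp * if (in_low(f)) gain else 1
      stim[sel] <- amp * sin(2 * pi * f * (tt[sel] - b_start))
      b_start <- b_end
      b_idx <- b_idx + 1L
    }
    # low-frequency background rhythm on the 2 s segment grid
    nseg_samp <- round(cfg$seg_len * fs)
    o <- floor(cfg$stim_onset * fs)
    edges <- unique(c(seq(o %% nseg_samp, n_total, by = nseg_samp), n_total))
    if (edges[1L] > 0) edges <- c(0, edges)
    rhythm <- matrix(0, m, n_total)
    lo <- cfg$low_band[1L]
    hi <- cfg$low_band[2L]
    for (e in seq_len(length(edges) - 1L)) {
      i0 <- edges[e] + 1L
      i1 <- edges[e + 1L]
      n <- i1 - i0 + 1L
      if (n < 8L) next
      shared <- .band_rhythm(n, fs, lo, hi, cfg$alpha_freq)
      seg <- outer(topo, shared)
      for (ch in seq_len(m)) {
        seg[ch, ] <- seg[ch, ] + 0.5 * .band_rhythm(n, fs, lo, hi,
                                                    cfg$alpha_freq)
      }
      if (stats::runif(1) < frag) {
        gap0 <- 1L + floor(stats::runif(1, 0, n / 2))
        seg[, gap0:(gap0 + floor(n / 2) - 1L)] <- 0
      }
      rhythm[, i0:i1] <- seg
    }
    rhythm <- cfg$alpha_amp * gain * rhythm
    sig <- rhythm + outer(topo, stim)
    for (ch in seq_len(m)) {
      sig[ch, ] <- sig[ch, ] + cfg$noise_sd * .pink_noise(n_total)
    }
    new_recording(subject_id, label, sig, fs,
                  stim_onset = cfg$stim_onset, stim_offset = offset,
                  channel_names = channel_names)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Per-subject seeds are derived from the master seed by a fixed counter
#' scheme (`cfg$seed + 104729 * counter`), so cohorts are reproducible and
#' individual subjects can be regenerated in isolation.
#'
#' @param cfg A [synth_config()].
#' @return List with `recordings` (list of `eeg_recording`) and `labels`
#'   (data frame `subject_id`, `label`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  counts <- c(AD = cfg$n_ad, FTD = cfg$n_ftd, CN = cfg$n_cn)
  recordings <- list()
  labels <- list()
  counter <- 0L
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      counter <- counter + 1L
      sid <- sprintf("%s%02d", cl, i)
      rec <- generate_subject(cl, cfg, cfg$seed + 104729L * counter,
                              subject_id = sid)
      recordings[[sid]] <- rec
      labels[[length(labels) + 1L]] <- data.frame(
        subject_id = sid, label = cl, stringsAsFactors = FALSE)
    }
  }
  list(recordings = recordings, labels = do.call(rbind, labels))
}
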