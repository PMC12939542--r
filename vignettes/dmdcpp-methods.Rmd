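---
title: "Clustered pattern projection on dynamic-mode EEG descriptors: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered pattern projection on dynamic-mode EEG descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Eyes-open photic-stimulation EEG is a hard setting for dementia
classification: posterior alpha is suppressed, responses are driven by a
stimulus whose frequency changes across blocks, and in Alzheimer's disease
(AD) the visually entrained and background low-frequency activity is not
replaced by a stable alternative pattern but progressively attenuated and
fragmented. Methods that assume a stable spectral template (band power,
covariance averages) degrade badly here. The approach implemented in this
package treats the *breakdown itself* as a recurrent, learnable structure:
short-window dynamical decompositions are clustered into class-specific
prototype dictionaries, and each analysis window is encoded by its
geometric alignment (cosine similarity) with those prototypes.

## Pipeline overview

For each subject with a usable stimulus interval:

1. **Segmentation.** The stimulus interval is cut into non-overlapping 2 s
   segments (grid anchored at the onset, trailing remainder discarded).
   Eligibility requires at least 19 segments (38 s); ten 20 s epochs of ten
   consecutive segments are placed at evenly spaced start indices
   `s_i = 1 + (i-1)(N_seg - 10)/9`, rounded half away from zero. Epochs are
   an indexing layer: the decomposition is computed once per segment even
   where epochs overlap.
2. **Stacked DMD.** Each segment (M channels x N samples) is
   delay-embedded with stack size S (channel-major: a snapshot column
   concatenates S consecutive samples over all channels), and exact
   dynamic mode decomposition with truncation rank R yields modes,
   discrete eigenvalues, continuous eigenvalues `omega = fs log lambda`
   (principal branch), eigenfrequencies `|Im omega| / 2 pi`, and modal
   amplitudes solved against the first snapshot. Channel-space modes are
   the first M rows of the augmented modes, then *rectified* by removing
   the across-channel complex mean of each mode (suppressing
   volume-conduction/common-mode inflation while preserving inter-sensor
   phase relations).
3. **Epoch descriptors.** Modes with eigenfrequency in [4, 40] Hz are
   retained (one representative per conjugate pair), sorted by ascending
   frequency, and the amplitude-weighted channel magnitudes are linearly
   interpolated onto a fixed P-column grid. Segment images are averaged
   within each epoch and the mean image is min-max rescaled to [0, 1],
   giving a descriptor matrix in `[0,1]^(M x P)` vectorized column-wise
   (channel index fastest).
4. **Dictionary learning.** Per class, the l2-normalized training
   descriptors are clustered by complete-linkage hierarchical clustering
   under cosine dissimilarity, cut top-down: a node splits only if its
   size exceeds `tau_sup`, its merge height exceeds `h_stop`, and both
   children hold at least `n_min` members; terminal nodes with at least
   `n_min` members survive, and each contributes its medoid (the member
   minimizing total within-group dissimilarity) as a dictionary atom.
   Atoms are observed epochs, never synthetic averages.
5. **Projection features and classification.** Every epoch is encoded by
   its cosine similarities to the two class dictionaries (blocks
   concatenated), standardized with train-only mean/sd, and classified by
   a linear SVM under leave-one-subject-out (LOSO) validation. Subject
   decisions are majority votes over the ten test epochs, with exact ties
   rejected; decided-subject accuracy carries a Wilson 95% interval.
6. **Reliability.** Signed geometric margins `(w'x + b)/||w||` are
   aggregated within subjects (median absolute margin, IQR, sign
   consistency `|P(m>0) - 0.5|`), subjects are grouped by outcome
   (TP/FP/TN/FN), and group gaps are tested by median-difference
   permutation tests with Cliff's delta effect sizes.

A PCA baseline replaces step 4-5's projection with train-fitted PCA
retaining 95% of variance, all else identical, to isolate the
contribution of the clustered projection.

## Fixed parameters

| Parameter | Default | Meaning |
|---|---|---|
| segment length | 2 s (N = 1000 samples at 500 Hz) | DMD window |
| T | 10 | segments per epoch (20 s epochs) |
| S | 48 | delay-embedding stack size |
| R | 100 | SVD truncation rank |
| P | 50 | mode-axis resolution of descriptors |
| band | [4, 40] Hz | retained eigenfrequencies |
| tau_sup | 11 | cluster split support threshold |
| n_min | 10 | minimum surviving cluster size |
| h_stop | 0.2 | dendrogram split height threshold |
| C | 1 | SVM box constraint |

These are the framework's published operating point; `default_config()`
carries them and `run_pipeline()` threads them through.

## Numerical choices

- **Truncated SVD.** Small problems use LAPACK `svd()` with a relative
  rank cut of 1e-10. The delay-embedded matrices of a full-size run
  (912 x 952) dominate compute, so there the factorization comes from the
  symmetric eigendecomposition of the smaller Gram matrix (method of
  snapshots), which is an order of magnitude faster; because that route
  squares the condition number, its rank cut is 1e-7. Both cuts guard
  the `Sigma^-1` inversion; modes at exactly zero eigenvalue are dropped.
- **Amplitude weighting of mode images.** Exact-DMD augmented modes
  `X' V Sigma^-1 w` with unit eigenvectors are *invariant to global
  scaling of the input signal*: their magnitudes are eigenvector images,
  not energies. An image built from raw `|phi|` therefore cannot express
  "low-frequency structure attenuated in AD", and the min-max rescale
  would have nothing to cancel. Each mode's channel magnitudes are
  therefore weighted by its modal amplitude `|c_j|` (the least-squares
  coefficient against the first snapshot), so the image reflects each
  mode's contribution to the modal expansion of the segment. This was
  verified to be load-bearing: without the weighting, synthetic cohorts
  with strong class effects are classified at chance; with it the same
  cohorts separate cleanly. `mode_image(..., weight = "none")` restores
  the unweighted behaviour.
- **Rounding of epoch starts.** Round half away from zero; for every
  eligible segment count this yields strictly increasing starts with
  first = 1 and last = N_seg - 9 (asserted, not assumed).
- **Degenerate inputs.** All-zero segments produce empty mode sets (not
  errors); empty band-filtered mode sets produce all-zero images with a
  warning; a constant epoch mean maps to the all-zero descriptor with a
  warning; constant feature columns are mapped to zero by the sigma-floor
  (1e-12) rule of the train-only standardizer; zero-norm vectors are hard
  errors wherever a cosine is required.
- **Ties.** Medoid ties break to the lowest index; mode-sorting ties
  break by descending magnitude norm; exact majority-vote ties are
  rejections. The SVM is solved by deterministic cyclic dual coordinate
  descent (no shuffling), so the entire pipeline is bit-reproducible.
- **Standardization.** Sample (n-1) standard deviation, train split only.
- **Permutation tests.** When all `choose(n1+n2, n1)` group reassignments
  fit within the permutation budget the null is enumerated exactly
  (`p = k / n_splits`); otherwise `n_perm` random reassignments are drawn
  and the add-one correction `p = (1 + k)/(1 + n_perm)` avoids p = 0.
  IQRs use type-7 percentiles. Cliff's delta confidence intervals use a
  seeded percentile bootstrap (2000 draws) within groups - a convention,
  not a reproduction target. Tests are two-sided at alpha = 0.1,
  reported, never used for gating.
- **PCA baseline.** Train-mean centering; components to 95% cumulative
  variance; component signs fixed by making the largest-magnitude loading
  positive.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method
assumes, not any particular dataset:

- a photic-entrainment sinusoid whose frequency cycles through
  {5, 10, 15, 20, 30} Hz in 15 s blocks over a 90 s stimulated span,
  with a fixed posterior-dominant amplitude topography;
- a band-limited (4-12 Hz) stochastic background rhythm with a spectral
  peak at 10 Hz, built per 2 s segment as a topography-shared source plus
  channel-specific components. A *pure* 10 Hz tone was deliberately
  rejected: it occupies roughly one of the fifty descriptor columns, so
  class effects on it are invisible at realistic noise levels; a
  band-limited rhythm expresses "low-frequency structure" across the
  whole lower quarter of the mode image, which is also closer to real
  theta-alpha background activity;
- pink (1/f) noise per channel (10 uV sd);
- class effects, and only these: a multiplicative gain on all 4-12 Hz
  components (CN 1.0, FTD 0.6, AD 0.35) and a per-segment fragmentation
  probability (CN 0.05, FTD 0.3, AD 0.6) that erases the rhythm over a
  random contiguous half of the segment, emulating within-window collapse
  of low-frequency organization. Everything else is label-independent,
  so there is no leakage channel besides the stated effects.

Rhythm sd 20 uV, entrainment amplitude 15 uV and noise sd 10 uV are in
the range of real scalp EEG and were fixed once. Determinism: per-subject
seeds derive from the master seed by a fixed counter scheme, and the
caller's RNG state is never consumed.

What the generator does **not** emulate: artifacts, inter-channel noise
correlation and volume conduction, non-stationary vigilance drift,
heterogeneous stimulus protocols, or any property of real dementia EEG
beyond the stated low-frequency attenuation/fragmentation. A green
end-to-end test therefore establishes that the pipeline recovers a known
class-dependent degradation of low-frequency dynamics above chance under
LOSO - not that it reproduces clinical performance figures. Published
accuracies from the real 88-subject cohort enter the test suite only as
printed confusion-matrix arithmetic (worked examples), never as outcomes
of this pipeline.

## Open design points resolved here

- *Eligibility boundary*: an interval of exactly 38 s yields 19 segments
  and is eligible; the grid anchors at onset and discards the remainder.
- *Split condition (a)* uses strict `size > tau_sup` ("exceeds"); with
  tau_sup = 11 and n_min = 10 a node of 11 could never split anyway.
- *Retention*: a node that fails the split test is kept iff its size is
  at least n_min, so every atom summarizes at least n_min epochs;
  members of discarded small nodes are not reassigned.
- *Column-to-frequency mapping*: the mode axis is a frequency-quantile
  axis, so "columns below 12 Hz" is epoch-dependent;
  `compute_descriptors()` records a per-epoch column-frequency map and
  `atom_low_freq_mass()` evaluates atoms against their own source
  epoch's map.
- *Margin convention*: geometric distance `(w'x + b)/||w||`, positive
  toward the task's positive class (AD, FTD, AD for the three tasks);
  the SVM cost defaults to 1.

## Known limitations

- No artifact rejection, filtering or re-referencing: inputs are assumed
  pre-cleaned.
- EDF/BrainVision ingestion is out of scope in this environment; use the
  plain-text recording container and BIDS-style `events.tsv`.
- Epoch-level metrics are reported for comparability but epochs within a
  subject are not independent samples; subject-level summaries are the
  meaningful unit.
- The divisive clustering is O(n^2) in training epochs; fine at cohort
  scale (hundreds of epochs), not designed for thousands of subjects.
- Reliability contrasts involving empty outcome groups (e.g. no false
  positives on an easy cohort) are skipped rather than imputed.
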