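#' Within-subject margin descriptors
#'
#' Three complementary summaries of one subject's epoch-wise signed margins:
#' confidence magnitude `median(|m|)`, dispersion `IQR(m)` (type-7
#' percentiles, 75th minus 25th), and sign consistency `|P(m > 0) - 0.5|`.
#'
#' @param margins Numeric vector of signed epoch margins (length >= 1).
#' @return Named numeric vector `c(med_abs, iqr, sign_cons)`.
#' @export
subject_descriptors <- function(margins) {
  stopifnot(length(margins) >= 1L)
  q <- stats::quantile(margins, c(0.25, 0.75), type = 7, names = FALSE)
  c(med_abs = stats::median(abs(margins)),
    iqr = q[2L] - q[1L],
    sign_cons = abs(mean(margins > 0) - 0.5))
}

#' Group decided subjects by classification outcome
#'
#' Decided subjects (majority vote, rejects excluded) are grouped into TP,
#' FN, TN, FP with respect to the task's positive class, and their margin
#' descriptors are computed.
#'
#' @param folds A `loso_result` from [run_task()].
#' @return Object of class `margin_records`: a data frame with one row per
#'   decided subject (`subject_id`, `outcome`, `med_abs`, `iqr`,
#'   `sign_cons`) plus a `margins` list attribute keyed by subject.
#' @export
outcome_grouping <- function(folds) {
  stopifnot(inherits(folds, "loso_result"))
  task <- attr(folds, "task")
  rows <- list()
  margins <- list()
  for (f in folds) {
    dec <- majority_vote(f$pred, task$classes)
    if (dec == "reject") next
    is_pos <- f$true_label == task$positive
    outcome <- if (is_pos) {
      if (dec == task$positive) "TP" else "FN"
    } else {
      if (dec == task$negative) "TN" else "FP"
    }
    d <- subject_descriptors(f$margins)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = f$subject, outcome = outcome,
      med_abs = d["med_abs"], iqr = d["iqr"], sign_cons = d["sign_cons"],
      row.names = NULL, stringsAsFactors = FALSE)
    margins[[f$subject]] <- f$margins
  }
  rec <- do.call(rbind, rows)
  structure(rec, class = c("margin_records", class(rec)), margins = margins)
}

#' Permutation test for a median gap
#'
#' Test statistic `median(a) - median(b)`; the null distribution reassigns
#' the pooled values between the two groups with the original group sizes
#' fixed. When all distinct splits can be enumerated within `n_perm`
#' (`choose(n1 + n2, n1) <= n_perm`), the test is exact:
#' `p = #(|gap*| >= |gap|) / n_splits`. Otherwise `n_perm` random
#' reassignments are drawn and the add-one finite-sample correction is
#' applied: `p = (1 + #(|gap*| >= |gap|)) / (1 + n_perm)`. Two-sided.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param n_perm Number of permutations (default 20000).
#' @param seed Optional seed for the sampled branch (the caller's RNG state
#'   is restored afterwards).
#' @return List with `delta_med`, `p_value`, `n_perm`, and `exact`.
#' @export
permutation_median_gap <- function(a, b, n_perm = 20000L, seed = NULL) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  obs <- stats::median(a) - stats::median(b)
  pool <- c(a, b)
  n <- length(pool)
  n1 <- length(a)
  thresh <- abs(obs) - 1e-12
  if (choose(n, n1) <= n_perm) {
    splits <- utils::combn(n, n1)
    gaps <- apply(splits, 2L, function(idx) {
      stats::median(pool[idx]) - stats::median(pool[-idx])
    })
    p <- sum(abs(gaps) >= thresh) / ncol(splits)
    return(list(delta_med = obs, p_value = p, n_perm = ncol(splits),
                exact = TRUE))
  }
  draw <- function() {
    gaps <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, n1)
      gaps[i] <- stats::median(pool[idx]) - stats::median(pool[-idx])
    }
    gaps
  }
  gaps <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  p <- (1 + sum(abs(gaps) >= thresh)) / (1 + n_perm)
  list(delta_med = obs, p_value = p, n_perm = n_perm, exact = FALSE)
}

#' Cliff's delta effect size with bootstrap confidence interval
#'
#' `delta = (#(a_i > b_j) - #(a_i < b_j)) / (n1 n2)`; ties contribute zero.
#' The confidence interval is a percentile bootstrap resampling within
#' groups.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param n_boot Bootstrap draws (default 2000); set to 0 to skip the CI.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap (caller's RNG restored).
#' @return List with `delta`, `ci`, `n1`, `n2`.
#' @export
cliffs_delta <- function(a, b, n_boot = 2000L, conf = 0.95, seed = NULL) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  dstat <- function(x, y) {
    cmp <- outer(x, y, "-")
    (sum(cmp > 0) - sum(cmp < 0)) / (length(x) * length(y))
  }
  delta <- dstat(a, b)
  ci <- c(lo = NA_real_, hi = NA_real_)
  if (n_boot > 0L) {
    boot <- function() {
      reps <- numeric(n_boot)
      for (i in seq_len(n_boot)) {
        reps[i] <- dstat(a[sample.int(length(a), replace = TRUE)],
                         b[sample.int(length(b), replace = TRUE)])
      }
      reps
    }
    reps <- if (is.null(seed)) boot() else .with_seed(seed, boot())
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
    ci <- c(lo = ci[1L], hi = ci[2L])
  }
  list(delta = delta, ci = ci, n1 = length(a), n2 = length(b))
}

#' Margin-based reliability report
#'
#' For each margin descriptor and each outcome contrast (TP vs FP among
#' predicted positives, TN vs FN among predicted negatives): median gap,
#' permutation p-value, and Cliff's delta with bootstrap CI. Comparisons
#' with an empty group are skipped.
#'
#' @param folds A `loso_result`.
#' @param n_perm Permutations per test (default 20000).
#' @param n_boot Bootstrap draws for the Cliff's delta CI.
#' @param seed Seed for permutation and bootstrap resampling.
#' @return Data frame with one row per descriptor x contrast.
#' @export
reliability_report <- function(folds, n_perm = 20000L, n_boot = 2000L,
                               seed = 7L) {
  rec <- outcome_grouping(folds)
  contrasts <- list(c("TP", "FP"), c("TN", "FN"))
  descriptors <- c("med_abs", "iqr", "sign_cons")
  out <- list()
  for (d in descriptors) {
    for (ct in contrasts) {
      g1 <- rec[[d]][rec$outcome == ct[1L]]
      g2 <- rec[[d]][rec$outcome == ct[2L]]
      if (length(g1) == 0L || length(g2) == 0L) next
      pt <- permutation_median_gap(g1, g2, n_perm = n_perm, seed = seed)
      cd <- cliffs_delta(g1, g2, n_boot = n_boot, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        descriptor = d, compare = paste(ct, collapse = "-"),
        delta_med = pt$delta_med, p_perm = pt$p_value,
        cliffs_delta = cd$delta, ci_lo = cd$ci["lo"], ci_hi = cd$ci["hi"],
        n1 = length(g1), n2 = length(g2),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(descriptor = character(0), compare = character(0),
                      delta_med = numeric(0), p_perm = numeric(0),
                      cliffs_delta = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), n1 = integer(0), n2 = integer(0)))
  }
  do.call(rbind, out)
}
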