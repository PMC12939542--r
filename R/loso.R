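#' Binary task specification
#'
#' The three tasks and their fixed positive classes: AD for AD vs. CN,
#' FTD for FTD vs. CN, AD for AD vs. FTD.
#'
#' @param name One of `"AD_vs_CN"`, `"FTD_vs_CN"`, `"AD_vs_FTD"`.
#' @return Object of class `task_spec` with fields `name`, `classes`
#'   (positive first), `positive`, `negative`.
#' @export
task_spec <- function(name = c("AD_vs_CN", "FTD_vs_CN", "AD_vs_FTD")) {
  name <- match.arg(name)
  classes <- switch(name,
                    AD_vs_CN = c("AD", "CN"),
                    FTD_vs_CN = c("FTD", "CN"),
                    AD_vs_FTD = c("AD", "FTD"))
  structure(list(name = name, classes = classes,
                 positive = classes[1L], negative = classes[2L]),
            class = "task_spec")
}

#' Leave-one-subject-out folds
#'
#' @param subject_ids Character vector of distinct subject identifiers.
#' @return List of folds, each `list(train = ids, test = id)`.
#' @export
loso_folds <- function(subject_ids) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (length(subject_ids) < 2L) stop("at least 2 subjects are required")
  lapply(subject_ids, function(s) {
    list(train = setdiff(subject_ids, s), test = s)
  })
}

#' Majority vote with rejection
#'
#' The class receiving strictly more than half of the epoch votes wins;
#' an exact tie abstains (`"reject"`).
#'
#' @param labels Character vector of per-epoch predicted labels.
#' @param classes The task's two class labels.
#' @return One of the two classes or `"reject"`.
#' @export
majority_vote <- function(labels, classes) {
  stopifnot(length(labels) >= 1L)
  n <- length(labels)
  k1 <- sum(labels == classes[1L])
  k2 <- sum(labels == classes[2L])
  if (k1 * 2L > n) classes[1L] else if (k2 * 2L > n) classes[2L] else "reject"
}

#' Run one binary task under leave-one-subject-out validation
#'
#' Per fold, class dictionaries (or the PCA projection) and the feature
#' standardization are learned on the training subjects only; a linear SVM
#' is fit on the standardized features and evaluated on the held-out
#' subject's epochs, producing predicted labels and signed geometric
#' margins (positive toward the task's positive class).
#'
#' @param dset A `descriptor_set` from [compute_descriptors()].
#' @param task A [task_spec()] (or its name).
#' @param cparams [cluster_params()] for dictionary learning.
#' @param features `"cpp"` (clustered pattern projection) or `"pca"`
#'   (95%-variance PCA baseline on the same descriptors).
#' @param cost SVM box constraint (default 1).
#' @return Object of class `loso_result`: a list of per-fold results
#'   (`subject`, `true_label`, `pred`, `margins`), with the task attached
#'   as an attribute.
#' @export
run_task <- function(dset, task, cparams = cluster_params(),
                     features = c("cpp", "pca"), cost = 1) {
  features <- match.arg(features)
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(dset, "descriptor_set"), inherits(task, "task_spec"))
  sel <- dset$meta$label %in% task$classes
  Z <- dset$Z[sel, , drop = FALSE]
  meta <- dset$meta[sel, , drop = FALSE]
  subjects <- unique(meta$subject_id)
  if (length(unique(meta$label)) < 2L) {
    stop("both task classes must be present in the descriptor set")
  }
  folds <- loso_folds(subjects)
  res <- lapply(folds, function(fold) {
    tr <- meta$subject_id %in% fold$train
    te <- meta$subject_id == fold$test
    if (length(unique(meta$label[tr])) < 2L) {
      stop(sprintf("fold %s: a task class is absent from the training split",
                   fold$test))
    }
    Htr_hte <- .stage2_features(Z, meta, tr, te, task, cparams, features)
    y <- ifelse(meta$label[tr] == task$positive, 1, -1)
    model <- linear_svm(Htr_hte$train, y, cost = cost)
    m <- svm_margin(model, Htr_hte$test)
    pred <- ifelse(m > 0, task$positive, task$negative)
    list(subject = fold$test,
         true_label = meta$label[te][1L],
         pred = pred,
         margins = m)
  })
  structure(res, class = "loso_result", task = task, features = features)
}

# Stage 2 feature construction for one fold: clustered pattern projection or
# the PCA-95% baseline, both fitted on the training rows only.
.stage2_features <- function(Z, meta, tr, te, task, cparams, features) {
  if (features == "cpp") {
    mk_ids <- function(rows) {
      paste0(meta$subject_id[rows], ":", meta$epoch_index[rows])
    }
    tr_rows <- which(tr)
    B <- lapply(task$classes, function(cl) {
      rows <- tr_rows[meta$label[tr_rows] == cl]
      learn_dictionary(t(Z[rows, , drop = FALSE]), cparams,
                       class_label = cl, ids = mk_ids(rows))
    })
    ftr <- build_feature_table(t(Z[tr, , drop = FALSE]), B[[1L]], B[[2L]],
                               split = "train")
    fte <- build_feature_table(t(Z[te, , drop = FALSE]), B[[1L]], B[[2L]],
                               split = "test")
    std <- standardize(ftr, fte)
    list(train = std$train$H, test = std$test$H)
  } else {
    proj <- fit_pca_95(t(Z[tr, , drop = FALSE]))
    ftr <- structure(list(H = apply_pca(proj, t(Z[tr, , drop = FALSE])),
                          meta = NULL, split = "train"),
                     class = "feature_table")
    fte <- structure(list(H = apply_pca(proj, t(Z[te, , drop = FALSE])),
                          meta = NULL, split = "test"),
                     class = "feature_table")
    std <- standardize(ftr, fte)
    list(train = std$train$H, test = std$test$H)
  }
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (positive).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1L, k >= 0L, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = center - half, hi = center + half)
}

# Metrics from one 2x2 confusion; division by zero reports 0 and flags it.
.prf <- function(tp, fp, fn) {
  div <- function(num, den) if (den == 0) 0 else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- div(2 * precision * recall, precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Epoch-level metrics from pooled confusion counts
#'
#' Per-class precision/recall/F1 (each class treated in turn as positive),
#' unweighted macro averages, and overall accuracy.
#'
#' @param tp,fp,tn,fn Pooled epoch-level confusion counts with respect to
#'   the task's positive class.
#' @param positive,negative Class display names.
#' @return List with `accuracy`, `per_class` (2 x 3 matrix), `macro`
#'   (length-3 vector), and `counts`.
#' @export
epoch_metrics <- function(tp, fp, tn, fn, positive = "pos", negative = "neg") {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  pos <- .prf(tp, fp, fn)
  neg <- .prf(tn, fn, fp)
  per_class <- rbind(neg, pos)
  rownames(per_class) <- c(negative, positive)
  total <- tp + fp + tn + fn
  list(accuracy = if (total == 0) 0 else (tp + tn) / total,
       per_class = per_class,
       macro = colMeans(per_class),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Subject-level metrics from decided-subject confusion counts
#'
#' @param tp,fn,fp,tn Subject-level confusion counts over decided subjects.
#' @param n_rejected Number of rejected (tied) subjects.
#' @param conf Confidence level for the Wilson interval.
#' @return List with `accuracy` (decided subjects only), `wilson_ci`,
#'   `reject_rate`, and `counts`.
#' @export
subject_metrics <- function(tp, fn, fp, tn, n_rejected = 0L, conf = 0.95) {
  tp <- unname(tp); fn <- unname(fn); fp <- unname(fp); tn <- unname(tn)
  decided <- tp + fn + fp + tn
  correct <- tp + tn
  acc <- if (decided == 0) 0 else correct / decided
  ci <- if (decided == 0) c(lo = 0, hi = 1) else wilson_ci(correct, decided, conf)
  list(accuracy = acc, wilson_ci = ci,
       reject_rate = n_rejected / (decided + n_rejected),
       counts = c(tp = tp, fn = fn, fp = fp, tn = tn,
                  rejected = n_rejected))
}

#' Pooled evaluation summary of a LOSO run
#'
#' Pools the per-fold epoch confusion counts (conserving per-subject
#' counts), computes epoch-level metrics, aggregates epochs to subjects by
#' majority vote with rejection, and reports decided-subject accuracy with
#' its Wilson interval and the reject rate.
#'
#' @param folds A `loso_result` from [run_task()].
#' @param conf Confidence level for the Wilson interval.
#' @return Object of class `eval_summary`.
#' @export
pooled_metrics <- function(folds, conf = 0.95) {
  stopifnot(inherits(folds, "loso_result"))
  task <- attr(folds, "task")
  pos <- task$positive
  neg <- task$negative
  ep <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  sub <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  n_rej <- 0L
  decisions <- character(length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    is_pos <- f$true_label == pos
    ep["tp"] <- ep["tp"] + sum(is_pos & f$pred == pos)
    ep["fn"] <- ep["fn"] + sum(is_pos & f$pred == neg)
    ep["fp"] <- ep["fp"] + sum(!is_pos & f$pred == pos)
    ep["tn"] <- ep["tn"] + sum(!is_pos & f$pred == neg)
    dec <- majority_vote(f$pred, task$classes)
    decisions[i] <- dec
    if (dec == "reject") {
      n_rej <- n_rej + 1L
    } else if (is_pos) {
      if (dec == pos) sub["tp"] <- sub["tp"] + 1L else sub["fn"] <- sub["fn"] + 1L
    } else {
      if (dec == neg) sub["tn"] <- sub["tn"] + 1L else sub["fp"] <- sub["fp"] + 1L
    }
  }
  structure(
    list(task = task,
         epoch = epoch_metrics(ep["tp"], ep["fp"], ep["tn"], ep["fn"],
                               positive = pos, negative = neg),
         subject = subject_metrics(sub["tp"], sub["fn"], sub["fp"],
                                   sub["tn"], n_rej, conf),
         decisions = stats::setNames(decisions,
                                     vapply(folds, `[[`, "", "subject"))),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_summary> task %s (positive: %s)\n",
              x$task$name, x$task$positive))
  cat(sprintf("  epoch accuracy: %.3f  macro P/R/F1: %.3f / %.3f / %.3f\n",
              x$epoch$accuracy, x$epoch$macro["precision"],
              x$epoch$macro["recall"], x$epoch$macro["f1"]))
  cat(sprintf("  pooled epoch counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$epoch$counts["tp"], x$epoch$counts["fp"],
              x$epoch$counts["tn"], x$epoch$counts["fn"]))
  cat(sprintf("  subject accuracy (decided): %.3f  95%% Wilson CI [%.3f, %.3f]  reject rate %.1f%%\n",
              x$subject$accuracy, x$subject$wilson_ci["lo"],
              x$subject$wilson_ci["hi"], 100 * x$subject$reject_rate))
  invisible(x)
}
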