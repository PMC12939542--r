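#' Project a descriptor vector onto a dictionary
#'
#' Component k is the cosine similarity between `z` and atom k; values lie
#' in `[-1, 1]` and are invariant to positive rescaling of `z`.
#'
#' @param z Non-zero numeric vector of length M*P.
#' @param B A `cpp_dictionary` with at least one atom.
#' @return Numeric vector of K cosine similarities.
#' @export
project <- function(z, B) {
  stopifnot(inherits(B, "cpp_dictionary"), ncol(B$atoms) >= 1L)
  zn <- sqrt(sum(z^2))
  if (zn == 0) stop("degenerate zero-norm vector cannot be projected")
  an <- sqrt(colSums(B$atoms^2))
  as.vector(crossprod(B$atoms, z)) / (zn * an)
}

#' Build the concatenated projection feature table
#'
#' Rows are the epochs of the split (in input order); columns are the
#' cosine similarities to the atoms of class 1 followed by class 2.
#'
#' @param Z_split Matrix with the split's descriptor vectors in columns.
#' @param B1,B2 Class dictionaries (both learned from training data only).
#' @param meta Optional per-epoch metadata data frame (one row per column
#'   of `Z_split`).
#' @param split `"train"` or `"test"`.
#' @return Object of class `feature_table` with fields `H` (epochs x
#'   (K1 + K2) matrix), `meta`, `split`.
#' @export
build_feature_table <- function(Z_split, B1, B2, meta = NULL,
                                split = c("train", "test")) {
  split <- match.arg(split)
  stopifnot(inherits(B1, "cpp_dictionary"), inherits(B2, "cpp_dictionary"))
  if (ncol(B1$atoms) == 0L || ncol(B2$atoms) == 0L) {
    stop("empty dictionary for class ",
         if (ncol(B1$atoms) == 0L) B1$class_label else B2$class_label,
         ": relax the clustering thresholds (tau_sup / n_min / h_stop)")
  }
  H <- t(apply(Z_split, 2L, function(z) c(project(z, B1), project(z, B2))))
  colnames(H) <- c(paste0(B1$class_label, ":", seq_len(ncol(B1$atoms))),
                   paste0(B2$class_label, ":", seq_len(ncol(B2$atoms))))
  structure(list(H = H, meta = meta, split = split), class = "feature_table")
}

#' Standardize feature tables with train-only statistics
#'
#' Per-column mean and sample (n-1) standard deviation are estimated on the
#' training rows only and applied to both splits. Columns whose training
#' standard deviation falls below `1e-12` are mapped to zero in both splits.
#'
#' @param train A `feature_table` (non-empty).
#' @param test Optional `feature_table` transformed with the train
#'   statistics.
#' @return List with standardized `train`, `test` (or `NULL`), and
#'   `standardizer` (fields `mu`, `sigma`, `constant`).
#' @export
standardize <- function(train, test = NULL) {
  stopifnot(inherits(train, "feature_table"), nrow(train$H) >= 1L)
  mu <- colMeans(train$H)
  sigma <- apply(train$H, 2L, stats::sd)
  sigma[is.na(sigma)] <- 0
  constant <- sigma < 1e-12
  scale_by <- ifelse(constant, Inf, sigma)
  tf <- function(H) sweep(sweep(H, 2L, mu, "-"), 2L, scale_by, "/")
  train$H <- tf(train$H)
  if (!is.null(test)) {
    stopifnot(inherits(test, "feature_table"),
              ncol(test$H) == length(mu))
    test$H <- tf(test$H)
  }
  list(train = train, test = test,
       standardizer = list(mu = mu, sigma = sigma, constant = constant))
}
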