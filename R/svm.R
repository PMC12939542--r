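#' Linear support-vector classifier (L2-regularized hinge loss)
#'
#' Deterministic dual coordinate descent solver for the C-SVM with linear
#' kernel and an augmented (regularized) bias term, cycling through the
#' training rows in fixed order until the maximal projected-gradient KKT
#' violation drops below `tol`. No randomness is involved, so refits on
#' identical inputs are bit-for-bit identical.
#'
#' @param X Numeric matrix, rows are training samples.
#' @param y Labels coded -1 / +1 (+1 is the task's positive class).
#' @param cost Box constraint C (default 1).
#' @param tol KKT stopping tolerance.
#' @param max_pass Maximum number of full passes over the data.
#' @return Object of class `linear_svm` with fields `w`, `b`, `cost`.
#' @export
linear_svm <- function(X, y, cost = 1, tol = 1e-8, max_pass = 2000L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(-1, 1)))
  n <- nrow(X)
  Xa <- cbind(X, 1)
  q <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  for (pass in seq_len(max_pass)) {
    max_viol <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * Xa[i, ]) - 1
      pg <- if (alpha[i] <= 0) min(g, 0) else if (alpha[i] >= cost) max(g, 0) else g
      if (abs(pg) > 1e-14) {
        a_old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - g / q[i], 0), cost)
        w <- w + (alpha[i] - a_old) * y[i] * Xa[i, ]
        max_viol <- max(max_viol, abs(pg))
      }
    }
    if (max_viol < tol) break
  }
  p <- ncol(X)
  structure(list(w = w[seq_len(p)], b = w[p + 1L], cost = cost),
            class = "linear_svm")
}

#' Signed geometric decision margins
#'
#' `m = (x^T w + b) / ||w||_2`: the signed distance to the separating
#' hyperplane, positive toward the class trained as +1.
#'
#' @param model A `linear_svm`.
#' @param X Matrix of samples in rows.
#' @return Numeric vector of margins (all zero if the model is degenerate).
#' @export
svm_margin <- function(model, X) {
  stopifnot(inherits(model, "linear_svm"))
  nw <- sqrt(sum(model$w^2))
  raw <- as.vector(X %*% model$w + model$b)
  if (nw == 0) rep(0, length(raw)) else raw / nw
}
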