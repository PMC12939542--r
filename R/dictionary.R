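#' Divisive clustering parameters
#'
#' @param tau_sup Support threshold: a node is split only if its size
#'   strictly exceeds `tau_sup` (default 11).
#' @param n_min Minimum cluster size for both children of a split and for a
#'   terminal group to be retained (default 10).
#' @param h_stop Dendrogram height that a node's merge must exceed for the
#'   node to be split (default 0.2, cosine dissimilarity units).
#' @param linkage Linkage rule; only `"complete"` is supported.
#' @return Object of class `cluster_params`.
#' @export
cluster_params <- function(tau_sup = 11L, n_min = 10L, h_stop = 0.2,
                           linkage = "complete") {
  linkage <- match.arg(linkage, "complete")
  stopifnot(tau_sup >= 1L, n_min >= 1L, h_stop > 0, h_stop < 2)
  structure(list(tau_sup = as.integer(tau_sup), n_min = as.integer(n_min),
                 h_stop = h_stop, linkage = linkage),
            class = "cluster_params")
}

#' Pairwise cosine dissimilarity
#'
#' `delta_ij = 1 - cos(z_i, z_j)` for the columns of `Z`. Values lie in
#' `[0, 2]`, the diagonal is exactly zero, and the matrix is symmetric.
#'
#' @param Z Numeric matrix with observations in columns; no zero columns.
#' @return Symmetric n x n dissimilarity matrix.
#' @export
cosine_dissimilarity <- function(Z) {
  stopifnot(is.matrix(Z))
  nrm <- sqrt(colSums(Z^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop(sprintf("degenerate zero-norm vector in column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  Zn <- sweep(Z, 2L, nrm, "/")
  D <- 1 - crossprod(Zn)
  D[D < 0] <- 0
  D[D > 2] <- 2
  diag(D) <- 0
  (D + t(D)) / 2
}

# Member leaves under each node of an hclust merge tree.
.hclust_members <- function(merge) {
  n_nodes <- nrow(merge)
  members <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    kids <- merge[k, ]
    mem <- integer(0)
    for (kid in kids) {
      mem <- c(mem, if (kid < 0) -kid else members[[kid]])
    }
    members[[k]] <- sort(mem)
  }
  members
}

#' Hierarchical divisive clustering with retention thresholds
#'
#' Builds the complete-linkage dendrogram under cosine dissimilarity and
#' cuts it top-down: a node is split into its two dendrogram children iff
#' (a) its size strictly exceeds `tau_sup`, (b) its merge height exceeds
#' `h_stop`, and (c) both children contain at least `n_min` members.
#' Terminal nodes with at least `n_min` members are the surviving groups;
#' smaller terminal nodes are discarded.
#'
#' @param Z Matrix with observations in columns.
#' @param params [cluster_params()].
#' @return List of integer index groups (column indices into `Z`), in
#'   dendrogram order; may be empty.
#' @export
divisive_cluster <- function(Z, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  n <- ncol(Z)
  if (n == 0L) return(list())
  if (n == 1L) {
    return(if (params$n_min <= 1L) list(1L) else list())
  }
  D <- cosine_dissimilarity(Z)
  hc <- stats::hclust(stats::as.dist(D), method = params$linkage)
  members <- .hclust_members(hc$merge)
  groups <- list()
  visit <- function(node) {
    # node > 0: internal merge row; node < 0: leaf -node
    if (node < 0L) {
      if (params$n_min <= 1L) groups[[length(groups) + 1L]] <<- -node
      return(invisible())
    }
    mem <- members[[node]]
    if (length(mem) > params$tau_sup && hc$height[node] > params$h_stop) {
      kids <- hc$merge[node, ]
      sizes <- vapply(kids, function(k) {
        if (k < 0L) 1L else length(members[[k]])
      }, integer(1))
      if (all(sizes >= params$n_min)) {
        visit(kids[1L])
        visit(kids[2L])
        return(invisible())
      }
    }
    if (length(mem) >= params$n_min) {
      groups[[length(groups) + 1L]] <<- mem
    }
    invisible()
  }
  visit(nrow(hc$merge))
  groups
}

#' Medoid of a group under cosine dissimilarity
#'
#' Returns the member minimizing the total within-group dissimilarity; ties
#' are broken by the lowest index.
#'
#' @param Z Matrix with observations in columns.
#' @param group Non-empty integer vector of column indices.
#' @return List with `index` (column index into `Z`) and `vector`.
#' @export
medoid <- function(Z, group) {
  stopifnot(length(group) >= 1L)
  if (length(group) == 1L) {
    return(list(index = group, vector = Z[, group]))
  }
  D <- cosine_dissimilarity(Z[, group, drop = FALSE])
  i <- which.min(colSums(D))
  list(index = group[i], vector = Z[, group[i]])
}

# Recursive farthest-first ordering of dictionary atoms: start from the atom
# with maximal mean dissimilarity to the others, then repeatedly take the
# atom farthest (max-min dissimilarity) from those already chosen. Purely a
# reporting order; features do not depend on it.
.farthest_first_order <- function(atoms) {
  K <- ncol(atoms)
  if (K <= 1L) return(seq_len(K))
  D <- cosine_dissimilarity(atoms)
  sel <- which.max(colSums(D) / (K - 1))
  rest <- setdiff(seq_len(K), sel)
  while (length(rest)) {
    mind <- apply(D[sel, rest, drop = FALSE], 2L, min)
    nxt <- rest[which.max(mind)]
    sel <- c(sel, nxt)
    rest <- setdiff(rest, nxt)
  }
  sel
}

#' Learn a class-specific medoid dictionary
#'
#' l2-normalizes the class-restricted training vectors, runs
#' [divisive_cluster()], extracts one medoid per surviving group, and orders
#' the atoms by recursive farthest-first ranking (reporting order only).
#' Every atom is an exact copy of one (normalized) training vector.
#'
#' @param Z_class Matrix with the class's training vectors in columns.
#' @param params [cluster_params()].
#' @param class_label Label of the class the vectors belong to.
#' @param ids Optional identifiers (one per column) recorded as medoid
#'   provenance; defaults to column indices.
#' @return Object of class `cpp_dictionary` with fields `atoms`
#'   ((M*P) x K matrix), `group_sizes`, `medoid_source_ids`, `class_label`.
#'   Empty (`K = 0`) with a warning if no group survives.
#' @export
learn_dictionary <- function(Z_class, params = cluster_params(),
                             class_label = NA_character_, ids = NULL) {
  stopifnot(is.matrix(Z_class))
  if (is.null(ids)) ids <- as.character(seq_len(ncol(Z_class)))
  stopifnot(length(ids) == ncol(Z_class))
  nrm <- sqrt(colSums(Z_class^2))
  if (any(nrm == 0)) {
    stop("degenerate zero-norm training vector(s); cannot normalize")
  }
  Zn <- sweep(Z_class, 2L, nrm, "/")
  groups <- divisive_cluster(Zn, params)
  if (length(groups) == 0L) {
    warning("no surviving groups; returning an empty dictionary")
    return(structure(list(atoms = matrix(0, nrow(Z_class), 0),
                          group_sizes = integer(0),
                          medoid_source_ids = character(0),
                          class_label = class_label),
                     class = "cpp_dictionary"))
  }
  meds <- lapply(groups, function(g) medoid(Zn, g))
  atoms <- do.call(cbind, lapply(meds, `[[`, "vector"))
  sizes <- vapply(groups, length, integer(1))
  src <- ids[vapply(meds, `[[`, integer(1), "index")]
  ord <- .farthest_first_order(atoms)
  structure(list(atoms = atoms[, ord, drop = FALSE],
                 group_sizes = sizes[ord],
                 medoid_source_ids = src[ord],
                 class_label = class_label),
            class = "cpp_dictionary")
}

#' @export
print.cpp_dictionary <- function(x, ...) {
  cat(sprintf("<cpp_dictionary> class %s: %d atom(s) of dim %d; group sizes: %s\n",
              x$class_label, ncol(x$atoms), nrow(x$atoms),
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}
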