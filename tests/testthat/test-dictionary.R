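test_that("cosine_dissimilarity basics", {
  z <- c(1, 2, 3)
  D <- cosine_dissimilarity(cbind(z, z, 3 * z))
  expect_equal(max(abs(D)), 0)
  D2 <- cosine_dissimilarity(cbind(c(1, 0), c(0, 1)))
  expect_equal(D2[1, 2], 1)
  expect_identical(diag(D2), c(0, 0))
  expect_true(isSymmetric(D2))
  expect_error(cosine_dissimilarity(cbind(z, 0 * z)),
               "degenerate zero-norm vector in column\\(s\\): 2")
  withr::with_seed(30, Z <- matrix(rnorm(50), 5))
  D3 <- cosine_dissimilarity(Z)
  expect_true(all(D3 >= 0 & D3 <= 2))
})

test_that("divisive_cluster honours the split and retention conditions", {
  p <- cluster_params()
  # 12 near-identical vectors: root height < h_stop, one group survives
  withr::with_seed(31, {
    base <- abs(rnorm(6)) + 1
    Z <- sapply(1:12, function(i) base + 1e-4 * rnorm(6))
  })
  g <- divisive_cluster(Z, p)
  expect_length(g, 1L)
  expect_identical(sort(g[[1L]]), 1:12)
  # two orthogonal bundles of 12: exactly two surviving groups of 12
  Z2 <- make_two_bundles(each = 12L)
  g2 <- divisive_cluster(Z2, p)
  expect_length(g2, 2L)
  expect_identical(sort(vapply(g2, length, integer(1))), c(12L, 12L))
  expect_identical(sort(unlist(g2)), 1:24)
  # fewer than n_min vectors: nothing survives
  g3 <- divisive_cluster(Z2[, 1:9], p)
  expect_length(g3, 0L)
  # empty input
  expect_length(divisive_cluster(Z2[, 0, drop = FALSE], p), 0L)
})

test_that("surviving groups are disjoint subsets meeting the size floor", {
  p <- cluster_params(tau_sup = 5L, n_min = 3L, h_stop = 0.1)
  withr::with_seed(32, {
    for (i in 1:10) {
      n <- sample(3:40, 1)
      Z <- matrix(rnorm(6 * n), 6) + 2 # keep away from zero norm
      g <- divisive_cluster(Z, p)
      all_idx <- unlist(g)
      expect_identical(anyDuplicated(all_idx), 0L)
      expect_true(all(all_idx %in% seq_len(n)))
      expect_true(all(vapply(g, length, integer(1)) >= p$n_min))
    }
  })
})

test_that("medoid matches the exhaustive argmin with lowest-index ties", {
  a <- c(1, 1, 0)
  b <- c(0, 1, 1)
  Z <- cbind(a, a, b)
  expect_identical(medoid(Z, 1:3)$index, 1L)
  expect_identical(medoid(Z, 2L)$index, 2L)
  # brute-force oracle (helper-fixtures.R)
  withr::with_seed(33, {
    for (i in 1:50) {
      n <- sample(2:20, 1)
      Z <- matrix(rnorm(5 * n), 5) + 3
      g <- sort(sample(n, sample(seq_len(n), 1)))
      expect_identical(medoid(Z, g)$index, brute_medoid(Z, g))
    }
  })
})

test_that("learn_dictionary extracts medoids of surviving groups", {
  Z <- make_two_bundles(each = 12L)
  B <- learn_dictionary(Z, cluster_params(), class_label = "CN")
  expect_identical(ncol(B$atoms), 2L)
  expect_identical(sort(B$group_sizes), c(12L, 12L))
  # every atom is an exact copy of one l2-normalized training vector
  Zn <- sweep(Z, 2, sqrt(colSums(Z^2)), "/")
  for (k in 1:2) {
    hit <- apply(Zn, 2, function(col) identical(col, B$atoms[, k]))
    expect_identical(sum(hit), 1L)
  }
  # provenance ids point at the medoid columns
  expect_identical(
    B$atoms,
    Zn[, as.integer(B$medoid_source_ids), drop = FALSE],
    ignore_attr = TRUE)
})

test_that("the atom set is invariant to training order", {
  Z <- make_two_bundles(each = 12L, seed = 44)
  B1 <- learn_dictionary(Z, cluster_params())
  perm <- withr::with_seed(45, sample(ncol(Z)))
  B2 <- learn_dictionary(Z[, perm], cluster_params())
  key <- function(B) {
    cols <- apply(round(B$atoms, 12), 2, paste, collapse = ",")
    sort(cols)
  }
  expect_identical(key(B1), key(B2))
})

test_that("an unclusterable class yields an empty dictionary with a warning", {
  withr::with_seed(46, Z <- matrix(rnorm(5 * 4), 5) + 2)
  expect_warning(B <- learn_dictionary(Z, cluster_params()), "no surviving")
  expect_identical(ncol(B$atoms), 0L)
})
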