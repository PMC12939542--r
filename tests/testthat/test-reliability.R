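test_that("subject_descriptors worked examples and oracle", {
  expect_equal(unname(subject_descriptors(rep(2, 6))), c(2, 0, 0.5))
  expect_equal(subject_descriptors(c(-1, 1, -1, 1))[["sign_cons"]], 0)
  d <- subject_descriptors(c(1, 2, 3, 4))
  expect_equal(d[["med_abs"]], 2.5)
  # order-statistics oracle for the type-7 IQR: q25 = 1.75, q75 = 3.25
  x <- c(1, 2, 3, 4)
  q7 <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(d[["iqr"]], q7(0.75) - q7(0.25))
  expect_equal(d[["iqr"]], 1.5)
})

test_that("outcome_grouping assigns decided subjects to TP/FN/TN/FP", {
  mk <- function(subject, true, npos) {
    preds <- rep(c("AD", "CN"), c(npos, 10 - npos))
    list(subject = subject, true = true, pred = preds,
         margins = ifelse(preds == "AD", 1.5, -0.5))
  }
  folds <- make_fake_folds(list(
    mk("s1", "AD", 9), mk("s2", "AD", 1), mk("s3", "CN", 2),
    mk("s4", "CN", 8), mk("s5", "CN", 5)))
  rec <- outcome_grouping(folds)
  expect_identical(rec$outcome[match(paste0("s", 1:4), rec$subject_id)],
                   c("TP", "FN", "TN", "FP"))
  expect_false("s5" %in% rec$subject_id) # rejected subject in no group
  expect_identical(nrow(rec), 4L)
})

test_that("permutation_median_gap is exact on small groups", {
  # all-tied data: p = 1
  out <- permutation_median_gap(rep(3, 4), rep(3, 3))
  expect_identical(out$p_value, 1)
  # (3,3) groups: exact enumeration over the 20 splits
  a <- c(10, 11, 12); b <- c(0, 1, 2)
  out2 <- permutation_median_gap(a, b)
  expect_true(out2$exact)
  expect_identical(out2$n_perm, 20L)
  # independent brute-force oracle
  pool <- c(a, b)
  gaps <- apply(utils::combn(6, 3), 2, function(idx) {
    median(pool[idx]) - median(pool[-idx])
  })
  p_oracle <- mean(abs(gaps) >= abs(median(a) - median(b)) - 1e-12)
  expect_identical(out2$p_value, p_oracle)
  expect_equal(out2$delta_med, 10)
  # random small groups agree with the oracle too
  withr::with_seed(81, {
    for (i in 1:20) {
      a <- rnorm(3); b <- rnorm(3)
      out3 <- permutation_median_gap(a, b)
      pool <- c(a, b)
      gaps <- apply(utils::combn(6, 3), 2, function(idx) {
        median(pool[idx]) - median(pool[-idx])
      })
      expect_identical(out3$p_value,
                       mean(abs(gaps) >= abs(out3$delta_med) - 1e-12))
    }
  })
})

test_that("sampled permutation p-values are seeded and translation invariant", {
  withr::with_seed(82, {
    a <- rnorm(12); b <- rnorm(9) + 0.5
  })
  p1 <- permutation_median_gap(a, b, n_perm = 500L, seed = 7L)
  p2 <- permutation_median_gap(a, b, n_perm = 500L, seed = 7L)
  expect_false(p1$exact)
  expect_identical(p1$p_value, p2$p_value)
  p3 <- permutation_median_gap(a + 100, b + 100, n_perm = 500L, seed = 7L)
  expect_identical(p1$p_value, p3$p_value)
  expect_equal(p3$delta_med, p1$delta_med)
})

test_that("cliffs_delta matches brute-force pair counting", {
  expect_identical(cliffs_delta(c(5, 6), c(1, 2), n_boot = 0L)$delta, 1)
  expect_identical(cliffs_delta(c(1, 2, 2), c(1, 2, 2), n_boot = 0L)$delta, 0)
  brute <- function(a, b) {
    s <- 0L
    for (x in a) for (y in b) s <- s + sign(x - y)
    s / (length(a) * length(b))
  }
  withr::with_seed(83, {
    for (i in 1:40) {
      a <- sample(1:6, sample(2:8, 1), replace = TRUE)
      b <- sample(1:6, sample(2:8, 1), replace = TRUE)
      cd <- cliffs_delta(a, b, n_boot = 0L)
      expect_equal(cd$delta, brute(a, b))
      # antisymmetry
      expect_equal(cliffs_delta(b, a, n_boot = 0L)$delta, -cd$delta)
    }
  })
  # bootstrap CI is seeded and covers the point estimate
  withr::with_seed(84, {
    a <- rnorm(10, 1); b <- rnorm(8)
  })
  c1 <- cliffs_delta(a, b, n_boot = 500L, seed = 3L)
  c2 <- cliffs_delta(a, b, n_boot = 500L, seed = 3L)
  expect_identical(c1$ci, c2$ci)
  expect_true(c1$ci["lo"] <= c1$delta && c1$delta <= c1$ci["hi"])
})

test_that("reliability_report compares outcome groups per descriptor", {
  withr::with_seed(85, {
    mk <- function(subject, true, npos, mscale) {
      preds <- rep(c("AD", "CN"), c(npos, 10 - npos))
      list(subject = subject, true = true, pred = preds,
           margins = mscale * ifelse(preds == "AD", 1, -1) + rnorm(10, sd = .1))
    }
    rows <- c(
      lapply(1:6, function(i) mk(paste0("tp", i), "AD", 9, 2)),
      lapply(1:3, function(i) mk(paste0("fp", i), "CN", 8, 0.4)),
      lapply(1:6, function(i) mk(paste0("tn", i), "CN", 1, 1.5)),
      lapply(1:3, function(i) mk(paste0("fn", i), "AD", 2, 0.5)))
  })
  folds <- make_fake_folds(rows)
  rpt <- reliability_report(folds, n_perm = 500L, n_boot = 200L, seed = 5L)
  expect_setequal(unique(rpt$compare), c("TP-FP", "TN-FN"))
  expect_setequal(unique(rpt$descriptor), c("med_abs", "iqr", "sign_cons"))
  expect_true(all(rpt$p_perm > 0 & rpt$p_perm <= 1))
  expect_true(all(rpt$cliffs_delta >= -1 & rpt$cliffs_delta <= 1))
  # TP subjects were built with larger |m| than FP subjects
  gap <- rpt$delta_med[rpt$descriptor == "med_abs" & rpt$compare == "TP-FP"]
  expect_gt(gap, 0)
})
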