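test_that("delay_embed builds the stacked snapshot pair", {
  x <- matrix(c(1, 2, 3, 4), 1)
  emb <- delay_embed(x, 1L)
  expect_identical(emb$X, matrix(c(1, 2, 3), 1))
  expect_identical(emb$Xp, matrix(c(2, 3, 4), 1))
  emb2 <- delay_embed(matrix(rnorm(2 * 1000), 2), 48L)
  expect_identical(dim(emb2$X), c(96L, 952L))
  expect_identical(dim(emb2$X), dim(emb2$Xp))
  expect_error(delay_embed(matrix(1:6, 2), 3L), "insufficient samples")
})

test_that("X and X' share the shifted block structure", {
  withr::with_seed(21, {
    for (i in 1:10) {
      m <- sample(1:4, 1)
      S <- sample(2:6, 1)
      n <- S + sample(5:20, 1)
      emb <- delay_embed(matrix(rnorm(m * n), m), S)
      # dropping the last row-block of X' equals dropping the first of X
      expect_equal(emb$Xp[seq_len(m * (S - 1)), , drop = FALSE],
                   emb$X[m + seq_len(m * (S - 1)), , drop = FALSE])
    }
  })
})

test_that("fit_dmd recovers analytic eigenstructure", {
  fs <- 500
  # pure rotation at 10 Hz, 2 channels
  sys <- make_linear_system(10, 0, fs, M = 2L, N = 300L, seed = 2)
  emb <- delay_embed(sys$x, 1L)
  ms <- fit_dmd(emb$X, emb$Xp, dmd_params(1L, 10L, fs), n_channels = 2L)
  expect_lt(min(abs(ms$freqs_hz - 10)), 1e-6)
  # damped cosine at 12 Hz, decay 2 / s, on all channels, with stacking
  tt <- (0:999) / fs
  s <- exp(-2 * tt) * cos(2 * pi * 12 * tt)
  x2 <- rbind(s, 0.5 * s, -0.8 * s)
  emb2 <- delay_embed(x2, 5L)
  ms2 <- fit_dmd(emb2$X, emb2$Xp, dmd_params(5L, 10L, fs), n_channels = 3L)
  i <- which.min(abs(ms2$freqs_hz - 12))
  expect_equal(Re(ms2$omegas[i]), -2, tolerance = 1e-6)
  expect_equal(abs(Im(ms2$omegas[i])) / (2 * pi), 12, tolerance = 1e-6)
  # constant signal: fixed point at lambda = 1, frequency 0
  xc <- matrix(5, 3, 100)
  embc <- delay_embed(xc, 1L)
  msc <- fit_dmd(embc$X, embc$Xp, dmd_params(1L, 10L, fs), n_channels = 3L)
  k <- which.max(Mod(msc$eigvals))
  expect_equal(Mod(msc$eigvals[k]), 1, tolerance = 1e-8)
  expect_equal(msc$freqs_hz[k], 0, tolerance = 1e-8)
})

test_that("fit_dmd returns an empty mode set on zero input", {
  ms <- fit_dmd(matrix(0, 4, 50), matrix(0, 4, 50),
                dmd_params(2L, 10L, 500), n_channels = 2L)
  expect_length(ms$eigvals, 0L)
  expect_identical(ncol(ms$modes), 0L)
})

test_that("complex eigenvalues appear in conjugate pairs with equal frequency", {
  withr::with_seed(8, {
    x <- matrix(rnorm(3 * 120), 3)
  })
  emb <- delay_embed(x, 4L)
  ms <- fit_dmd(emb$X, emb$Xp, dmd_params(4L, 12L, 100), n_channels = 3L)
  cplx <- ms$eigvals[abs(Im(ms$eigvals)) > 1e-10]
  expect_true(length(cplx) %% 2L == 0L)
  for (lam in cplx) {
    expect_true(any(Mod(cplx - Conj(lam)) < 1e-8))
  }
  fr <- sort(round(ms$freqs_hz[abs(Im(ms$eigvals)) > 1e-10], 8))
  expect_identical(fr[seq(1, length(fr), 2)], fr[seq(2, length(fr), 2)])
})

test_that("modal expansion reconstructs noiseless low-rank snapshots", {
  fs <- 250
  sys <- make_linear_system(c(3, 7), c(0, -1), fs, M = 5L, N = 200L, seed = 4)
  emb <- delay_embed(sys$x, 3L)
  ms <- fit_dmd(emb$X, emb$Xp, dmd_params(3L, 20L, fs), n_channels = 5L)
  ns <- ncol(emb$X)
  vand <- outer(ms$eigvals, 0:(ns - 1), "^")
  recon <- Re(ms$modes_aug %*% (ms$amplitudes * vand))
  expect_lt(norm(recon - emb$X, "F") / norm(emb$X, "F"), 1e-8)
})

test_that("rectify_modes removes the common mode and is idempotent", {
  ones <- matrix(1 + 0i, 5, 1)
  expect_true(all(rectify_modes(ones) == 0))
  withr::with_seed(13, {
    raw <- matrix(complex(real = rnorm(20), imaginary = rnorm(20)), 5, 4)
  })
  rect <- rectify_modes(raw)
  expect_lt(max(Mod(colMeans(rect))), 1e-12)
  # idempotent
  expect_equal(rectify_modes(rect), rect)
  # zero-mean input unchanged
  zm <- sweep(raw, 2, colMeans(raw), "-")
  expect_equal(rectify_modes(zm), zm)
  # linear
  expect_equal(rectify_modes(2 * raw + zm),
               2 * rectify_modes(raw) + rectify_modes(zm))
  # subtracting any real channel-constant preserves pairwise phase
  # differences of the rectified residual
  shifted <- raw + 0.7
  expect_equal(rectify_modes(shifted), rectify_modes(raw))
  d1 <- Arg(rect[1, ]) - Arg(rect[2, ])
  rect2 <- rectify_modes(shifted)
  expect_equal(Arg(rect2[1, ]) - Arg(rect2[2, ]), d1)
})
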