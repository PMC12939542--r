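test_that("band_filter_modes keeps the closed [4, 40] Hz band", {
  m <- matrix(1 + 0i, 3, 3)
  ms <- make_modeset(m, c(2, 10, 45))
  kept <- band_filter_modes(ms)
  expect_identical(kept$freqs_hz, 10)
  edge <- band_filter_modes(make_modeset(m[, 1, drop = FALSE], 4.0))
  expect_identical(edge$freqs_hz, 4.0)
  edge40 <- band_filter_modes(make_modeset(m[, 1, drop = FALSE], 40.0))
  expect_identical(edge40$freqs_hz, 40.0)
})

test_that("conjugate pairs collapse to one representative", {
  fs <- 500
  sys <- make_linear_system(10, 0, fs, M = 2L, N = 200L, seed = 6)
  emb <- delay_embed(sys$x, 1L)
  ms <- fit_dmd(emb$X, emb$Xp, dmd_params(1L, 10L, fs), n_channels = 2L)
  expect_identical(sum(abs(ms$freqs_hz - 10) < 1e-6), 2L) # the pair
  kept <- band_filter_modes(ms)
  expect_identical(sum(abs(kept$freqs_hz - 10) < 1e-6), 1L)
  expect_true(all(Im(kept$omegas) >= 0))
})

test_that("mode_image interpolates sorted magnitudes onto the P grid", {
  withr::with_seed(7, mags <- matrix(abs(rnorm(12)), 3, 4))
  freqs <- c(20, 5, 31, 12)
  ms <- make_modeset(mags + 0i, freqs)
  # J = P: identity up to frequency sorting
  img <- mode_image(ms, P = 4L)
  expect_equal(img, mags[, order(freqs)])
  # J = 1: constant extension
  one <- make_modeset(mags[, 2, drop = FALSE] + 0i, 9)
  img1 <- mode_image(one, P = 5L)
  expect_equal(img1, matrix(mags[, 2], 3, 5))
  # J = 2: closed-form linear interpolation
  two <- make_modeset(mags[, 1:2] + 0i, c(25, 6))
  a <- mags[, 2]; b <- mags[, 1] # sorted by frequency: col 2 first
  P <- 7L
  exp_img <- sapply(seq_len(P), function(p) a + (b - a) * (p - 1) / (P - 1))
  expect_equal(mode_image(two, P = P), exp_img)
  # empty mode set: all-zero sentinel with warning
  empty <- band_filter_modes(make_modeset(mags + 0i, c(1, 2, 3, 100)))
  expect_warning(imge <- mode_image(empty, P = 4L), "no retained modes")
  expect_true(all(imge == 0))
})

test_that("mode_image weights modes by modal amplitude by default", {
  mags <- matrix(1, 2, 2)
  ms <- make_modeset(mags + 0i, c(5, 10), amplitudes = c(3 + 0i, 0 + 1i))
  img <- mode_image(ms, P = 2L)
  expect_equal(img, cbind(c(3, 3), c(1, 1)))
  expect_equal(mode_image(ms, P = 2L, weight = "none"), mags)
})

test_that("epoch_descriptor averages, rescales, and vectorizes", {
  withr::with_seed(17, img <- matrix(runif(12, 1, 9), 3, 4))
  d <- epoch_descriptor(list(img, img, img))
  expect_equal(d$image, (img - min(img)) / (max(img) - min(img)))
  expect_identical(d$vector, as.vector(d$image))
  expect_identical(min(d$image), 0)
  expect_identical(max(d$image), 1)
  # affine midpoint example
  m2 <- matrix(c(2, 4, 6, 4), 2)
  d2 <- epoch_descriptor(list(m2))
  expect_equal(d2$image[2, 1], 0.5)
  # order preservation (monotone rescale)
  stack <- withr::with_seed(18, lapply(1:5, function(i) matrix(runif(20), 4)))
  d3 <- epoch_descriptor(stack)
  mean_img <- Reduce(`+`, stack) / 5
  expect_identical(order(as.vector(mean_img)), order(d3$vector))
  # permutation of segments leaves the descriptor unchanged
  d4 <- epoch_descriptor(stack[c(3, 1, 5, 2, 4)])
  expect_identical(d3$image, d4$image)
  # degenerate constant mean
  expect_warning(dz <- epoch_descriptor(list(matrix(7, 2, 2))), "degenerate")
  expect_true(all(dz$vector == 0))
})

test_that("descriptors are invariant to global positive input scaling", {
  withr::with_seed(19, seg <- matrix(rnorm(3 * 150), 3))
  params <- dmd_params(4L, 12L, 100)
  img_of <- function(s) {
    mode_image(band_filter_modes(segment_modes(s, params), 1, 45), P = 10L)
  }
  i1 <- img_of(seg)
  i2 <- img_of(3.7 * seg)
  d1 <- epoch_descriptor(list(i1))
  d2 <- epoch_descriptor(list(i2))
  expect_equal(d1$image, d2$image, tolerance = 1e-8)
})

test_that("descriptor tables round-trip through TSV", {
  co <- generate_cohort(tiny_config(n_ad = 1L, n_cn = 0L))
  d <- tiny_descriptors(co)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptors(d, path)
  d2 <- read_descriptors(path)
  expect_equal(d2$Z, d$Z, tolerance = 1e-12)
  expect_identical(d2$meta$subject_id, d$meta$subject_id)
})
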