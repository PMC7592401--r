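test_that("the periodized wavelet transform reconstructs perfectly", {
  set.seed(3)
  for (dims in list(c(64, 64), c(64, 48), c(128, 64))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    p <- dwt2(x, levels = 3)
    expect_lt(max(abs(idwt2(p) - x)) / max(abs(x)), 1e-8)
  }
  expect_error(dwt2(matrix(0, 30, 30), levels = 3), "divisible")
  expect_error(dwt2(matrix(0, 16, 16), levels = 3), "small")
})

test_that("noise sd estimation is robust and homogeneous", {
  expect_equal(estimate_noise_sigma(dwt2(matrix(0, 64, 64))), 0)
  set.seed(9)
  x <- matrix(rnorm(256 * 256), 256, 256)
  s <- estimate_noise_sigma(dwt2(x))
  expect_gt(s, 0.9)
  expect_lt(s, 1.1)
  # homogeneity: scaling the input scales the estimate
  expect_equal(estimate_noise_sigma(dwt2(3.7 * x)), 3.7 * s)
})

test_that("the Wiener gain shrinks coefficients as specified", {
  band <- matrix(c(-2, 4, 0, 1), 2, 2)
  expect_identical(local_wiener_pass(band, matrix(1, 2, 2), 0), band)
  expect_equal(local_wiener_pass(band, matrix(0, 2, 2), 1), matrix(0, 2, 2))
  # scalar case: 4 * 3 / (3 + 1) = 3
  expect_equal(local_wiener_pass(matrix(4), matrix(3), 1), matrix(3))
  expect_error(local_wiener_pass(band, matrix(-1, 2, 2), 1), "non-negative")
  # output magnitude never exceeds input magnitude
  set.seed(4)
  b <- matrix(rnorm(64), 8, 8)
  v <- matrix(stats::rgamma(64, 1), 8, 8)
  expect_true(all(abs(local_wiener_pass(b, v, 0.7)) <= abs(b) + 1e-15))
})

test_that("denoising is the identity on noiseless piecewise-constant input", {
  img <- denoise_phantom()
  out <- dlwfdw_denoise(img)
  expect_lt(sqrt(mean((out - img)^2)), 1e-6)
  # explicit sigma = 0 is the identity to transform precision
  expect_lt(max(abs(dlwfdw_denoise(img, sigma = 0) - img)), 1e-8)
})

test_that("denoising reduces noise and detail-band energy", {
  img <- denoise_phantom()
  set.seed(0)
  noisy <- img + matrix(rnorm(length(img), 0, 20), nrow(img))
  out <- dlwfdw_denoise(noisy)
  # uniform-region noise sd strictly reduced
  roi <- img == 0 & row(img) > 100 & col(img) > 100
  expect_lt(stats::sd(out[roi]), stats::sd(noisy[roi]))
  # per-band energy never increases: shrink factors are in [0, 1]
  p_in <- dwt2(noisy)
  sig <- estimate_noise_sigma(p_in)
  for (l in 1:3) {
    for (b in c("LH", "HL", "HH")) {
      shrunk <- local_wiener_pass(p_in$detail[[l]][[b]],
                                  matrix(1, nrow(p_in$detail[[l]][[b]]),
                                         ncol(p_in$detail[[l]][[b]])), sig)
      expect_lte(sum(shrunk^2), sum(p_in$detail[[l]][[b]]^2))
    }
  }
})

test_that("denoising PSNR gain clears the regression anchor", {
  img <- denoise_phantom()
  set.seed(0)
  noisy <- img + matrix(rnorm(length(img), 0, 20), nrow(img))
  gain <- psnr(dlwfdw_denoise(noisy), img) - psnr(noisy, img)
  expect_gte(gain, 4)        # minimum acceptable improvement
  expect_gte(gain, 8)        # regression anchor: first verified run gave 8.4 dB
})
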