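lib4 <- default_material_library(c("air", "blood", "fat", "bone"))
cl4 <- cluster_materials(lib4)
co4 <- cbind(lib4$mu_low_cm1, lib4$mu_high_cm1)
rownames(co4) <- lib4$name

test_that("single-pixel decomposition recovers pure and binary mixtures", {
  # exactly at a library coordinate
  out <- decompose_pixel(co4["blood", ], cl4, lib4)
  expect_equal(unname(out$fractions["blood"]), 1)
  expect_equal(sum(out$fractions), 1)
  expect_false(out$out_of_hull)

  # midpoint of the blood-fat segment: 0.5/0.5, third vertex zero
  mid <- (co4["blood", ] + co4["fat", ]) / 2
  out2 <- decompose_pixel(mid, cl4, lib4)
  expect_equal(unname(out2$fractions["blood"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(out2$fractions["fat"]), 0.5, tolerance = 1e-9)
  expect_equal(sum(out2$fractions > 1e-9), 2)

  # forward-model round trip at 0.3 blood + 0.7 fat
  p <- 0.3 * co4["blood", ] + 0.7 * co4["fat", ]
  out3 <- decompose_pixel(p, cl4, lib4)
  expect_equal(unname(out3$fractions[c("blood", "fat")]), c(0.3, 0.7),
               tolerance = 1e-9)
})

test_that("image decomposition labels pure-material blocks correctly", {
  # 8x8 image of pure-material blocks, in attenuation units
  labels <- matrix(rep(c("air", "blood", "fat", "bone"), each = 16), 8, 8)
  low <- matrix(co4[labels, 1], 8, 8)
  high <- matrix(co4[labels, 2], 8, 8)
  vf <- decompose_image(list(low = low, high = high, units = "mu"), lib4)
  argmax <- colnames(vf$fractions)[max.col(vf$fractions)]
  expect_equal(argmax, as.vector(labels))
  expect_equal(rowSums(vf$fractions), rep(1, 64), tolerance = 1e-12)

  # a constant water image decomposes to water everywhere
  libw <- default_material_library(c("air", "water", "bone"))
  vfw <- decompose_image(list(low = matrix(0, 4, 4), high = matrix(0, 4, 4),
                              units = "hu"), libw)
  expect_equal(fraction_map(vfw, "water"), matrix(1, 4, 4))
})

test_that("per-pixel fractions always satisfy the map invariants", {
  set.seed(42)
  pair <- list(low = matrix(rnorm(32 * 32, 0.25, 0.08), 32, 32),
               high = matrix(rnorm(32 * 32, 0.22, 0.07), 32, 32),
               units = "mu")
  vf <- decompose_image(pair, lib4)
  expect_true(all(vf$fractions >= 0))
  expect_true(all(vf$fractions <= 1 + 1e-12))
  expect_equal(rowSums(vf$fractions), rep(1, 1024), tolerance = 1e-9)
  expect_true(all(rowSums(vf$fractions > 1e-9) <= 3))
})

test_that("decomposition is independent of pixel processing order", {
  set.seed(8)
  pair <- list(low = matrix(rnorm(32 * 32, 0.25, 0.08), 32, 32),
               high = matrix(rnorm(32 * 32, 0.22, 0.07), 32, 32),
               units = "mu")
  one <- decompose_image(pair, lib4, chunks = 1)
  many <- decompose_image(pair, lib4, chunks = 7)
  expect_identical(one$fractions, many$fractions)
  expect_identical(one$out_of_hull, many$out_of_hull)
  expect_identical(one$triangles[one$triangle_id], many$triangles[many$triangle_id])
})

test_that("out-of-hull points are clamped to the hull and flagged", {
  # a metal-artifact-like point far beyond bone
  p <- c(2 * max(co4[, 1]), 2 * max(co4[, 2]))
  out <- decompose_pixel(p, cl4, lib4)
  expect_true(out$out_of_hull)
  expect_equal(sum(out$fractions), 1)
  expect_true(all(out$fractions >= 0))
  vf <- decompose_image(list(low = matrix(p[1], 2, 2),
                             high = matrix(p[2], 2, 2), units = "mu"), lib4)
  expect_true(all(out_of_hull_mask(vf)))
})

test_that("noiseless rendered phantoms round-trip exactly", {
  pair <- render_dect(make_qa_head(), default_material_library())
  lib <- default_material_library(c("air", "water", "acrylic"))
  vf <- decompose_image(pair, lib)
  for (m in lib$name) {
    expect_lt(max(abs(fraction_map(vf, m) - pair$truth[[m]])), 1e-9)
  }
})

test_that("tidy and glance views of a map are consistent with it", {
  libw <- default_material_library(c("air", "water", "bone"))
  vf <- decompose_image(list(low = matrix(0, 4, 4), high = matrix(0, 4, 4),
                             units = "hu"), libw)
  td <- tidy(vf)
  expect_equal(nrow(td), 16 * 3)
  expect_equal(sum(td$fraction), 16)
  gl <- glance(vf)
  expect_equal(gl$n_pixels, 16)
  expect_equal(gl$frac_out_of_hull, 0)
})
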