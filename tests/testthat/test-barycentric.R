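unit_triangle <- function() {
  lib <- material_library(c("p", "q", "r"), c(1, 1, 1),
                          c(0, 1, 0), c(0, 0, 1))
  triangle(lib, c("p", "q", "r"))
}

test_that("barycentric solve recovers vertex, centroid and hand-solved cases", {
  tri <- unit_triangle()
  # at vertex 1
  s <- solve_barycentric(c(0, 0), tri)
  expect_equal(s$fractions, c(1, 0, 0))
  expect_true(s$inside)
  # at the centroid
  s2 <- solve_barycentric(c(1 / 3, 1 / 3), tri)
  expect_equal(s2$fractions, rep(1 / 3, 3))
  # interior point, area-ratio value
  s3 <- solve_barycentric(c(0.25, 0.25), tri)
  expect_equal(s3$fractions, c(0.5, 0.25, 0.25))
  expect_true(s3$inside)
  # exterior point, direct 3x3 solve checked by hand
  s4 <- solve_barycentric(c(1, 1), tri)
  expect_equal(s4$fractions, c(-1, 1, 1))
  expect_false(s4$inside)
  expect_lt(s4$residual, 1e-12)
})

test_that("degenerate triangles are rejected with the vertices named", {
  lib <- material_library(c("x", "y", "z"), c(1, 1, 1),
                          c(0, 1, 2), c(0, 1, 2))
  tri <- triangle(lib, c("x", "y", "z"))
  expect_error(solve_barycentric(c(0.5, 0.5), tri), "x, y, z")
})

test_that("solver agrees with the area-ratio construction on random cases", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 1000) {
    v <- matrix(runif(6, -1, 1), 3, 2)
    lib <- try(material_library(c("u", "v", "w"), c(1, 1, 1),
                                pmax(v[, 1] + 1, 0), pmax(v[, 2] + 1, 0)),
               silent = TRUE)
    if (inherits(lib, "try-error")) next
    tri <- triangle(lib, 1:3)
    A <- tri$coords
    area2 <- abs((A[2, 1] - A[1, 1]) * (A[3, 2] - A[1, 2]) -
                   (A[3, 1] - A[1, 1]) * (A[2, 2] - A[1, 2]))
    if (area2 < 1e-3) next    # keep well-conditioned triangles in the sweep
    p <- runif(2, 0, 2)
    got <- solve_barycentric(p, tri)$fractions
    want <- area_ratio_barycentric(p, A[1, ], A[2, ], A[3, ])
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("volume-to-mass conversion is density-weighted renormalization", {
  lib <- material_library(c("w", "d"), c(1, 2), c(0.2, 0.4), c(0.18, 0.3))
  expect_equal(volume_to_mass_fraction(c(w = 1, d = 0), lib), c(w = 1, d = 0))
  # equal volumes of densities 1 and 2 -> masses 1/3 and 2/3
  expect_equal(volume_to_mass_fraction(c(w = 0.5, d = 0.5), lib),
               c(w = 1 / 3, d = 2 / 3))

  lib3 <- material_library(c("a", "b", "c"), c(1.0, 1.05, 0.92),
                           c(0.1, 0.2, 0.3), c(0.1, 0.18, 0.25))
  alpha <- c(a = 0.2, b = 0.5, c = 0.3)
  # independent spreadsheet-style arithmetic
  w <- c(0.2 * 1.0, 0.5 * 1.05, 0.3 * 0.92)
  expect_equal(unname(volume_to_mass_fraction(alpha, lib3)), w / sum(w))
  expect_equal(sum(volume_to_mass_fraction(alpha, lib3)), 1)

  expect_error(volume_to_mass_fraction(c(a = 0, b = 0, c = 0), lib3), "mass")
})
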