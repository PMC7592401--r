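test_that("a triangle already containing the point is returned unchanged", {
  lib <- default_material_library(c("air", "blood", "fat", "bone"))
  cl <- cluster_materials(lib)
  tri <- triangle(lib, c("air", "blood", "fat"))
  # a point at the blood coordinate is inside (vertex case)
  p <- unlist(lib[lib$name == "blood", c("mu_low_cm1", "mu_high_cm1")],
              use.names = FALSE)
  out <- select_triangle(p, tri, lib, cl)
  expect_identical(out$names, tri$names)
})

test_that("the containing candidate is found when the initial triangle fails", {
  lib <- default_material_library(c("air", "blood", "fat", "bone"))
  cl <- cluster_materials(lib)
  co <- lib_pts <- cbind(lib$mu_low_cm1, lib$mu_high_cm1)
  rownames(co) <- lib$name
  # synthesize a point strictly inside (blood, fat, bone)
  p <- 0.2 * co["blood", ] + 0.3 * co["fat", ] + 0.5 * co["bone", ]
  # verify by brute force that only triangles with bone contain it
  containing <- character(0)
  for (cmb in utils::combn(lib$name, 3, simplify = FALSE)) {
    s <- solve_barycentric(p, triangle(lib, cmb))
    if (s$inside) containing <- c(containing, paste(sort(cmb), collapse = "|"))
  }
  expect_true("blood|bone|fat" %in% containing)
  initial <- triangle(lib, c("blood", "fat", "air"))
  out <- select_triangle(p, initial, lib, cl)
  expect_true(solve_barycentric(p, out)$inside)
  expect_true(paste(sort(out$names), collapse = "|") %in% containing)
})

test_that("candidates sharing vertices with the initial triangle are preferred", {
  # geometry built so the point is inside two triangles: one shares two
  # vertices with the initial triangle, the other shares none
  lib <- material_library(
    name = c("a", "b", "c", "d", "e", "f"),
    density_g_cm3 = rep(1, 6),
    mu_low_cm1 = c(0, 4, 2, 2, -3, 9) + 5,
    mu_high_cm1 = c(0, 0, 3, -2, -4, 6) + 5
  )
  p <- c(2, 0.5) + 5
  initial <- triangle(lib, c("a", "b", "d"))      # does not contain p
  expect_false(solve_barycentric(p, initial)$inside)
  shares2 <- triangle(lib, c("a", "b", "c"))      # contains p, shares a, b
  sharesnone <- triangle(lib, c("c", "e", "f"))   # contains p, shares none
  expect_true(solve_barycentric(p, shares2)$inside)
  expect_true(solve_barycentric(p, sharesnone)$inside)
  d2 <- bidirectional_hausdorff(shares2$coords, initial$coords)
  d0 <- bidirectional_hausdorff(sharesnone$coords, initial$coords)
  expect_lt(d2, d0)
  cl <- cluster_materials(lib, radius = 0.01)
  out <- select_triangle(p, initial, lib, cl)
  expect_setequal(out$names, c("a", "b", "c"))
})

test_that("a point outside the library hull raises the outside-hull signal", {
  lib <- default_material_library(c("air", "blood", "fat", "bone"))
  cl <- cluster_materials(lib)
  initial <- triangle(lib, c("air", "blood", "fat"))
  expect_error(select_triangle(c(5, 0.1), initial, lib, cl),
               class = "mmdect_outside_hull")
})

test_that("the selected triangle always contains the query point", {
  set.seed(23)
  lib <- default_material_library(c("air", "blood", "fat", "bone"))
  cl <- cluster_materials(lib)
  co <- cbind(lib$mu_low_cm1, lib$mu_high_cm1)
  initial <- triangle(lib, c("air", "blood", "fat"))
  for (rep in 1:50) {
    w <- stats::rgamma(4, 1)
    w <- w / sum(w)
    p <- colSums(co * w)        # random point inside the hull
    out <- select_triangle(p, initial, lib, cl)
    expect_true(solve_barycentric(p, out)$inside)
  }
})
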