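lib_full <- default_material_library()

test_that("angio phantom geometry and composition follow the design", {
  spec <- make_angio_phantom()
  expect_equal(nrow(spec$vials), 12)
  expect_equal(spec$vials$r_mm, rep(6, 12))           # 12 mm diameter
  # vials pairwise disjoint on the ring
  d <- as.matrix(dist(cbind(spec$vials$cx_mm, spec$vials$cy_mm)))
  diag(d) <- Inf
  expect_true(all(d > 12))
  expect_error(make_angio_phantom(iodine_mg_ml = 1:7, koh_percent = 1:6),
               "12")
  # zero concentration everywhere renders indistinguishable from water
  spec0 <- make_angio_phantom(iodine_mg_ml = rep(0, 3), koh_percent = rep(0, 3))
  pair0 <- render_dect(spec0, lib_full)
  water_disk <- mmdect:::disk_mask(spec0, 0, 0, 10)
  vial_disk <- mmdect:::disk_mask(spec0, spec0$vials$cx_mm[1],
                                  spec0$vials$cy_mm[1], 5)
  expect_equal(mean(pair0$low[vial_disk]), mean(pair0$low[water_disk]),
               tolerance = 1e-12)

  # one iodine vial: its mu excess over water is larger at low energy
  spec1 <- make_angio_phantom(iodine_mg_ml = 5, koh_percent = numeric(0))
  pair1 <- render_dect(spec1, lib_full)
  vd <- mmdect:::disk_mask(spec1, spec1$vials$cx_mm[1], spec1$vials$cy_mm[1], 4)
  muw <- c(0.222209, 0.194798)
  d_low <- mean(hu_to_mu(pair1$low[vd], muw[1])) - muw[1]
  d_high <- mean(hu_to_mu(pair1$high[vd], muw[2])) - muw[2]
  expect_gt(d_low, d_high)
  expect_gt(d_low, 0)
})

test_that("QA phantoms have pure inserts and correctly scaled pinholes", {
  body <- make_qa_body()
  pure <- vapply(body$shapes$composition,
                 function(cm) length(cm) == 1 && cm == 1, logical(1))
  expect_true(all(pure))

  head <- make_qa_head(c(1, 2, 3))
  expect_equal(head$pins$diameter_mm, c(1, 2, 3))
  truth <- render_dect(head, lib_full)$truth
  # supersampled air areas of the pins scale as 1:4:9
  areas <- vapply(seq_len(3), function(i) {
    m <- mmdect:::disk_mask(head, head$pins$cx_mm[i], head$pins$cy_mm[i],
                            head$pins$diameter_mm[i] / 2 + 1)
    sum(truth$air[m])
  }, numeric(1))
  expect_equal(areas / areas[1], c(1, 4, 9), tolerance = 0.05)
  expect_error(make_qa_head(c(0.2)), "0.5")
  expect_error(make_qa_head(c(6)), "0.5")
})

test_that("abdomen ground truth is a valid composition everywhere", {
  spec <- make_abdomen()
  pair <- render_dect(spec, lib_full)
  total <- Reduce("+", pair$truth)
  expect_equal(max(abs(total - 1)), 0, tolerance = 1e-12)
  expect_true(all(unlist(pair$truth) >= 0))
  # exterior pixels are pure air
  expect_equal(pair$truth$air[1, 1], 1)
  expect_equal(pair$truth$air[1, 256], 1)
  # bone contrast decreases with energy
  bone_mask <- mmdect:::disk_mask(spec, 0, -70, 10)
  expect_gt(mean(pair$low[bone_mask]), mean(pair$high[bone_mask]))
  # every ROI disk sits strictly inside its pure material region
  for (i in seq_len(nrow(spec$rois))) {
    r <- spec$rois[i, ]
    m <- mmdect:::disk_mask(spec, r$cx_mm, r$cy_mm, r$r_mm)
    expect_equal(mean(pair$truth[[r$material]][m]), 1,
                 tolerance = 1e-12, label = paste("ROI", i))
  }
})

test_that("rendering is deterministic and noise is calibrated", {
  spec <- make_qa_head()
  a <- render_dect(spec, lib_full, noise_sigma_hu = 10, seed = 123)
  b <- render_dect(spec, lib_full, noise_sigma_hu = 10, seed = 123)
  expect_identical(a$low, b$low)
  expect_identical(a$high, b$high)
  cc <- render_dect(spec, lib_full, noise_sigma_hu = 10, seed = 124)
  expect_false(identical(a$low, cc$low))

  # a pure-water spec renders exactly 0 HU noiseless
  w <- phantom_spec(64, 1, "water",
                    mmdect:::shape_row("circle", 0, 0, c(water = 1), r = 10))
  pw <- render_dect(w, lib_full)
  expect_equal(max(abs(pw$low)), 0, tolerance = 1e-10)
  expect_equal(max(abs(pw$high)), 0, tolerance = 1e-10)

  # rendered noise sd within 10% of request over >= 1e4 uniform pixels
  noisy <- render_dect(w, lib_full, noise_sigma_hu = c(12, 7), seed = 5)
  expect_equal(stats::sd(noisy$low), 12, tolerance = 0.1)
  expect_equal(stats::sd(noisy$high), 7, tolerance = 0.1)

  # unknown material is a key error
  bad <- phantom_spec(16, 1, "air",
                      mmdect:::shape_row("circle", 0, 0, c(unobtanium = 1), r = 4))
  expect_error(render_dect(bad, lib_full), "unobtanium")
})

test_that("phantom specs reject invalid compositions and geometry", {
  expect_error(
    phantom_spec(64, 1, "air",
                 mmdect:::shape_row("circle", 0, 0, c(water = 0.7), r = 5)),
    "sum to 1")
  expect_error(
    phantom_spec(64, 1, "air",
                 mmdect:::shape_row("circle", 60, 0, c(water = 1), r = 10)),
    "fit")
})
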