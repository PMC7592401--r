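#' Construct a phantom specification
#'
#' A phantom spec is a geometric description of a 2-D test object: a grid,
#' a background material, and an ordered list of shapes painted onto it
#' (later shapes overwrite earlier ones where they cover). Each shape
#' carries a per-material volume-fraction composition summing to 1.
#' Coordinates are in mm with the origin at the grid centre; x runs along
#' columns, y along rows (upward).
#'
#' @param n grid size, `c(rows, cols)` or a scalar.
#' @param spacing_mm pixel spacing in mm (> 0).
#' @param background background material name.
#' @param shapes tibble with columns `geometry` (`"circle"`, `"annulus"`,
#'   `"ellipse"`, `"rect"`), `cx_mm`, `cy_mm`, size columns (`r_mm`,
#'   `r_in_mm`, `rx_mm`, `ry_mm`, `w_mm`, `h_mm` as the geometry needs)
#'   and list-column `composition` (named numeric, non-negative, sum 1).
#' @param rois,vials,pins optional metadata tibbles used by the evaluation
#'   stage (ROI disks, contrast vials, resolution pins).
#' @param name phantom name.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n, spacing_mm, background, shapes,
                         rois = NULL, vials = NULL, pins = NULL,
                         name = "phantom") {
  n <- rep_len(as.integer(n), 2)
  if (any(n < 1) || spacing_mm <= 0) abort("invalid grid or spacing")
  shapes <- tibble::as_tibble(shapes)
  half_x <- n[2] * spacing_mm / 2
  half_y <- n[1] * spacing_mm / 2
  for (i in seq_len(nrow(shapes))) {
    comp <- shapes$composition[[i]]
    if (is.null(names(comp)) || any(comp < 0) || abs(sum(comp) - 1) > 1e-9) {
      abort("every shape composition must be named, non-negative and sum to 1")
    }
    ext <- shape_extent(shapes[i, ])
    if (abs(shapes$cx_mm[i]) + ext[1] > half_x ||
        abs(shapes$cy_mm[i]) + ext[2] > half_y) {
      abort(paste0("shape ", i, " does not fit inside the grid"))
    }
  }
  structure(list(n = n, spacing_mm = spacing_mm, background = background,
                 shapes = shapes, rois = rois, vials = vials, pins = pins,
                 name = name),
            class = "phantom_spec")
}

shape_extent <- function(s) {
  switch(s$geometry,
    circle = rep(s$r_mm, 2),
    annulus = rep(s$r_mm, 2),
    ellipse = c(s$rx_mm, s$ry_mm),
    rect = c(s$w_mm / 2, s$h_mm / 2),
    abort(paste0("unknown geometry: ", s$geometry))
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$name, ": ", x$n[1], "x", x$n[2], " @ ",
      x$spacing_mm, " mm, background ", x$background, ", ",
      nrow(x$shapes), " shape(s)\n", sep = "")
  invisible(x)
}

shape_row <- function(geometry, cx, cy, composition, r = NA, r_in = NA,
                      rx = NA, ry = NA, w = NA, h = NA) {
  tibble::tibble(geometry = geometry, cx_mm = cx, cy_mm = cy, r_mm = r,
                 r_in_mm = r_in, rx_mm = rx, ry_mm = ry, w_mm = w, h_mm = h,
                 composition = list(composition))
}

pure <- function(material) setNames(1, material)

#' Synthetic angiography phantom (contrast and calcium-surrogate vials)
#'
#' A water-filled Plexiglas cylinder holding up to 12 circular vials of
#' 12 mm diameter on a ring, filled with dilutions of an iodinated
#' contrast stock (350 mg iodine/ml) and of a 50% w/w KOH stock (the
#' calcium-plaque surrogate). Iodine vials are parameterized directly in
#' mg iodine per ml; a vial at concentration c holds a volume fraction
#' c/350 of the stock in water. KOH vials are parameterized in % w/w,
#' converted to a stock volume fraction via the solution densities.
#'
#' @param iodine_mg_ml iodine concentrations, one vial each (default 1-10
#'   mg/ml; the lowest, about 1 mg/ml, matches the weakest clinically
#'   realistic enhancement).
#' @param koh_percent KOH concentrations in % w/w (default 5-50%).
#' @return A `phantom_spec` (256 x 256, 0.5 mm pixels) whose `vials` table
#'   records each vial's solute, concentration and true stock volume and
#'   mass fractions.
#' @export
make_angio_phantom <- function(iodine_mg_ml = c(1, 2, 3, 4, 5, 10),
                               koh_percent = c(5, 10, 20, 30, 40, 50)) {
  n_vials <- length(iodine_mg_ml) + length(koh_percent)
  if (n_vials > 12) abort("the angiography phantom holds at most 12 vials")
  lib <- default_material_library()

  shapes <- dplyr::bind_rows(
    shape_row("circle", 0, 0, pure("acrylic"), r = 60),   # Plexiglas casing
    shape_row("circle", 0, 0, pure("water"), r = 56)
  )
  vial_r <- 6          # 12 mm diameter
  ring_r <- 38
  angles <- (seq_len(12) - 1) * 2 * pi / 12
  vials <- list()
  slot <- 0
  for (c_i in iodine_mg_ml) {
    slot <- slot + 1
    a <- angles[slot]
    alpha <- c_i / 350
    comp <- c(omnipaque350 = alpha, water = 1 - alpha)
    shapes <- dplyr::bind_rows(shapes,
      shape_row("circle", ring_r * cos(a), ring_r * sin(a), comp, r = vial_r))
    vials[[slot]] <- tibble::tibble(
      vial = slot, solute = "omnipaque350", concentration = c_i,
      conc_units = "mg I/ml", cx_mm = ring_r * cos(a), cy_mm = ring_r * sin(a),
      r_mm = vial_r, stock_volume_fraction = alpha,
      stock_mass_fraction = true_stock_mass_fraction(comp, lib, "omnipaque350")
    )
  }
  for (p in koh_percent) {
    slot <- slot + 1
    a <- angles[slot]
    w <- p / 100
    # stock volume fraction v solving w = 0.5*1.514*v / (1.514*v + (1-v))
    v <- w / (0.757 - 0.514 * w)
    comp <- c(koh50 = v, water = 1 - v)
    shapes <- dplyr::bind_rows(shapes,
      shape_row("circle", ring_r * cos(a), ring_r * sin(a), comp, r = vial_r))
    vials[[slot]] <- tibble::tibble(
      vial = slot, solute = "koh50", concentration = p,
      conc_units = "% w/w KOH", cx_mm = ring_r * cos(a), cy_mm = ring_r * sin(a),
      r_mm = vial_r, stock_volume_fraction = v,
      stock_mass_fraction = true_stock_mass_fraction(comp, lib, "koh50")
    )
  }
  phantom_spec(256, 0.5, "air", shapes, vials = dplyr::bind_rows(vials),
               name = "angiography")
}

true_stock_mass_fraction <- function(comp, lib, stock) {
  m <- volume_to_mass_fraction(comp, lib)
  unname(m[stock])
}

#' Synthetic CT quality-assurance phantom, body section
#'
#' Water cylinder in an acrylic casing, holding pure inserts of Water,
#' Lexan, Acrylic and Teflon plus air holes of several diameters.
#'
#' @return A `phantom_spec` (256 x 256, 0.8 mm pixels); `rois` marks a
#'   disk inside each insert.
#' @export
make_qa_body <- function() {
  ring_r <- 55
  mats <- c("water", "lexan", "acrylic", "teflon")
  ang <- c(45, 135, 225, 315) * pi / 180
  shapes <- dplyr::bind_rows(
    shape_row("circle", 0, 0, pure("acrylic"), r = 95),
    shape_row("circle", 0, 0, pure("water"), r = 90)
  )
  for (i in seq_along(mats)) {
    shapes <- dplyr::bind_rows(shapes,
      shape_row("circle", ring_r * cos(ang[i]), ring_r * sin(ang[i]),
                pure(mats[i]), r = 12))
  }
  hole_d <- c(2, 4, 6)
  for (i in seq_along(hole_d)) {
    shapes <- dplyr::bind_rows(shapes,
      shape_row("circle", -20 + 20 * (i - 1), 0, pure("air"), r = hole_d[i] / 2))
  }
  rois <- tibble::tibble(
    material = mats, cx_mm = ring_r * cos(ang), cy_mm = ring_r * sin(ang),
    r_mm = 8
  )
  phantom_spec(256, 0.8, "air", shapes, rois = rois, name = "qa_body")
}

#' @rdname make_qa_body
#' @param pin_diameters_mm air-pinhole diameters in mm, each in
#'   `[0.5, 5]`; default 1, 2 and 3 mm, the range used to probe spatial
#'   resolution.
#' @export
make_qa_head <- function(pin_diameters_mm = c(1, 2, 3)) {
  if (any(pin_diameters_mm < 0.5 | pin_diameters_mm > 5)) {
    abort("pin diameters must lie in [0.5, 5] mm")
  }
  shapes <- dplyr::bind_rows(
    shape_row("circle", 0, 0, pure("acrylic"), r = 44),
    shape_row("circle", 0, 0, pure("water"), r = 40)
  )
  npin <- length(pin_diameters_mm)
  ang <- (seq_len(npin) - 1) * 2 * pi / max(npin, 1)
  pins <- tibble::tibble(
    diameter_mm = pin_diameters_mm,
    cx_mm = 20 * cos(ang), cy_mm = 20 * sin(ang)
  )
  for (i in seq_len(npin)) {
    shapes <- dplyr::bind_rows(shapes,
      shape_row("circle", pins$cx_mm[i], pins$cy_mm[i], pure("air"),
                r = pins$diameter_mm[i] / 2))
  }
  phantom_spec(192, 0.5, "air", shapes, pins = pins, name = "qa_head")
}

#' Synthetic abdominal DECT slice
#'
#' An elliptical body with a subcutaneous fat ring, blood-equivalent soft
#' tissue, visceral fat deposits, a bone (spine) region and air (bowel gas
#' and exterior). Region boundaries are kept disjoint so every pixel mixes
#' at most two materials (partial volume at one boundary). The `rois`
#' table marks 8 blood and 8 fat disks strictly interior to their regions.
#'
#' @return A `phantom_spec` (256 x 256, 1.5 mm pixels) with ROI metadata.
#' @export
make_abdomen <- function() {
  shapes <- dplyr::bind_rows(
    shape_row("ellipse", 0, 0, pure("fat"), rx = 170, ry = 115),   # body + subcut fat
    shape_row("ellipse", 0, 0, pure("blood"), rx = 152, ry = 97),  # soft tissue
    shape_row("circle", 0, -70, pure("bone"), r = 14),             # spine
    shape_row("circle", -48, 28, pure("air"), r = 8),              # bowel gas
    shape_row("circle", -20, 48, pure("air"), r = 6),
    # visceral fat deposits
    shape_row("circle", 55, 28, pure("fat"), r = 9),
    shape_row("circle", 64, -18, pure("fat"), r = 9),
    shape_row("circle", -70, -18, pure("fat"), r = 9),
    shape_row("circle", -84, 12, pure("fat"), r = 9)
  )
  blood_rois <- tibble::tibble(
    material = "blood",
    cx_mm = c(0, 30, -30, 80, 110, -110, 30, -55),
    cy_mm = c(40, -20, -35, 30, -20, 20, 70, 60),
    r_mm = 7
  )
  fat_rois <- tibble::tibble(
    material = "fat",
    cx_mm = c(55, 64, -70, -84, 0, 0, 161, -161),
    cy_mm = c(28, -18, -18, 12, 106, -106, 0, 0),
    r_mm = c(5, 5, 5, 5, 5, 5, 4, 4)
  )
  phantom_spec(256, 1.5, "air", shapes,
               rois = dplyr::bind_rows(blood_rois, fat_rois), name = "abdomen")
}

#' Render a phantom spec as a dual-energy CT image pair
#'
#' Forward model: per pixel and energy the linear attenuation is the
#' composition-weighted sum of the library materials' coefficients,
#' \eqn{\mu(E) = \sum_i \alpha_i \mu_i(E)}. Shape boundaries are handled
#' by 4x4 supersampling (16 area samples per pixel), so boundary pixels
#' carry genuine partial-volume mixtures. The attenuation maps are
#' converted to HU per energy and independent additive Gaussian noise of
#' the requested sd is applied with the given seed.
#'
#' @param spec a `phantom_spec`.
#' @param library a [material_library()] containing every material the
#'   spec uses.
#' @param kvp_pair tube voltages, metadata only.
#' @param noise_sigma_hu per-energy Gaussian noise sd in HU (length 1 or
#'   2); 0 renders noiseless.
#' @param seed RNG seed for the noise (the caller's RNG state is
#'   preserved).
#' @return A list of class `dect_pair`: `low`, `high` (HU matrices),
#'   `kvp`, `spacing_mm`, `units = "hu"`, `truth` (named list of
#'   ground-truth volume-fraction matrices) and `spec`.
#' @export
render_dect <- function(spec, library = default_material_library(),
                        kvp_pair = c(80, 140), noise_sigma_hu = c(0, 0),
                        seed = 0) {
  mats <- unique(c(spec$background,
                   unlist(lapply(spec$shapes$composition, names))))
  unknown <- setdiff(mats, library$name)
  if (length(unknown)) {
    abort(paste0("phantom uses materials absent from the library: ",
                 paste(unknown, collapse = ", ")))
  }
  truth <- phantom_truth(spec, mats)
  mu_of <- function(which) {
    col <- if (which == "low") library$mu_low_cm1 else library$mu_high_cm1
    mu <- matrix(0, spec$n[1], spec$n[2])
    for (m in mats) mu <- mu + truth[[m]] * col[match(m, library$name)]
    mu
  }
  muw <- water_mu(library)
  low <- mu_to_hu(mu_of("low"), muw[1])
  high <- mu_to_hu(mu_of("high"), muw[2])
  sig <- rep_len(noise_sigma_hu, 2)
  if (any(sig > 0)) {
    noise <- with_preserved_seed(seed, list(
      rnorm(length(low), 0, 1), rnorm(length(high), 0, 1)
    ))
    low <- low + sig[1] * matrix(noise[[1]], spec$n[1], spec$n[2])
    high <- high + sig[2] * matrix(noise[[2]], spec$n[1], spec$n[2])
  }
  structure(list(low = low, high = high, kvp = kvp_pair,
                 spacing_mm = spec$spacing_mm, units = "hu", mu_water = muw,
                 truth = truth, spec = spec),
            class = "dect_pair")
}

# Ground-truth composition maps: painter's algorithm with supersampled
# area-fraction coverage per shape.
phantom_truth <- function(spec, mats) {
  truth <- setNames(lapply(mats, function(m) {
    matrix(as.numeric(m == spec$background), spec$n[1], spec$n[2])
  }), mats)
  for (i in seq_len(nrow(spec$shapes))) {
    s <- spec$shapes[i, ]
    cov <- shape_coverage(s, spec$n, spec$spacing_mm)
    comp <- s$composition[[1]]
    for (m in mats) {
      cm <- if (m %in% names(comp)) comp[[m]] else 0
      truth[[m]] <- truth[[m]] * (1 - cov) + cov * cm
    }
  }
  truth
}

shape_coverage <- function(s, n, spacing, ss = 4) {
  xc <- (seq_len(n[2]) - (n[2] + 1) / 2) * spacing
  yc <- ((n[1] + 1) / 2 - seq_len(n[1])) * spacing   # row 1 = top
  off <- ((seq_len(ss) - (ss + 1) / 2) / ss) * spacing
  cov <- matrix(0, n[1], n[2])
  for (ox in off) for (oy in off) {
    X <- matrix(xc + ox, n[1], n[2], byrow = TRUE)
    Y <- matrix(yc + oy, n[1], n[2])
    cov <- cov + shape_inside(s, X, Y)
  }
  cov / ss^2
}

shape_inside <- function(s, X, Y) {
  dx <- X - s$cx_mm
  dy <- Y - s$cy_mm
  switch(s$geometry,
    circle = (dx^2 + dy^2 <= s$r_mm^2) + 0,
    annulus = {
      d2 <- dx^2 + dy^2
      (d2 <= s$r_mm^2 & d2 > s$r_in_mm^2) + 0
    },
    ellipse = ((dx / s$rx_mm)^2 + (dy / s$ry_mm)^2 <= 1) + 0,
    rect = (abs(dx) <= s$w_mm / 2 & abs(dy) <= s$h_mm / 2) + 0
  )
}

#' @export
print.dect_pair <- function(x, ...) {
  cat("<dect_pair> ", nrow(x$low), "x", ncol(x$low), " @ ", x$spacing_mm,
      " mm, ", x$kvp[1], "/", x$kvp[2], " kVp, units ", x$units, "\n", sep = "")
  invisible(x)
}

# mask of pixel centres within a metadata disk (ROI, vial, pin)
disk_mask <- function(spec, cx_mm, cy_mm, r_mm, shrink_mm = 0) {
  xc <- (seq_len(spec$n[2]) - (spec$n[2] + 1) / 2) * spec$spacing_mm
  yc <- ((spec$n[1] + 1) / 2 - seq_len(spec$n[1])) * spec$spacing_mm
  X <- matrix(xc, spec$n[1], spec$n[2], byrow = TRUE)
  Y <- matrix(yc, spec$n[1], spec$n[2])
  (X - cx_mm)^2 + (Y - cy_mm)^2 <= (r_mm - shrink_mm)^2
}
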