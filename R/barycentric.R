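#' Material triangles in attenuation space
#'
#' A triangle is an ordered triplet of library materials serving as
#' barycentric vertices. It is non-degenerate when its vertices are not
#' collinear in the \eqn{(\mu_{low}, \mu_{high})} plane.
#'
#' @param library a [material_library()].
#' @param vertices character vector of 3 material names, or integer indices
#'   into the library.
#' @return A list of class `material_triangle` with `names` (length 3) and
#'   `coords` (3 x 2 matrix of attenuation coordinates).
#' @export
triangle <- function(library, vertices) {
  if (length(vertices) != 3) abort("a triangle needs exactly 3 vertices")
  if (is.character(vertices)) {
    idx <- match(vertices, library$name)
    if (anyNA(idx)) abort(paste0("unknown materials: ",
                                 paste(vertices[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(vertices)
  }
  structure(
    list(names = library$name[idx], coords = lib_coords(library)[idx, , drop = FALSE],
         idx = idx),
    class = "material_triangle"
  )
}

# 3x3 system matrix of a triangle: rows mu_low, mu_high, volume conservation
triangle_matrix <- function(coords) {
  rbind(coords[, 1], coords[, 2], c(1, 1, 1))
}

triangle_degenerate <- function(coords, tol = 1e-12) {
  # determinant of the 3x3 system equals twice the signed triangle area
  det3 <- det(triangle_matrix(coords))
  scale <- max(abs(coords), 1e-30)
  abs(det3) < tol * scale^2
}

#' Solve per-pixel volume fractions as barycentric coordinates
#'
#' Solves the 3x3 linear system `A x = b` whose first two rows are the
#' vertex attenuation coefficients at the low and high energies and whose
#' third row of ones enforces volume conservation
#' (\eqn{\alpha_1+\alpha_2+\alpha_3 = 1}); `b` is the pixel's measured
#' \eqn{(\mu_{low}, \mu_{high}, 1)}. The solution is the pixel's
#' barycentric coordinate with respect to the triangle: when the point lies
#' inside, each \eqn{\alpha_i} equals the area of the sub-triangle opposite
#' vertex i over the total area, and all fractions are non-negative.
#'
#' @param point numeric length-2 vector `c(mu_low, mu_high)`.
#' @param triangle a [triangle()] (or any list with a 3 x 2 `coords`
#'   matrix).
#' @param tol containment tolerance: the point counts as inside when
#'   `min(fractions) >= -tol`.
#' @return A list of class `volume_fractions` with `fractions` (length 3,
#'   summing to 1), `inside` (logical) and `residual` (norm of
#'   `A x - b`, zero up to round-off for a non-degenerate solve).
#' @examples
#' lib <- default_material_library(c("air", "blood", "fat"))
#' tri <- triangle(lib, c("air", "blood", "fat"))
#' solve_barycentric(c(0.21, 0.19), tri)
#' @export
solve_barycentric <- function(point, triangle, tol = 1e-9) {
  coords <- triangle$coords
  if (triangle_degenerate(coords)) {
    abort(paste0("degenerate triangle (collinear vertices): ",
                 paste(triangle$names %||% seq_len(3), collapse = ", ")))
  }
  A <- triangle_matrix(coords)
  b <- c(point[1], point[2], 1)
  x <- solve(A, b)
  structure(
    list(fractions = as.numeric(x), inside = min(x) >= -tol,
         residual = sqrt(sum((A %*% x - b)^2))),
    class = "volume_fractions"
  )
}

# Vectorized barycentric solve: points is n x 2; returns n x 3 fractions.
solve_barycentric_many <- function(points, coords) {
  A <- triangle_matrix(coords)
  B <- rbind(t(points), rep(1, nrow(points)))
  t(solve(A, B))
}

#' Convert volume fractions to mass fractions
#'
#' Mass fractions weight each material's volume fraction by its density:
#' \eqn{m_i = \alpha_i \rho_i / \sum_j \alpha_j \rho_j}. This is the
#' quantity concentration plots report.
#'
#' @param fractions named numeric vector of per-material volume fractions
#'   (non-negative, summing to 1), names matching library materials; or an
#'   unnamed vector aligned with `library` rows.
#' @param library a [material_library()] supplying densities.
#' @return Named numeric vector of mass fractions summing to 1.
#' @examples
#' lib <- default_material_library(c("water", "bone"))
#' volume_to_mass_fraction(c(water = 0.5, bone = 0.5), lib)
#' @export
volume_to_mass_fraction <- function(fractions, library) {
  if (!is.null(names(fractions))) {
    idx <- match(names(fractions), library$name)
    if (anyNA(idx)) abort("fraction names must match library materials")
    rho <- library$density_g_cm3[idx]
  } else {
    if (length(fractions) != nrow(library)) {
      abort("unnamed fractions must align with library rows")
    }
    rho <- library$density_g_cm3
    names(fractions) <- library$name
  }
  w <- fractions * rho
  total <- sum(w)
  if (total <= 0) abort("all-zero density weighting: fractions give no mass")
  w / total
}

#' @export
print.volume_fractions <- function(x, ...) {
  cat("<volume_fractions> ", paste(signif(x$fractions, 6), collapse = ", "),
      if (x$inside) " (inside)" else " (outside)", "\n", sep = "")
  invisible(x)
}
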