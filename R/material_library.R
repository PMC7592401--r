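#' Build a material attenuation library
#'
#' A material library is a tibble with one row per material carrying its
#' mass density and linear attenuation coefficients at the two effective
#' energies of a dual-energy CT acquisition. It is the coordinate system in
#' which every decomposition happens: each material is a point in the 2-D
#' attenuation plane \eqn{(\mu_{low}, \mu_{high})}, and per-pixel volume
#' fractions are barycentric coordinates with respect to triangles of these
#' points.
#'
#' @param name character vector of unique material names.
#' @param density_g_cm3 mass densities in g/cm^3, all > 0.
#' @param mu_low_cm1,mu_high_cm1 linear attenuation coefficients (cm^-1) at
#'   the low- and high-energy settings, all >= 0.
#' @param group group label per material; clustering and triangle search are
#'   restricted to one group at a time. Default: a single group.
#' @param kvp_pair the two tube voltages (kVp) the coefficients correspond
#'   to, low first.
#'
#' @return A tibble of class `material_library` with columns `name`,
#'   `density_g_cm3`, `mu_low_cm1`, `mu_high_cm1`, `group` and attribute
#'   `kvp_pair`.
#' @examples
#' material_library(
#'   name = c("water", "bone"),
#'   density_g_cm3 = c(1, 1.92),
#'   mu_low_cm1 = c(0.222, 0.764),
#'   mu_high_cm1 = c(0.195, 0.511)
#' )
#' @export
material_library <- function(name, density_g_cm3, mu_low_cm1, mu_high_cm1,
                             group = "default", kvp_pair = c(80, 140)) {
  lib <- tibble::tibble(
    name = as.character(name),
    density_g_cm3 = as.numeric(density_g_cm3),
    mu_low_cm1 = as.numeric(mu_low_cm1),
    mu_high_cm1 = as.numeric(mu_high_cm1),
    group = rep_len(as.character(group), length(name))
  )
  validate_material_library(lib)
  attr(lib, "kvp_pair") <- as.numeric(kvp_pair)
  class(lib) <- c("material_library", class(lib))
  lib
}

validate_material_library <- function(lib) {
  if (nrow(lib) == 0) abort("material library must contain at least one material")
  if (anyDuplicated(lib$name)) abort("material names must be unique within a library")
  if (any(lib$density_g_cm3 <= 0)) abort("material densities must be positive")
  if (any(lib$mu_low_cm1 < 0) || any(lib$mu_high_cm1 < 0)) {
    abort("linear attenuation coefficients must be non-negative")
  }
  coords <- paste(signif(lib$mu_low_cm1, 12), signif(lib$mu_high_cm1, 12))
  if (anyDuplicated(coords)) {
    abort("degenerate library: two materials share identical (mu_low, mu_high) coordinates")
  }
  invisible(lib)
}

#' Read and write material libraries as delimited tables
#'
#' @param path file path of a CSV with columns `name`, `density_g_cm3`,
#'   `mu_low_cm1`, `mu_high_cm1` and optionally `group`.
#' @param kvp_pair tube voltages the table's coefficients refer to.
#' @return `read_material_library()` returns a `material_library` tibble.
#' @export
read_material_library <- function(path, kvp_pair = c(80, 140)) {
  if (!file.exists(path)) abort(paste0("material library file not found: ", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "density_g_cm3", "mu_low_cm1", "mu_high_cm1")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    abort(paste0("material library table lacks columns: ", paste(missing, collapse = ", ")))
  }
  material_library(tab$name, tab$density_g_cm3, tab$mu_low_cm1, tab$mu_high_cm1,
                   group = if ("group" %in% names(tab)) tab$group else "default",
                   kvp_pair = kvp_pair)
}

#' @rdname read_material_library
#' @param library a `material_library`.
#' @export
write_material_library <- function(library, path) {
  write.csv(as.data.frame(library), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged material library at 80/140 kVp effective energies
#'
#' Linear attenuation coefficients for air, water, blood, fat, cortical
#' bone, Lexan, Acrylic, Teflon, 50% w/w KOH solution and an iodinated
#' contrast stock (350 mg iodine/ml), evaluated at the effective energies
#' of 80 and 140 kVp spectra (52 and 69 keV). Values were derived once from
#' standard photon mass-attenuation tabulations (generation script under
#' `inst/scripts/`) and frozen in `inst/extdata/`.
#'
#' @param materials optional character vector restricting the library to a
#'   subset (order preserved as given).
#' @return A `material_library` tibble.
#' @examples
#' default_material_library(c("air", "blood", "fat", "bone"))
#' @export
default_material_library <- function(materials = NULL) {
  path <- system.file("extdata", "material_library_80_140kvp.csv",
                      package = "mmdect", mustWork = TRUE)
  lib <- read_material_library(path, kvp_pair = c(80, 140))
  if (!is.null(materials)) {
    missing <- setdiff(materials, lib$name)
    if (length(missing)) {
      abort(paste0("unknown library materials: ", paste(missing, collapse = ", ")))
    }
    lib <- lib[match(materials, lib$name), ]
    validate_material_library(lib)
  }
  lib
}

#' Convert between Hounsfield units and linear attenuation
#'
#' Uses the defining CT relation \eqn{HU = 1000 (\mu - \mu_w) / \mu_w},
#' applied per energy: \eqn{\mu = \mu_w (1 + HU/1000)}, clipped below at 0
#' (no physical attenuation is negative).
#'
#' @param image_hu numeric vector or matrix of CT numbers (HU).
#' @param mu_water water linear attenuation (cm^-1) at the same energy; > 0.
#' @return Grid of linear attenuation coefficients, same shape as input.
#' @examples
#' hu_to_mu(c(-1000, 0, 1000), mu_water = 0.2222)
#' @export
hu_to_mu <- function(image_hu, mu_water) {
  if (!is.numeric(mu_water) || length(mu_water) != 1 || mu_water <= 0) {
    abort("mu_water must be a single positive number")
  }
  pmax(mu_water * (1 + image_hu / 1000), 0)
}

#' @rdname hu_to_mu
#' @param image_mu grid of linear attenuation coefficients (cm^-1).
#' @export
mu_to_hu <- function(image_mu, mu_water) {
  if (!is.numeric(mu_water) || length(mu_water) != 1 || mu_water <= 0) {
    abort("mu_water must be a single positive number")
  }
  1000 * (image_mu - mu_water) / mu_water
}

# internal: n x 2 matrix of library coordinates in attenuation space
lib_coords <- function(library) {
  cbind(library$mu_low_cm1, library$mu_high_cm1)
}

# internal: diagonal of the library's bounding box in attenuation space
lib_diagonal <- function(library) {
  sqrt(diff(range(library$mu_low_cm1))^2 + diff(range(library$mu_high_cm1))^2)
}
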