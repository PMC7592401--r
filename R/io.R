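#' Read a co-registered DECT image pair from files or matrices
#'
#' Supported formats: delimited numeric grids (`.csv`, `.tsv`, `.txt`) and
#' NIfTI (`.nii`, `.nii.gz`, first slice of a volume; requires the RNifti
#' package). Both images must have the same shape.
#'
#' @param low,high file paths or numeric matrices (low- and high-energy
#'   images).
#' @param units `"hu"` (default) or `"mu"`.
#' @param kvp_pair,spacing_mm metadata attached to the pair.
#' @return A `dect_pair` (without ground truth).
#' @export
read_dect_pair <- function(low, high, units = "hu", kvp_pair = c(80, 140),
                           spacing_mm = 1) {
  L <- read_image(low)
  H <- read_image(high)
  if (!identical(dim(L), dim(H))) {
    abort("mismatched image shapes between low- and high-energy images")
  }
  structure(list(low = L, high = H, kvp = kvp_pair, spacing_mm = spacing_mm,
                 units = units, truth = NULL, spec = NULL),
            class = "dect_pair")
}

read_image <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.character(x) || length(x) != 1) {
    abort("image input must be a matrix or a single file path")
  }
  if (!file.exists(x)) abort(paste0("image file not found: ", x))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", x)))
  if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    as.matrix(read.csv(x, header = FALSE, sep = sep))
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("reading NIfTI requires the RNifti package")
    }
    arr <- RNifti::readNifti(x)
    a <- as.array(arr)
    if (length(dim(a)) > 2) a <- a[, , 1]
    matrix(as.numeric(a), nrow(a), ncol(a))
  } else {
    abort(paste0("unsupported image format: .", ext))
  }
}

#' Write a decomposition's per-material fraction images
#'
#' One image per library material plus the triangle-id map and the
#' out-of-hull mask, as headerless CSV grids or NIfTI.
#'
#' @param vf a `vf_map`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (default) or `"nifti"`.
#' @return Invisibly, the written file paths.
#' @export
write_vf_map <- function(vf, dir, format = c("csv", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(m, name) {
    if (format == "csv") {
      p <- file.path(dir, paste0(name, ".csv"))
      write.table(m, p, sep = ",", row.names = FALSE, col.names = FALSE)
    } else {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        abort("writing NIfTI requires the RNifti package")
      }
      p <- file.path(dir, paste0(name, ".nii"))
      RNifti::writeNifti(RNifti::asNifti(m), p)
    }
    p
  }
  for (m in colnames(vf$fractions)) {
    paths <- c(paths, wr(fraction_map(vf, m), paste0("fraction_", m)))
  }
  paths <- c(paths, wr(matrix(vf$triangle_id, vf$dim[1], vf$dim[2]), "triangle_id"))
  paths <- c(paths, wr(out_of_hull_mask(vf) + 0, "out_of_hull"))
  invisible(paths)
}

#' Write an evaluation report as delimited tables plus a text summary
#'
#' @param report an `mmd_report`.
#' @param dir output directory.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(report[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sum_path <- file.path(dir, "summary.txt")
  con <- file(sum_path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(c(paths, sum_path))
}
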