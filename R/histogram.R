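#' Two-dimensional histogram in the linear attenuation domain
#'
#' Bins the per-pixel \eqn{(\mu_{low}, \mu_{high})} coordinates of a DECT
#' image pair on a regular 2-D grid. The histogram is the working view in
#' which materials group by their response to X-ray photons; clustering and
#' triangle selection operate on the same coordinates.
#'
#' @param image_pair a `dect_pair` (see [render_dect()]) or a list with
#'   numeric matrices `low` and `high` of equal shape. Images in HU are
#'   converted to attenuation with the pair's water coefficients.
#' @param n_bins positive integer, number of bins per axis.
#' @param library material library used for the HU-to-mu conversion when
#'   the pair is in HU; defaults to the packaged library.
#' @return A list of class `attenuation_histogram` with `edges_low`,
#'   `edges_high` (length `n_bins + 1` bin boundaries covering the data
#'   range exactly) and the `n_bins x n_bins` integer matrix `counts`
#'   (rows index the low-energy axis). `sum(counts)` equals the pixel
#'   count.
#' @export
build_histogram2d <- function(image_pair, n_bins, library = default_material_library()) {
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1) {
    abort("n_bins must be a positive integer")
  }
  n_bins <- as.integer(n_bins)
  pair <- as_mu_pair(image_pair, library)
  low <- pair$low
  high <- pair$high
  if (length(low) == 0) abort("empty image")

  edges_low <- histogram_edges(low, n_bins)
  edges_high <- histogram_edges(high, n_bins)
  ix <- bin_index(low, edges_low)
  iy <- bin_index(high, edges_high)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ix, levels = seq_len(n_bins)),
               factor(iy, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  structure(
    list(edges_low = edges_low, edges_high = edges_high, counts = counts),
    class = "attenuation_histogram"
  )
}

histogram_edges <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) r[2] <- r[1] + max(abs(r[1]), 1) * 1e-9
  seq(r[1], r[2], length.out = n_bins + 1)
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin.int(pmax.int(i, 1L), length(edges) - 1L)
}

#' @export
print.attenuation_histogram <- function(x, ...) {
  cat("<attenuation_histogram> ", nrow(x$counts), "x", ncol(x$counts),
      " bins, ", sum(x$counts), " pixels\n", sep = "")
  invisible(x)
}

#' @rdname build_histogram2d
#' @param x an `attenuation_histogram`.
#' @param ... unused.
#' @method tidy attenuation_histogram
#' @export
tidy.attenuation_histogram <- function(x, ...) {
  nb <- nrow(x$counts)
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  tidyr::expand_grid(mu_low = mid(x$edges_low), mu_high = mid(x$edges_high)) |>
    dplyr::arrange(.data$mu_high, .data$mu_low) |>
    dplyr::mutate(count = as.vector(x$counts)) |>
    dplyr::arrange(dplyr::desc(.data$count))
}

#' @method autoplot attenuation_histogram
#' @export
autoplot.attenuation_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mu_low, .data$mu_high, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = expression(mu[low] ~ (cm^-1)), y = expression(mu[high] ~ (cm^-1)),
                  fill = "pixels", title = "2-D attenuation histogram")
}

# internal: coerce an image pair to linear attenuation units.
as_mu_pair <- function(image_pair, library) {
  if (inherits(image_pair, "dect_pair")) {
    low <- image_pair$low
    high <- image_pair$high
    units <- image_pair$units %||% "hu"
  } else if (is.list(image_pair) && all(c("low", "high") %in% names(image_pair))) {
    low <- image_pair$low
    high <- image_pair$high
    units <- image_pair$units %||% "hu"
  } else {
    abort("image_pair must be a dect_pair or a list with elements 'low' and 'high'")
  }
  if (!identical(dim(low), dim(high)) || length(low) != length(high)) {
    abort("mismatched image shapes between low- and high-energy images")
  }
  if (identical(units, "hu")) {
    muw <- image_pair$mu_water %||% water_mu(library)
    low <- hu_to_mu(low, muw[1])
    high <- hu_to_mu(high, muw[2])
  }
  list(low = low, high = high)
}

# water linear attenuation for the HU <-> mu conversion: taken from the
# library when present, else from the packaged default table
water_mu <- function(library) {
  i <- match("water", library$name)
  if (is.na(i)) {
    ref <- default_material_library("water")
    return(c(ref$mu_low_cm1, ref$mu_high_cm1))
  }
  c(library$mu_low_cm1[i], library$mu_high_cm1[i])
}
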