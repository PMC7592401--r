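# Independent oracles used to cross-check the implementation. These are
# deliberately naive and share no code with the package internals.

# directed Hausdorff by the plain O(|A||B|) max-min double loop
naive_directed_hausdorff <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 2)
  if (is.null(dim(B))) B <- matrix(B, ncol = 2)
  keep <- !(paste(A[, 1], A[, 2]) %in% paste(B[, 1], B[, 2]))
  A <- A[keep, , drop = FALSE]
  if (nrow(A) == 0) return(0)
  d_max <- 0
  for (i in seq_len(nrow(A))) {
    d_min <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < d_min) d_min <- d
    }
    if (d_min > d_max) d_max <- d_min
  }
  d_max
}

# barycentric coordinates by the sub-triangle area-ratio construction:
# alpha_i = area(opposite sub-triangle) / total area, signed areas so the
# identity also holds for exterior points
area_ratio_barycentric <- function(p, v1, v2, v3) {
  signed_area <- function(a, b, c) {
    0.5 * ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
  }
  total <- signed_area(v1, v2, v3)
  c(signed_area(p, v2, v3), signed_area(v1, p, v3), signed_area(v1, v2, p)) / total
}

# brute-force agglomeration: repeatedly merge the closest pair of groups
# whose merged members all stay within `radius` of the merged centroid
oracle_agglomerate <- function(pts, radius) {
  groups <- lapply(seq_len(nrow(pts)), identity)
  repeat {
    k <- length(groups)
    if (k < 2) break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        ci <- colMeans(pts[groups[[i]], , drop = FALSE])
        cj <- colMeans(pts[groups[[j]], , drop = FALSE])
        d <- sqrt(sum((ci - cj)^2))
        if (d >= best_d) next
        merged <- c(groups[[i]], groups[[j]])
        cm <- colMeans(pts[merged, , drop = FALSE])
        ok <- all(sqrt(rowSums((pts[merged, , drop = FALSE] -
                                  rep(cm, each = length(merged)))^2)) <= radius)
        if (ok) {
          best <- c(i, j)
          best_d <- d
        }
      }
    }
    if (is.null(best)) break
    groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    groups[[best[2]]] <- NULL
  }
  lapply(groups, sort)
}

# canonical form of a partition for comparison
partition_key <- function(groups) {
  sorted <- lapply(groups, sort)
  paste(sort(vapply(sorted, paste, character(1), collapse = ",")), collapse = ";")
}

# a small well-spread test library (coordinates chosen in convex position)
toy_library <- function() {
  material_library(
    name = c("a", "b", "c", "d"),
    density_g_cm3 = c(0.001, 1, 0.95, 1.9),
    mu_low_cm1 = c(0.00, 0.22, 0.20, 0.76),
    mu_high_cm1 = c(0.00, 0.20, 0.18, 0.51)
  )
}

psnr <- function(x, ref) {
  10 * log10(diff(range(ref))^2 / mean((x - ref)^2))
}

# piecewise-constant test image used by the denoising tests
denoise_phantom <- function(n = 128) {
  img <- matrix(0, n, n)
  img[20:70, 30:100] <- 100
  img[80:110, 10:60] <- -60
  img[40:55, 60:120] <- 180
  img
}
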