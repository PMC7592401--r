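#' Local clustering of the material library in attenuation space
#'
#' Materials responding similarly to X-ray photons lie close together in
#' the 2-D attenuation plane; grouping them into clusters shrinks the
#' search domain for the per-pixel triangle selection and lets independent
#' groups be decomposed in parallel. Membership follows the Euclidean
#' distance to the cluster agent (the centroid of the member coordinates):
#' clusters are built by greedy agglomeration, repeatedly merging the
#' closest pair of clusters whose merged members would all stay within
#' `radius` of the recomputed centroid. Agglomeration is restricted to one
#' library group at a time. Ties (equal merge distances) are broken toward
#' the lowest library index, so the result is deterministic and, when all
#' pairwise distances are distinct, independent of material order.
#'
#' @param library a [material_library()].
#' @param radius Euclidean acceptance threshold in attenuation units
#'   (cm^-1); every member must lie within `radius` of its cluster agent.
#'   Default: 5% of the library's attenuation-space bounding-box diagonal.
#' @return A tibble of class `material_clusters`, one row per cluster, with
#'   columns `cluster` (index), `group`, `agent_low`, `agent_high` (agent
#'   coordinate), `radius` and list-column `members` (library material
#'   names).
#' @examples
#' lib <- default_material_library(c("air", "water", "blood", "fat", "bone"))
#' cluster_materials(lib)
#' @export
cluster_materials <- function(library, radius = NULL) {
  validate_material_library(library)
  if (is.null(radius)) radius <- 0.05 * lib_diagonal(library)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("radius must be a single positive number")
  }
  coords <- lib_coords(library)
  out <- list()
  for (g in unique(library$group)) {
    idx <- which(library$group == g)
    clusters <- agglomerate(coords[idx, , drop = FALSE], radius)
    for (cl in clusters) {
      mi <- idx[cl]
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g,
        agent_low = mean(coords[mi, 1]),
        agent_high = mean(coords[mi, 2]),
        radius = radius,
        members = list(library$name[mi]),
        member_idx = list(mi)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::mutate(res, cluster = dplyr::row_number(), .before = 1)
  class(res) <- c("material_clusters", class(res))
  attr(res, "library") <- library
  res
}

# Greedy agglomeration of points (n x 2) under a centroid-radius constraint.
# Returns a list of integer index vectors (into rows of pts), each sorted;
# clusters ordered by their smallest member index.
agglomerate <- function(pts, radius) {
  n <- nrow(pts)
  groups <- as.list(seq_len(n))
  repeat {
    k <- length(groups)
    if (k == 1) break
    cent <- t(vapply(groups, function(g) colMeans(pts[g, , drop = FALSE]), numeric(2)))
    d <- as.matrix(stats::dist(cent))
    d[upper.tri(d, diag = TRUE)] <- Inf
    best <- NULL
    ord <- order(d)  # ascending merge distance; ties resolved by position
    for (o in ord) {
      if (!is.finite(d[o])) break
      i <- (o - 1) %% k + 1
      j <- (o - 1) %/% k + 1
      merged <- sort(c(groups[[i]], groups[[j]]))
      cm <- colMeans(pts[merged, , drop = FALSE])
      dd <- sqrt((pts[merged, 1] - cm[1])^2 + (pts[merged, 2] - cm[2])^2)
      if (all(dd <= radius)) {
        best <- list(i = i, j = j, merged = merged)
        break
      }
    }
    if (is.null(best)) break
    groups[[min(best$i, best$j)]] <- best$merged
    groups[[max(best$i, best$j)]] <- NULL
  }
  groups[order(vapply(groups, min, numeric(1)))]
}

#' Assign an attenuation point to its nearest cluster
#'
#' Returns the cluster whose agent is nearest (Euclidean) to the query
#' point, provided that distance is within the cluster's acceptance radius;
#' otherwise signals "no cluster" by returning `NA`. Equidistant agents are
#' resolved toward the lower cluster index.
#'
#' @param point numeric length-2 vector `c(mu_low, mu_high)`.
#' @param clusters a `material_clusters` tibble from [cluster_materials()].
#' @return The matching cluster index (row of `clusters`), or `NA_integer_`
#'   when no agent lies within its radius of the point.
#' @export
assign_cluster <- function(point, clusters) {
  if (!inherits(clusters, "material_clusters") || nrow(clusters) == 0) {
    abort("clusters must be a non-empty material_clusters object")
  }
  d <- sqrt((clusters$agent_low - point[1])^2 + (clusters$agent_high - point[2])^2)
  i <- which.min(d)  # which.min takes the first minimum: lower index wins ties
  if (d[i] <= clusters$radius[i]) clusters$cluster[i] else NA_integer_
}

#' Augment clusters so that unassigned points become assignable
#'
#' When the existing sub-groups do not suffice — some attenuation points
#' fall outside every cluster's acceptance radius — new clusters are
#' created from those points (greedy agglomeration under the same radius
#' constraint) and appended; existing memberships are never changed.
#'
#' @inheritParams assign_cluster
#' @param library the library the clusters were built from.
#' @param unassigned matrix (n x 2) or length-2 vector of attenuation
#'   points for which [assign_cluster()] returned no cluster.
#' @return An augmented `material_clusters` tibble; with empty `unassigned`
#'   the input is returned unchanged.
#' @export
update_subgroups <- function(library, clusters, unassigned) {
  if (is.null(unassigned) || length(unassigned) == 0) return(clusters)
  if (is.null(dim(unassigned))) unassigned <- matrix(unassigned, ncol = 2)
  radius <- clusters$radius[1]
  new_groups <- agglomerate(unassigned, radius)
  add <- lapply(new_groups, function(g) {
    cm <- colMeans(unassigned[g, , drop = FALSE])
    tibble::tibble(group = clusters$group[1], agent_low = cm[1], agent_high = cm[2],
                   radius = radius, members = list(character(0)),
                   member_idx = list(integer(0)))
  })
  res <- dplyr::bind_rows(c(list(dplyr::select(clusters, -"cluster")), add))
  res <- dplyr::mutate(res, cluster = dplyr::row_number(), .before = 1)
  class(res) <- c("material_clusters", class(res))
  attr(res, "library") <- attr(clusters, "library")
  res
}

#' @export
print.material_clusters <- function(x, ...) {
  cat("<material_clusters> ", nrow(x), " cluster(s), radius ",
      signif(x$radius[1], 4), " cm^-1\n", sep = "")
  NextMethod()
}
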