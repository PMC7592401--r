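#' Re-select a containing triangle by Hausdorff similarity
#'
#' When a pixel's attenuation point falls outside the initial triangle its
#' fractions violate non-negativity, so a new triangle must be chosen that
#' contains the point. Among all candidate triangles that contain it —
#' every 3-combination of library materials in the search scope, plus
#' every triplet of cluster agents — the one most similar to the initial
#' triangle is returned, similarity being the bi-directional Hausdorff
#' distance between the two vertex sets. Ties are broken lexicographically
#' on sorted vertex names.
#'
#' @param point numeric length-2 attenuation coordinate.
#' @param initial a [triangle()]; if it already contains `point` it is
#'   returned unchanged.
#' @param library a [material_library()].
#' @param clusters optional `material_clusters`; supplies agent-triplet
#'   candidates and, with `scope = "group"`, restricts material candidates
#'   to the group of the cluster nearest the point.
#' @param convention Hausdorff convention, see [bidirectional_hausdorff()].
#' @param scope `"group"` (default; honours the reduced search domain of
#'   the local clustering) or `"library"` (whole-library enumeration).
#' @param tol containment tolerance passed to [solve_barycentric()].
#' @return A `material_triangle` containing the point. If no candidate
#'   contains it the point lies outside the library's convex hull and an
#'   error of class `mmdect_outside_hull` is signalled (callers such as
#'   [decompose_image()] catch it and clamp to the hull instead).
#' @export
select_triangle <- function(point, initial, library, clusters = NULL,
                            convention = "standard-max",
                            scope = c("group", "library"), tol = 1e-9) {
  scope <- match.arg(scope)
  if (!triangle_degenerate(initial$coords) &&
      solve_barycentric(point, initial, tol = tol)$inside) {
    return(initial)
  }
  cand <- candidate_triangles(library, clusters, point, scope)
  best <- NULL
  best_d <- Inf
  best_key <- NULL
  for (tri in cand) {
    if (triangle_degenerate(tri$coords)) next
    if (!solve_barycentric(point, tri, tol = tol)$inside) next
    d <- bidirectional_hausdorff(tri$coords, initial$coords, convention = convention)
    key <- paste(sort(tri$names), collapse = "|")
    # material triangles outrank agent triplets on exact ties ("~" sorts last)
    if (any(startsWith(tri$names, "agent:"))) key <- paste0("~", key)
    if (d < best_d - 1e-15 ||
        (abs(d - best_d) <= 1e-15 && !is.null(best_key) && key < best_key)) {
      best <- tri
      best_d <- d
      best_key <- key
    }
  }
  if (is.null(best)) {
    abort("no candidate triangle contains the point (outside the library's convex hull)",
          class = "mmdect_outside_hull")
  }
  best
}

# All candidate triangles: material 3-combinations (within scope) plus
# cluster-agent triplets (agents carry no material identity; their names
# are "agent:<cluster>").
candidate_triangles <- function(library, clusters, point = NULL, scope = "library") {
  mats <- seq_len(nrow(library))
  if (scope == "group" && !is.null(clusters) && !is.null(point)) {
    ci <- nearest_cluster(point, clusters)
    g <- clusters$group[ci]
    in_group <- which(library$group == g)
    if (length(in_group) >= 3) mats <- in_group
  }
  out <- list()
  if (length(mats) >= 3) {
    combs <- combn(mats, 3)
    for (k in seq_len(ncol(combs))) {
      out[[length(out) + 1L]] <- triangle(library, combs[, k])
    }
  }
  if (!is.null(clusters) && nrow(clusters) >= 3) {
    agents <- cbind(clusters$agent_low, clusters$agent_high)
    combs <- combn(seq_len(nrow(clusters)), 3)
    for (k in seq_len(ncol(combs))) {
      idx <- combs[, k]
      out[[length(out) + 1L]] <- structure(
        list(names = paste0("agent:", clusters$cluster[idx]),
             coords = agents[idx, , drop = FALSE], idx = NA),
        class = "material_triangle"
      )
    }
  }
  out
}

nearest_cluster <- function(point, clusters) {
  d <- sqrt((clusters$agent_low - point[1])^2 + (clusters$agent_high - point[2])^2)
  which.min(d)
}
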