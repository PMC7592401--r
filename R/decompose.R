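#' Decompose a DECT image pair into per-pixel material volume fractions
#'
#' The image-domain multi-material decomposition: every pixel is a point in
#' the 2-D linear attenuation plane, and its composition is the barycentric
#' coordinate of that point with respect to a triangle of library
#' materials. Per pixel the pipeline is: (1) form the initial triangle from
#' the three cluster agents nearest the point; (2) solve the constrained
#' 3x3 system; when the solve lands inside, the agent vertices are refined
#' to each cluster's member material nearest the point and the solve is
#' repeated on the refined vertices, so that pure-material pixels are
#' recovered exactly; (3) otherwise the triangle is re-selected among all
#' containing candidates by bi-directional Hausdorff similarity to the
#' initial triangle; (4) points outside the library's convex hull are
#' projected onto the hull boundary and flagged. Pixels are independent, so
#' the result does not depend on processing order (`chunks` splits the work
#' without changing any value).
#'
#' @param image_pair a `dect_pair` or list with matrices `low`, `high` (and
#'   optional `units`, `"hu"` assumed).
#' @param library a [material_library()].
#' @param clusters optional precomputed [cluster_materials()] result.
#' @param radius clustering radius when `clusters` is not supplied.
#' @param convention Hausdorff convention for triangle re-selection.
#' @param scope `"group"` or `"library"` candidate enumeration scope.
#' @param tol containment tolerance on barycentric fractions.
#' @param chunks number of row-blocks to process (order-independence
#'   contract; any value gives identical results).
#' @return An object of class `vf_map`: list with `fractions` (pixels x
#'   materials matrix; each row has at most 3 non-zero entries in `[0, 1]`
#'   summing to 1), `dim` (image dimensions), `triangle_id` (integer per
#'   pixel into `triangles`, a character vector of vertex-name keys),
#'   `out_of_hull` (logical per pixel), `library`, `clusters`.
#' @examples
#' lib <- default_material_library(c("air", "water", "bone"))
#' img <- list(low = matrix(0, 4, 4), high = matrix(0, 4, 4), units = "hu")
#' vf <- decompose_image(img, lib)
#' fraction_map(vf, "water")[1, 1]
#' @export
decompose_image <- function(image_pair, library, clusters = NULL, radius = NULL,
                            convention = "standard-max",
                            scope = c("group", "library"),
                            tol = 1e-9, chunks = 1) {
  scope <- match.arg(scope)
  validate_material_library(library)
  pair <- as_mu_pair(image_pair, library)
  dm <- dim(pair$low) %||% c(length(pair$low), 1L)
  if (is.null(clusters)) clusters <- cluster_materials(library, radius = radius)
  pts <- cbind(as.vector(pair$low), as.vector(pair$high))
  n <- nrow(pts)

  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / ceiling(n / chunks)))
  parts <- lapply(idx_chunks, function(ii) {
    decompose_points(pts[ii, , drop = FALSE], library, clusters, convention, scope, tol)
  })
  fractions <- do.call(rbind, lapply(parts, `[[`, "fractions"))
  tri_keys <- unlist(lapply(parts, `[[`, "tri_key"), use.names = FALSE)
  out_of_hull <- unlist(lapply(parts, `[[`, "out_of_hull"), use.names = FALSE)
  triangles <- sort(unique(tri_keys))
  structure(
    list(fractions = fractions, dim = dm,
         triangle_id = match(tri_keys, triangles), triangles = triangles,
         out_of_hull = out_of_hull, library = library, clusters = clusters),
    class = "vf_map"
  )
}

#' Decompose a single attenuation point
#'
#' Single-pixel interface to the same machinery as [decompose_image()].
#'
#' @inheritParams decompose_image
#' @param point numeric length-2 vector `c(mu_low, mu_high)` in cm^-1.
#' @return A list with `fractions` (named over the full library, at most 3
#'   non-zero, summing to 1), `triangle` (vertex names used) and
#'   `out_of_hull` flag.
#' @export
decompose_pixel <- function(point, clusters, library, convention = "standard-max",
                            scope = c("group", "library"), tol = 1e-9) {
  scope <- match.arg(scope)
  res <- decompose_points(matrix(point, ncol = 2), library, clusters,
                          convention, scope, tol)
  list(fractions = setNames(res$fractions[1, ], library$name),
       triangle = strsplit(res$tri_key[1], "|", fixed = TRUE)[[1]],
       out_of_hull = res$out_of_hull[1])
}

# Core vectorized solver over an n x 2 point matrix. Returns fractions
# (n x m over library), tri_key (character), out_of_hull (logical).
decompose_points <- function(pts, library, clusters, convention, scope, tol) {
  n <- nrow(pts)
  m <- nrow(library)
  coords <- lib_coords(library)
  fractions <- matrix(0, n, m, dimnames = list(NULL, library$name))
  tri_key <- character(n)
  out_of_hull <- logical(n)
  done <- logical(n)

  agents <- cbind(clusters$agent_low, clusters$agent_high)
  k <- nrow(agents)

  # --- stage 0: exact sparse representations ------------------------------
  # A point numerically on a library vertex or on the segment between two
  # materials has a unique sparsest composition; assign it directly. The
  # tolerance is far below any realistic noise level, so this stage only
  # fires for (numerically) exact data and never alters noisy solves.
  eps <- 1e-9 * max(lib_diagonal(library), 1e-12)
  Dm <- sqrt(point_dists(pts, coords))
  nearest_mat <- max.col(-Dm, ties.method = "first")
  at_vertex <- Dm[cbind(seq_len(n), nearest_mat)] <= eps
  if (any(at_vertex)) {
    sel <- which(at_vertex)
    fractions[cbind(sel, nearest_mat[sel])] <- 1
    tri_key[sel] <- library$name[nearest_mat[sel]]
    done[sel] <- TRUE
  }
  if (!all(done) && m >= 2) {
    pairs <- combn(m, 2)
    pend0 <- which(!done)
    for (pp in seq_len(ncol(pairs))) {
      if (!length(pend0)) break
      a <- coords[pairs[1, pp], ]
      b <- coords[pairs[2, pp], ]
      ab <- b - a
      len2 <- sum(ab^2)
      tt <- ((pts[pend0, 1] - a[1]) * ab[1] + (pts[pend0, 2] - a[2]) * ab[2]) / len2
      px <- a[1] + tt * ab[1]
      py <- a[2] + tt * ab[2]
      on_seg <- tt >= 0 & tt <= 1 &
        sqrt((pts[pend0, 1] - px)^2 + (pts[pend0, 2] - py)^2) <= eps
      if (any(on_seg)) {
        sel <- pend0[on_seg]
        fractions[cbind(sel, pairs[1, pp])] <- 1 - tt[on_seg]
        fractions[cbind(sel, pairs[2, pp])] <- tt[on_seg]
        tri_key[sel] <- paste(library$name[pairs[, pp]], collapse = "|")
        done[sel] <- TRUE
        pend0 <- pend0[!on_seg]
      }
    }
  }
  if (all(done)) {
    return(list(fractions = fractions, tri_key = tri_key, out_of_hull = out_of_hull))
  }

  # --- stage 1: initial agent triangles (3 nearest agents per point) ------
  if (k >= 3) {
    D <- point_dists(pts, agents)
    i1 <- max.col(-D, ties.method = "first")
    D[cbind(seq_len(n), i1)] <- Inf
    i2 <- max.col(-D, ties.method = "first")
    D[cbind(seq_len(n), i2)] <- Inf
    i3 <- max.col(-D, ties.method = "first")
    trip <- cbind(i1, i2, i3)
    trip_sorted <- t(apply(trip, 1, sort))
    init_id <- paste(trip_sorted[, 1], trip_sorted[, 2], trip_sorted[, 3])
  } else {
    # too few clusters for an agent triangle: nearest 3 materials instead
    D <- point_dists(pts, coords)
    i1 <- max.col(-D, ties.method = "first")
    D[cbind(seq_len(n), i1)] <- Inf
    i2 <- max.col(-D, ties.method = "first")
    D[cbind(seq_len(n), i2)] <- Inf
    i3 <- max.col(-D, ties.method = "first")
    trip_sorted <- t(apply(cbind(i1, i2, i3), 1, sort))
    init_id <- paste("m", trip_sorted[, 1], trip_sorted[, 2], trip_sorted[, 3])
  }

  member_idx <- clusters$member_idx
  singleton <- all(lengths(member_idx) == 1)

  init_coords_of <- function(id) {
    part <- strsplit(id, " ", fixed = TRUE)[[1]]
    if (part[1] == "m") coords[as.integer(part[-1]), , drop = FALSE]
    else agents[as.integer(part), , drop = FALSE]
  }

  for (id in unique(init_id)) {
    sel <- which(init_id == id & !done)
    if (!length(sel)) next
    part <- strsplit(id, " ", fixed = TRUE)[[1]]
    material_init <- part[1] == "m"
    vidx <- as.integer(if (material_init) part[-1] else part)
    vcoords <- if (material_init) coords[vidx, , drop = FALSE]
               else agents[vidx, , drop = FALSE]
    if (triangle_degenerate(vcoords)) next  # fall through to re-selection
    fr <- solve_barycentric_many(pts[sel, , drop = FALSE], vcoords)
    inside <- rowMins(fr) >= -tol
    if (!any(inside)) next
    sel_in <- sel[inside]
    if (material_init) {
      fractions[cbind(rep(sel_in, each = 3), rep(vidx, length(sel_in)))] <-
        as.vector(t(fr[inside, , drop = FALSE]))
      tri_key[sel_in] <- paste(library$name[vidx], collapse = "|")
      done[sel_in] <- TRUE
    } else {
      # refine agent vertices to each cluster's member nearest the point
      members <- lapply(vidx, function(ci) member_idx[[ci]])
      if (singleton || all(lengths(members) <= 1)) {
        midx <- vapply(members, function(x) if (length(x)) x[1] else NA_integer_,
                       integer(1))
        res <- assign_refined(pts, sel_in, midx, coords, library, fractions,
                              tri_key, done, tol)
        fractions <- res$fractions; tri_key <- res$tri_key; done <- res$done
      } else {
        midx_mat <- vapply(seq_along(members), function(j) {
          mm <- members[[j]]
          if (length(mm) == 1) rep(mm, length(sel_in))
          else mm[max.col(-point_dists(pts[sel_in, , drop = FALSE],
                                       coords[mm, , drop = FALSE]),
                          ties.method = "first")]
        }, integer(length(sel_in)))
        if (length(sel_in) == 1) midx_mat <- matrix(midx_mat, nrow = 1)
        key <- apply(midx_mat, 1, paste, collapse = " ")
        for (kk in unique(key)) {
          ss <- sel_in[key == kk]
          midx <- as.integer(strsplit(kk, " ", fixed = TRUE)[[1]])
          res <- assign_refined(pts, ss, midx, coords, library, fractions,
                                tri_key, done, tol)
          fractions <- res$fractions; tri_key <- res$tri_key; done <- res$done
        }
      }
    }
  }

  # --- stage 2: Hausdorff-guided re-selection for remaining points --------
  if (any(!done)) {
    pend <- which(!done)
    grp <- if (scope == "group") {
      nc <- max.col(-point_dists(pts[pend, , drop = FALSE], agents),
                    ties.method = "first")
      clusters$group[nc]
    } else rep("(library)", length(pend))

    for (g in unique(grp)) {
      gsel <- pend[grp == g]
      mats <- if (scope == "group") which(library$group == g) else seq_len(m)
      if (length(mats) < 3) mats <- seq_len(m)
      cand <- enumerate_candidates(mats, coords, library, agents, clusters)
      # pre-solve every candidate for all pending points of this group
      solved <- lapply(cand, function(cc) {
        if (cc$degenerate) return(NULL)
        fr <- solve_barycentric_many(pts[gsel, , drop = FALSE], cc$coords)
        list(fr = fr, inside = rowMins(fr) >= -tol)
      })
      for (id in unique(init_id[gsel])) {
        isel_mask <- init_id[gsel] == id
        icoords <- init_coords_of(id)
        dists <- vapply(cand, function(cc) {
          if (cc$degenerate) Inf
          else bidirectional_hausdorff(cc$coords, icoords, convention = convention)
        }, numeric(1))
        keys <- vapply(cand, `[[`, character(1), "key")
        ord <- order(dists, keys)
        remaining <- gsel[isel_mask]
        for (ci in ord) {
          if (!length(remaining)) break
          sv <- solved[[ci]]
          if (is.null(sv)) next
          pos <- match(remaining, gsel)
          hit <- sv$inside[pos]
          if (!any(hit)) next
          ss <- remaining[hit]
          fr <- sv$fr[pos[hit], , drop = FALSE]
          cc <- cand[[ci]]
          if (cc$kind == "material") {
            fractions[cbind(rep(ss, each = 3), rep(cc$vidx, length(ss)))] <-
              as.vector(t(fr))
            tri_key[ss] <- cc$key
            done[ss] <- TRUE
            remaining <- setdiff(remaining, ss)
          } else {
            members <- lapply(cc$vidx, function(cj) member_idx[[cj]])
            if (all(lengths(members) >= 1)) {
              midx_mat <- vapply(seq_along(members), function(j) {
                mm <- members[[j]]
                if (length(mm) == 1) rep(mm, length(ss))
                else mm[max.col(-point_dists(pts[ss, , drop = FALSE],
                                             coords[mm, , drop = FALSE]),
                                ties.method = "first")]
              }, integer(length(ss)))
              if (length(ss) == 1) midx_mat <- matrix(midx_mat, nrow = 1)
              key2 <- apply(midx_mat, 1, paste, collapse = " ")
              for (kk in unique(key2)) {
                s2 <- ss[key2 == kk]
                midx <- as.integer(strsplit(kk, " ", fixed = TRUE)[[1]])
                res <- assign_refined(pts, s2, midx, coords, library, fractions,
                                      tri_key, done, tol)
                fractions <- res$fractions; tri_key <- res$tri_key; done <- res$done
              }
              remaining <- setdiff(remaining, ss[done[ss]])
            }
          }
        }
      }
    }
  }

  # --- stage 3: convex-hull clamp for points no triangle contains ---------
  if (any(!done)) {
    sel <- which(!done)
    proj <- project_to_hull(pts[sel, , drop = FALSE], coords)
    for (jj in seq_along(sel)) {
      i <- sel[jj]
      e <- proj$edge[jj, ]
      tt <- proj$t[jj]
      fractions[i, e[1]] <- 1 - tt
      fractions[i, e[2]] <- fractions[i, e[2]] + tt
      tri_key[i] <- paste0("hull:", paste(library$name[e], collapse = "|"))
      out_of_hull[i] <- TRUE
    }
  }

  # numerical hygiene: clamp tolerated negatives, renormalize
  fractions[fractions < 0] <- 0
  fractions <- fractions / rowSums(fractions)
  list(fractions = fractions, tri_key = tri_key, out_of_hull = out_of_hull)
}

# refine-and-assign helper: solve points `sel` against material vertices
# `midx`; assign those inside. Returns updated state.
assign_refined <- function(pts, sel, midx, coords, library, fractions,
                           tri_key, done, tol) {
  if (anyNA(midx) || length(unique(midx)) < 3) {
    return(list(fractions = fractions, tri_key = tri_key, done = done))
  }
  vc <- coords[midx, , drop = FALSE]
  if (triangle_degenerate(vc)) {
    return(list(fractions = fractions, tri_key = tri_key, done = done))
  }
  fr <- solve_barycentric_many(pts[sel, , drop = FALSE], vc)
  inside <- rowMins(fr) >= -tol
  if (any(inside)) {
    ss <- sel[inside]
    fractions[cbind(rep(ss, each = 3), rep(midx, length(ss)))] <-
      as.vector(t(fr[inside, , drop = FALSE]))
    tri_key[ss] <- paste(library$name[midx], collapse = "|")
    done[ss] <- TRUE
  }
  list(fractions = fractions, tri_key = tri_key, done = done)
}

enumerate_candidates <- function(mats, coords, library, agents, clusters) {
  out <- list()
  if (length(mats) >= 3) {
    combs <- combn(mats, 3)
    for (kk in seq_len(ncol(combs))) {
      vidx <- combs[, kk]
      vc <- coords[vidx, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        kind = "material", vidx = vidx, coords = vc,
        degenerate = triangle_degenerate(vc),
        key = paste(library$name[vidx], collapse = "|")
      )
    }
  }
  if (nrow(agents) >= 3) {
    combs <- combn(seq_len(nrow(agents)), 3)
    for (kk in seq_len(ncol(combs))) {
      vidx <- combs[, kk]
      vc <- agents[vidx, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        kind = "agent", vidx = vidx, coords = vc,
        degenerate = triangle_degenerate(vc),
        # "~" sorts after material names: agent triplets lose exact ties
        key = paste0("~agent:", paste(vidx, collapse = "|"))
      )
    }
  }
  out
}

# Euclidean distances between n x 2 and k x 2 point sets -> n x k matrix
point_dists <- function(P, Q) {
  outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2
}

rowMins <- function(x) do.call(pmin, as.data.frame(x))

# Project points outside the convex hull of `coords` onto its boundary.
# Returns per-point nearest edge (indices into coords) and position t in
# [0, 1] along it.
project_to_hull <- function(pts, coords) {
  h <- grDevices::chull(coords[, 1], coords[, 2])
  edges <- cbind(h, c(h[-1], h[1]))
  n <- nrow(pts)
  best_d <- rep(Inf, n)
  best_t <- numeric(n)
  best_e <- matrix(1L, n, 2)
  for (r in seq_len(nrow(edges))) {
    a <- coords[edges[r, 1], ]
    b <- coords[edges[r, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    px <- a[1] + tt * ab[1]
    py <- a[2] + tt * ab[2]
    d <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_t[upd] <- tt[upd]
    best_e[upd, 1] <- edges[r, 1]
    best_e[upd, 2] <- edges[r, 2]
  }
  list(edge = best_e, t = best_t)
}

#' Extract one material's fraction image from a decomposition
#'
#' @param vf a `vf_map` from [decompose_image()].
#' @param material library material name.
#' @return Numeric matrix of that material's per-pixel volume fraction.
#' @export
fraction_map <- function(vf, material) {
  if (!material %in% colnames(vf$fractions)) {
    abort(paste0("unknown material: ", material))
  }
  matrix(vf$fractions[, material], vf$dim[1], vf$dim[2])
}

#' Out-of-hull mask of a decomposition
#'
#' Pixels whose attenuation point lay outside the library's convex hull
#' (e.g. metal artifacts) were clamped to the hull boundary and flagged.
#'
#' @param vf a `vf_map`.
#' @return Logical matrix.
#' @export
out_of_hull_mask <- function(vf) {
  matrix(vf$out_of_hull, vf$dim[1], vf$dim[2])
}

#' @export
print.vf_map <- function(x, ...) {
  cat("<vf_map> ", x$dim[1], "x", x$dim[2], " pixels, ",
      ncol(x$fractions), " materials (",
      paste(colnames(x$fractions), collapse = ", "), "); ",
      sum(x$out_of_hull), " out-of-hull pixel(s)\n", sep = "")
  invisible(x)
}

#' Tidy a volume-fraction map into a long tibble
#'
#' @param x a `vf_map`.
#' @param ... unused.
#' @return Tibble with columns `row`, `col`, `material`, `fraction`,
#'   `triangle`, `out_of_hull`.
#' @method tidy vf_map
#' @export
tidy.vf_map <- function(x, ...) {
  n <- prod(x$dim)
  base <- tibble::tibble(
    row = rep(seq_len(x$dim[1]), times = x$dim[2]),
    col = rep(seq_len(x$dim[2]), each = x$dim[1]),
    triangle = x$triangles[x$triangle_id],
    out_of_hull = x$out_of_hull
  )
  tidyr::pivot_longer(
    dplyr::bind_cols(base, tibble::as_tibble(x$fractions)),
    cols = dplyr::all_of(colnames(x$fractions)),
    names_to = "material", values_to = "fraction"
  )
}

#' @method glance vf_map
#' @export
glance.vf_map <- function(x, ...) {
  tibble::tibble(
    n_pixels = prod(x$dim),
    n_materials = ncol(x$fractions),
    n_triangles = length(x$triangles),
    frac_out_of_hull = mean(x$out_of_hull)
  )
}

#' @method autoplot vf_map
#' @export
autoplot.vf_map <- function(object, materials = colnames(object$fractions), ...) {
  df <- dplyr::filter(tidy(object), .data$material %in% materials)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~material) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "volume\nfraction")
}
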