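#' Directed Hausdorff distance between finite point sets
#'
#' Computes \eqn{h(A, B) = \max_{x \in A \setminus (A \cap B)} \min_{y \in
#' B} \lVert x - y \rVert} with the classical early-break scan: points are
#' visited in randomized order and the inner loop over `B` breaks as soon
#' as a distance falls below the running maximum, which cannot change the
#' result — randomization only affects how much work is skipped. Points of
#' `A` also present in `B` contribute zero and are excluded up front, so
#' `h(A, B) = 0` whenever `A` is a subset of `B`.
#'
#' @param A,B numeric matrices (n x 2) of points; a length-2 vector is
#'   taken as a single point.
#' @param seed integer seed for the scan-order randomization (result is
#'   invariant to it; default 0 keeps the work pattern reproducible).
#' @return A single non-negative distance.
#' @examples
#' directed_hausdorff(rbind(c(0, 0), c(10, 0)), rbind(c(0, 1)))
#' @export
directed_hausdorff <- function(A, B, seed = 0) {
  A <- as_point_matrix(A)
  B <- as_point_matrix(B)
  key <- function(p) paste(p[, 1], p[, 2])
  E <- A[!(key(A) %in% key(B)), , drop = FALSE]
  if (nrow(E) == 0) return(0)
  # local RNG scope so randomized scan order never leaks into user RNG state
  ord_E <- with_preserved_seed(seed, sample.int(nrow(E)))
  ord_B <- with_preserved_seed(seed + 1L, sample.int(nrow(B)))
  d_max <- 0
  for (i in ord_E) {
    x <- E[i, ]
    d_min <- Inf
    broke <- FALSE
    for (j in ord_B) {
      d <- sqrt(sum((x - B[j, ])^2))
      if (d < d_max) {       # this point cannot raise the max: skip it
        broke <- TRUE
        break
      }
      if (d < d_min) d_min <- d
    }
    if (!broke && d_min > d_max) d_max <- d_min
  }
  d_max
}

#' Bi-directional Hausdorff distance
#'
#' Combines the two directed distances \eqn{h(A,B)} and \eqn{h(B,A)}. Two
#' conventions are exposed: `"standard-max"` (the classical Hausdorff
#' metric, maximum of the directed values) and `"paper-min"` (minimum of
#' the two directed values, a laxer similarity score some formulations
#' use). Both are symmetric in `A` and `B`.
#'
#' @inheritParams directed_hausdorff
#' @param convention `"standard-max"` (default) or `"paper-min"`.
#' @return A single non-negative distance.
#' @export
bidirectional_hausdorff <- function(A, B, convention = c("standard-max", "paper-min"),
                                    seed = 0) {
  convention <- match.arg(convention)
  h_ab <- directed_hausdorff(A, B, seed = seed)
  h_ba <- directed_hausdorff(B, A, seed = seed)
  if (convention == "standard-max") max(h_ab, h_ba) else min(h_ab, h_ba)
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 2) abort("a point set must be an n x 2 matrix or a length-2 vector")
    x <- matrix(x, ncol = 2)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2 || nrow(x) == 0) abort("point sets must be non-empty n x 2 matrices")
  x
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
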