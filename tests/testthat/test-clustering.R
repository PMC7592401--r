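test_that("clustering degenerate cases behave as documented", {
  lib1 <- material_library("w", 1, 0.22, 0.19)
  cl1 <- cluster_materials(lib1, radius = 0.05)
  expect_equal(nrow(cl1), 1)
  expect_equal(c(cl1$agent_low, cl1$agent_high), c(0.22, 0.19))

  # two materials farther apart than any admissible merge: singletons
  lib2 <- material_library(c("w", "b"), c(1, 1.9), c(0.22, 0.76), c(0.19, 0.51))
  cl2 <- cluster_materials(lib2, radius = 0.05)
  expect_equal(nrow(cl2), 2)
  expect_equal(lengths(cl2$members), c(1L, 1L))

  expect_error(cluster_materials(lib2, radius = 0), "positive")
  expect_error(cluster_materials(lib2, radius = -1), "positive")
})

test_that("greedy agglomeration matches the brute-force oracle", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),      # blob 1
               c(2, 2), c(2.1, 2),                 # blob 2
               c(5, 0))                            # singleton
  lib <- material_library(letters[1:6], rep(1, 6), pts[, 1], pts[, 2])
  cl <- cluster_materials(lib, radius = 0.25)
  expect_equal(nrow(cl), 3)
  got <- lapply(cl$member_idx, sort)
  expect_equal(partition_key(got), partition_key(oracle_agglomerate(pts, 0.25)))
  # member-to-agent distances obey the radius constraint
  for (i in seq_len(nrow(cl))) {
    mi <- cl$member_idx[[i]]
    d <- sqrt((pts[mi, 1] - cl$agent_low[i])^2 + (pts[mi, 2] - cl$agent_high[i])^2)
    expect_true(all(d <= cl$radius[i]))
    # agent is the member centroid
    expect_equal(cl$agent_low[i], mean(pts[mi, 1]))
    expect_equal(cl$agent_high[i], mean(pts[mi, 2]))
  }
})

test_that("clustering is a partition and is input-order invariant", {
  set.seed(31)
  for (rep in 1:5) {
    pts <- cbind(runif(8), runif(8))
    lib <- material_library(letters[1:8], rep(1, 8), pts[, 1], pts[, 2])
    cl <- cluster_materials(lib, radius = 0.3)
    idx <- sort(unlist(cl$member_idx))
    expect_equal(idx, 1:8)   # disjoint cover of the library

    perm <- sample(8)
    libp <- material_library(letters[1:8][perm], rep(1, 8),
                             pts[perm, 1], pts[perm, 2])
    clp <- cluster_materials(libp, radius = 0.3)
    names_got <- lapply(cl$members, sort)
    names_perm <- lapply(clp$members, sort)
    expect_equal(partition_key(names_got), partition_key(names_perm))
  }
})

test_that("point assignment follows nearest-agent-within-radius with index tie-break", {
  lib <- material_library(c("a", "b"), c(1, 1), c(0, 1), c(0, 0))
  cl <- cluster_materials(lib, radius = 0.3)
  expect_equal(assign_cluster(c(0, 0), cl), 1L)           # exactly at an agent
  expect_identical(assign_cluster(c(0.5, 5), cl), NA_integer_)  # beyond every radius
  expect_equal(assign_cluster(c(0.5, 0), cl), NA_integer_)      # equidistant, too far
  cl2 <- cluster_materials(lib, radius = 0.6)
  expect_equal(assign_cluster(c(0.5, 0), cl2), 1L)        # tie -> lower index
  expect_error(assign_cluster(c(0, 0), cl[0, ]), "non-empty")
})

test_that("sub-group update makes every unassigned point assignable", {
  lib <- material_library(c("a", "b"), c(1, 1), c(0, 1), c(0, 0))
  cl <- cluster_materials(lib, radius = 0.1)
  expect_identical(update_subgroups(lib, cl, NULL), cl)
  expect_identical(update_subgroups(lib, cl, matrix(numeric(0), 0, 2)), cl)

  # one stray point becomes one singleton cluster at that coordinate
  up1 <- update_subgroups(lib, cl, c(5, 5))
  expect_equal(nrow(up1), 3)
  expect_equal(c(up1$agent_low[3], up1$agent_high[3]), c(5, 5))
  expect_equal(assign_cluster(c(5, 5), up1), 3L)

  # two well-separated blobs of stray points -> exactly two new clusters
  set.seed(7)
  blob1 <- cbind(runif(10, 4.98, 5.02), runif(10, 4.98, 5.02))
  blob2 <- cbind(runif(10, 7.98, 8.02), runif(10, 7.98, 8.02))
  stray <- rbind(blob1, blob2)
  up2 <- update_subgroups(lib, cl, stray)
  expect_equal(nrow(up2), 4)
  expect_equal(partition_key(lapply(3:4, function(i) sort(which(
    sqrt((stray[, 1] - up2$agent_low[i])^2 +
           (stray[, 2] - up2$agent_high[i])^2) <= 0.1)))),
    partition_key(list(1:10, 11:20)))
  for (i in seq_len(nrow(stray))) {
    expect_false(is.na(assign_cluster(stray[i, ], up2)))
  }
  # existing memberships unchanged
  expect_equal(up2$members[1:2], cl$members[1:2])
})
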