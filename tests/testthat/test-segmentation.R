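plane_scene <- function(seed = 1) {
  withr::with_seed(seed, {
    plane <- cbind(runif(5000, -20, 20), runif(5000, -20, 20),
                   rnorm(5000, sd = 0.02))
    sph <- cloud_matrix_t(sphere_cloud(1000, r = 2, center = c(0, 0, 3),
                                       seed = seed + 1))
    point_cloud(rbind(plane, sph), label = rep(0:1, c(5000, 1000)))
  })
}

test_that("RANSAC finds the stage plane and only it", {
  sc <- plane_scene()
  pl <- fit_stage_plane(sc, distance_threshold = 0.1)
  is_plane <- sc$label == 0
  # inliers = plane points only, within 1%
  expect_gte(length(intersect(pl$inlier_indices, which(is_plane))),
             0.99 * sum(is_plane))
  expect_lte(length(setdiff(pl$inlier_indices, which(is_plane))),
             0.01 * sum(is_plane))
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-3)

  # exact plane, zero noise: every point is an inlier, normal is +-z
  flat <- point_cloud(cbind(runif(500), runif(500), 0))
  pf <- fit_stage_plane(flat, distance_threshold = 0.1)
  expect_equal(length(pf$inlier_indices), 500)
  expect_equal(abs(pf$normal[3]), 1, tolerance = 1e-6)

  # uniform ball has no dominant plane at a tight threshold
  withr::with_seed(2, {
    ball <- matrix(runif(6000, -5, 5), ncol = 3)
    ball <- ball[rowSums(ball^2) < 25, ]
  })
  expect_error(fit_stage_plane(point_cloud(ball), distance_threshold = 0.01),
               "no dominant plane")
})

test_that("plane fit is deterministic and rigid-invariant", {
  sc <- plane_scene(seed = 3)
  p1 <- fit_stage_plane(sc, seed = 42)
  p2 <- fit_stage_plane(sc, seed = 42)
  expect_identical(p1$inlier_indices, p2$inlier_indices)

  moved <- rigid_move(sc, seed = 5)
  moved$label <- sc$label
  p3 <- fit_stage_plane(moved, seed = 42)
  expect_identical(p1$inlier_indices, p3$inlier_indices)
})

test_that("remove_stage keeps exactly the above-plane points", {
  sc <- plane_scene()
  pl <- fit_stage_plane(sc, distance_threshold = 0.1)
  kept <- remove_stage(sc, pl)
  expect_gte(mean(kept$label == 1), 0.99)
  expect_gte(nrow(kept), 0.99 * 1000)

  flat <- point_cloud(cbind(runif(500), runif(500), rnorm(500, sd = 0.01)))
  pf <- fit_stage_plane(flat, distance_threshold = 0.1)
  expect_equal(nrow(remove_stage(flat, pf)), 0)

  # a cloud with no inliers of a given plane passes through unchanged
  high <- point_cloud(cbind(runif(100), runif(100), runif(100, 5, 6)))
  expect_equal(nrow(remove_stage(high, pf)), 100)
})

test_that("region growing separates well-spaced grains with high purity", {
  two <- dplyr::bind_rows(
    sphere_cloud(2000, r = 1.5, center = c(0, 0, 0), seed = 1),
    sphere_cloud(2000, r = 1.5, center = c(10, 0, 0), seed = 2)
  )
  seg <- segment_grains(two, min_cluster_size = 200)
  expect_equal(attr(seg, "n_segments"), 2)
  truth <- rep(1:2, each = 2000)
  tab <- table(seg$label, truth)
  expect_gte(max(tab[1, ]) / sum(tab[1, ]), 0.95)
  expect_gte(max(tab[2, ]) / sum(tab[2, ]), 0.95)

  one <- sphere_cloud(2000, r = 1.5, seed = 4)
  seg1 <- segment_grains(one, min_cluster_size = 200)
  expect_equal(attr(seg1, "n_segments"), 1)
  expect_gte(mean(!is.na(seg1$label)), 0.95)

  expect_error(segment_grains(one[0, ]), "empty")
  expect_warning(segment_grains(one, min_cluster_size = 10000),
                 "outside")
})

test_that("segment labels partition a subset of the cloud", {
  two <- dplyr::bind_rows(
    sphere_cloud(1500, r = 1.5, center = c(0, 0, 0), seed = 6),
    sphere_cloud(1500, r = 1.5, center = c(8, 0, 0), seed = 7)
  )
  seg <- segment_grains(two, min_cluster_size = 100)
  segs <- split_segments(seg, drop = integer(0))
  expect_equal(sum(vapply(segs, nrow, 0L)), sum(!is.na(seg$label)))
  expect_lte(sum(vapply(segs, nrow, 0L)), nrow(two))
})

test_that("a one-grain scene survives the full segmentation chain", {
  sc <- make_scene(n_grains = 1, layout_spacing = 12, stage_extent = 16,
                   n_points_grain = 1200, seed = 8)
  ds <- voxel_downsample(sc$cloud, 0.1)
  pl <- fit_stage_plane(ds)
  grains <- remove_outliers(remove_stage(ds, pl))
  seg <- segment_grains(grains)
  expect_equal(attr(seg, "n_segments"), 1)
})
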