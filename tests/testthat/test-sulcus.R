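test_that("slicing produces nine centred slabs and rejects short grains", {
  g <- quick_grain(seed = 1)
  aligned <- pca_align(g$cloud)
  profs <- slice_grain(aligned)
  expect_length(profs, 9)
  centers <- vapply(profs, function(p) p$slab_center_x, numeric(1))
  expect_equal(centers, seq(-1.6, 1.6, by = 0.4))
  expect_equal(centers[5], 0)

  short <- make_grain(a = 1.5, b = 1.2, c = 1.0, groove_depth = 0.3,
                      groove_width = 1.0, n_points = 800, seed = 2)
  expect_error(slice_grain(pca_align(short$cloud)), "too short")
})

test_that("the maximal-hull slice is the central cross-section of a grain", {
  g <- quick_grain(seed = 3)
  profs <- slice_grain(pca_align(g$cloud))
  best <- select_max_hull_slice(profs)
  expect_equal(best$slab_center_x, 0)
  expect_identical(select_max_hull_slice(profs[5]), profs[[5]])
  expect_error(select_max_hull_slice(list()), "no profiles")
  degenerate <- slice_profile(rbind(c(0, 0), c(1, 1)))
  expect_error(select_max_hull_slice(list(degenerate)), "no valid")
})

test_that("edge points: lips of the deepest pocket, hull diameter when convex", {
  tri <- slice_profile(rbind(c(-2, 0), c(2, 0), c(0, 1)))
  ep <- sulcus_edge_points(tri)
  expect_equal(unname(ep), rbind(c(-2, 0), c(2, 0)))

  # grooved ring wider than tall: the lip pair is returned
  ring <- slice_profile(ring_profile(depth = 0.5))
  ep2 <- sulcus_edge_points(ring)
  gw <- 1.2
  zL <- -1.4 * sin(acos(gw / 3.2))
  expect_equal(ep2[, 1], c(p1 = -gw / 2, p2 = gw / 2), tolerance = 0.05)
  expect_equal(unname(ep2[, 2]), c(zL, zL), tolerance = 0.05)

  # brute-force diameter oracle for a convex profile (points on an ellipse)
  ang <- withr::with_seed(4, sort(runif(12, 0, 2 * pi)))
  hexa <- cbind(2.3 * cos(ang), 1.1 * sin(ang))
  pr <- slice_profile(hexa)
  ep3 <- sulcus_edge_points(pr)
  d2 <- as.matrix(dist(hexa))
  expect_equal(sqrt(sum((ep3[1, ] - ep3[2, ])^2)), max(d2), tolerance = 1e-9)

  dup <- slice_profile(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_error(sulcus_edge_points(dup), "degenerate")
})

test_that("RANSAC circle fitting is exact on circles and robust to outliers", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(1 + 3 * cos(th), 2 + 3 * sin(th))
  cm <- fit_sulcus_circle(circ)
  expect_equal(cm$center, c(1, 2), tolerance = 1e-6)
  expect_equal(cm$radius, 3, tolerance = 1e-6)

  withr::with_seed(5, {
    out <- cbind(runif(25, -3, 5), runif(25, -2, 6))
    noisy <- rbind(circ, out)
  })
  cm2 <- fit_sulcus_circle(noisy, threshold = 0.05, min_inlier_frac = 0.5)
  expect_equal(cm2$center, c(1, 2), tolerance = 0.02)

  expect_error(fit_sulcus_circle(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("RANSAC circle matches exhaustive 3-subset search on tiny inputs", {
  withr::with_seed(6, {
    pts <- rbind(
      cbind(2 * cos(runif(8, 0, 2 * pi)), 2 * sin(runif(8, 0, 2 * pi))),
      matrix(runif(8, -1, 1), ncol = 2)
    )
  })
  thr <- 0.05
  # brute force: best inlier count over all 3-point circumcircles
  best_cnt <- 0
  combs <- utils::combn(nrow(pts), 3)
  for (j in seq_len(ncol(combs))) {
    cc <- grain3d:::circumcircle(pts[combs[1, j], ], pts[combs[2, j], ],
                                 pts[combs[3, j], ])
    if (is.null(cc)) next
    resid <- abs(sqrt((pts[, 1] - cc$center[1])^2 +
                        (pts[, 2] - cc$center[2])^2) - cc$radius)
    best_cnt <- max(best_cnt, sum(resid <= thr))
  }
  fit <- fit_sulcus_circle(pts, threshold = thr, iterations = 2000,
                           min_inlier_frac = 0.1)
  expect_gte(length(fit$inlier_indices), best_cnt)
})

test_that("sulcus depth: V-profile, convex ring, and planted grooves", {
  # open crescent with lips (+-1, 0) and bottom vertex (0, -0.5)
  th <- seq(-asin(0.8), asin(0.8), length.out = 81)
  crescent <- slice_profile(cbind(1.25 * sin(th), 0.75 - 1.25 * cos(th)))
  expect_equal(sulcus_depth(crescent), 0.5, tolerance = 0.02)

  # grooveless convex ring: depth is sampling noise only
  ring0 <- slice_profile(ring_profile(depth = 0))
  expect_lte(sulcus_depth(ring0), 0.05)

  # planted groove depths recovered within 10% on clean rings
  for (d in c(0.3, 0.55, 0.8)) {
    pr <- slice_profile(ring_profile(depth = d, noise_sd = 0.005, seed = d * 100))
    expect_equal(sulcus_depth(pr), d, tolerance = 0.1)
  }

  line <- slice_profile(rbind(c(0, 0), c(0, 0), c(1, 0), c(0.5, 0)))
  expect_error(sulcus_depth(line), "degenerate|coincide|undefined|invalid")
})

test_that("depth is monotone in the planted groove depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1.0)
  meas <- vapply(depths, function(d) {
    g <- make_grain(c = 1.45, groove_depth = d, n_points = 6000,
                    noise_sd = 0.005, seed = 17)
    prof <- slice_grain(pca_align(g$cloud))
    sulcus_depth(select_max_hull_slice(prof))
  }, numeric(1))
  expect_true(all(diff(meas) > -0.02))
  expect_equal(meas[4], 0.75, tolerance = 0.1)
})

test_that("slice measures match analytic circle, square and groove areas", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- slice_profile(cbind(2 * cos(th), 2 * sin(th)))
  sm <- slice_measures(circ)
  expect_equal(sm$C_c, 4 * pi, tolerance = 0.005)
  expect_equal(sm$S_c, 4 * pi, tolerance = 0.005)
  expect_lt(abs(sm$S_s), 0.01)

  sq <- slice_profile(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  sms <- slice_measures(sq)
  expect_equal(sms$C_c, 4)
  expect_equal(sms$S_c, 1)
  expect_equal(sms$S_s, 0, tolerance = 1e-9)

  # grooved ring: sulcus area = planted wedge area (chord * depth / 2 for a
  # V-groove between the lips) within 15%
  d <- 0.5; gw <- 1.2
  pr <- slice_profile(ring_profile(depth = d, gw = gw, n = 720,
                                   noise_sd = 0.003, seed = 8))
  smg <- slice_measures(pr)
  zL <- -1.4 * sin(acos(gw / 3.2))
  planted <- polygon_area_oracle(rbind(
    c(-gw / 2, zL), c(gw / 2, zL), c(0, zL + d)
  ))
  expect_gt(smg$S_s, 0)
  expect_equal(smg$S_s, planted, tolerance = 0.15)

  flatline <- slice_profile(rbind(c(0, 0), c(1, 1e-12), c(2, 0)))
  expect_error(slice_measures(flatline), "degenerate|invalid")
})

test_that("slice measures and depth are invariant under 2D rigid motion", {
  pr0 <- ring_profile(depth = 0.5, noise_sd = 0.002, seed = 9)
  ang <- 0.83
  R2 <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
  pr1 <- sweep(pr0 %*% R2, 2, c(-3, 7))
  m0 <- slice_measures(slice_profile(pr0))
  m1 <- slice_measures(slice_profile(pr1))
  expect_equal(as.data.frame(m0), as.data.frame(m1), tolerance = 1e-6)
  expect_equal(sulcus_depth(slice_profile(pr0)), sulcus_depth(slice_profile(pr1)),
               tolerance = 1e-6)
})

test_that("sulcus area is non-negative on star-shaped profiles", {
  withr::with_seed(10, {
    for (i in 1:20) {
      th <- sort(runif(150, 0, 2 * pi))
      r <- 2 + 0.4 * sin(3 * th + runif(1, 0, pi)) + rnorm(150, sd = 0.01)
      pr <- slice_profile(cbind(r * cos(th), r * sin(th)))
      expect_gte(slice_measures(pr)$S_s, -1e-6)
    }
  })
})
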