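test_that("mesh construction validates faces", {
  v <- diag(3)
  expect_error(grain_mesh(v, rbind(c(1, 2, 4))), "out of")
  expect_error(grain_mesh(v, rbind(c(1, 2, 2))), "repeats")
  expect_s3_class(grain_mesh(v, rbind(c(1, 2, 3))), "grain_mesh")
})

test_that("surface area: Heron and cross-product forms agree", {
  tri <- grain_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), rbind(1:3))
  expect_equal(surface_area(tri), 6)
  expect_equal(surface_area(cube_mesh()), 6)
  expect_equal(surface_area(grain_mesh(diag(3), matrix(integer(0), ncol = 3))), 0)

  withr::with_seed(1, {
    for (i in 1:200) {
      v <- matrix(rnorm(9, sd = 5), 3, 3)
      m <- grain_mesh(v, rbind(1:3))
      h <- surface_area(m, "heron")
      cr <- surface_area(m, "cross")
      expect_lt(abs(h - cr), 1e-9 * max(cr, 1e-12))
    }
  })
})

test_that("enclosed volume handles cubes, spheres, mirrored and holed meshes", {
  expect_equal(enclosed_volume(cube_mesh()), 1)

  sph <- reconstruct_surface(sphere_cloud(5000, r = 3, seed = 2))
  expect_equal(enclosed_volume(sph), 4 / 3 * pi * 27, tolerance = 0.05)
  expect_equal(surface_area(sph), 4 * pi * 9, tolerance = 0.05)

  # inside-out cube: orientation repair recovers the positive volume
  cm <- cube_mesh()
  mirrored <- grain_mesh(cm$vertices, cm$faces[, c(1, 3, 2)])
  expect_equal(enclosed_volume(mirrored), 1)

  # flipping a single face makes the orientation inconsistent, not the volume
  flipped <- cm
  flipped$faces[1, ] <- flipped$faces[1, c(1, 3, 2)]
  expect_equal(enclosed_volume(flipped), 1)

  # one missing face = a 3..4-edge hole: fan-filled silently
  holed <- grain_mesh(cm$vertices, cm$faces[-1, , drop = FALSE])
  expect_equal(enclosed_volume(holed), 1)
  # but an over-large hole is a named error
  expect_error(enclosed_volume(holed, hole_fill_max_edges = 2),
               "boundary loop of 3 open edges")
})

test_that("reconstructed surfaces are watertight with vertices from the input", {
  g <- quick_grain(seed = 3)
  mesh <- reconstruct_surface(g$cloud)
  # vertices are a subset of input points
  pts <- cloud_matrix_t(g$cloud)
  key_in <- paste(pts[, 1], pts[, 2], pts[, 3])
  key_v <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  expect_true(all(key_v %in% key_in))
  # watertight: every edge shared by exactly two faces
  F <- mesh$faces
  ekey <- paste(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2]))
  ekey <- c(ekey, paste(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3])))
  ekey <- c(ekey, paste(pmin(F[, 3], F[, 1]), pmax(F[, 3], F[, 1])))
  expect_true(all(table(ekey) == 2))

  expect_error(reconstruct_surface(point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))),
               "at least 4")
})

test_that("OBB dimensions recover a rotated box and are rigid-invariant", {
  box <- box_cloud(c(6, 3, 2.8))
  moved <- rigid_move(box, seed = 4)
  d <- obb_dimensions(pca_align(moved))
  expect_equal(d$l, 6, tolerance = 0.02)
  expect_equal(d$w, 3, tolerance = 0.02)
  expect_equal(d$h, 2.8, tolerance = 0.02)

  moved2 <- rigid_move(box, seed = 9, translation = c(-20, 4, 7))
  d2 <- obb_dimensions(pca_align(moved2))
  expect_equal(unlist(d), unlist(d2), tolerance = 1e-6)

  # default synthetic grains sit in the 6-10 mm length class
  g <- quick_grain(seed = 5)
  dims <- obb_dimensions(pca_align(g$cloud))
  expect_gte(dims$l, 6)
  expect_lte(dims$l, 10)
})

test_that("projected outlines recover rectangle area and perimeter", {
  box <- box_cloud(c(6, 3, 2.8), spacing = 0.06)
  # real scans are never on an exact lattice; break Delaunay degeneracy
  box <- withr::with_seed(31, {
    point_cloud(cloud_matrix_t(box) + matrix(rnorm(3 * nrow(box), sd = 0.004),
                                             ncol = 3))
  })
  out <- projected_outline(box, axis = "z")
  expect_equal(out$area, 6 * 3, tolerance = 0.03)
  expect_equal(out$perimeter, 2 * (6 + 3), tolerance = 0.03)

  sq <- withr::with_seed(6, {
    g <- as.matrix(expand.grid(seq(0, 1, by = 0.02), seq(0, 1, by = 0.02)))
    g <- g + matrix(runif(2 * nrow(g), -0.004, 0.004), ncol = 2)
    point_cloud(cbind(pmin(pmax(g, 0), 1), runif(nrow(g))))
  })
  out2 <- projected_outline(sq, axis = "z")
  expect_equal(out2$area, 1, tolerance = 0.03)
  expect_equal(out2$perimeter, 4, tolerance = 0.03)

  expect_error(projected_outline(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0))), "z"),
               "at least 3")
  collin <- point_cloud(cbind(seq(0, 1, 0.1), seq(0, 1, 0.1), 0))
  expect_error(projected_outline(collin, axis = "z"), "collinear")
})

test_that("roundness and sphericity match closed forms and bounds", {
  expect_equal(roundness(list(area = 4 * pi, perimeter = 4 * pi)), 1)
  expect_equal(roundness(list(area = 4, perimeter = 8)), pi / 4)
  expect_error(roundness(list(area = 1, perimeter = 0)), "zero perimeter")

  expect_equal(sphericity(4 / 3 * pi * 27, 4 * pi * 9), 1)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-9)
  expect_equal(sphericity(1, 6), 0.8060, tolerance = 1e-4)
  expect_error(sphericity(0, 6), "> 0")

  # sphericity decreases as a fixed-volume prolate spheroid elongates
  prolate_E <- function(ratio) {
    b <- (1 / ratio)^(1 / 3)   # fixes V = 4/3 pi a b^2 with a = ratio * b
    a <- ratio * b
    e <- sqrt(1 - b^2 / a^2)
    S <- 2 * pi * b^2 * (1 + a / (b * e) * asin(e))
    sphericity(4 / 3 * pi * a * b^2, S)
  }
  Es <- vapply(c(1.2, 1.5, 2, 3, 5), prolate_E, numeric(1))
  expect_true(all(diff(Es) < 0))
  expect_true(all(Es > 0 & Es < 1))
})

test_that("mesh measures and outlines are rigid-motion invariant", {
  g <- quick_grain(seed = 7)
  a1 <- pca_align(g$cloud)
  a2 <- pca_align(rigid_move(g$cloud, seed = 8))
  V1 <- enclosed_volume(reconstruct_surface(a1))
  V2 <- enclosed_volume(reconstruct_surface(a2))
  expect_equal(V1, V2, tolerance = 0.005)
  S1 <- surface_area(reconstruct_surface(a1))
  S2 <- surface_area(reconstruct_surface(a2))
  expect_equal(S1, S2, tolerance = 0.005)
  o1 <- projected_outline(a1, "x")
  o2 <- projected_outline(a2, "x")
  expect_equal(o1$area, o2$area, tolerance = 0.005)
  expect_equal(o1$perimeter, o2$perimeter, tolerance = 0.005)
})
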