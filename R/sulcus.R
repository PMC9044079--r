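#' Cross-section slice profiles
#'
#' A `slice_profile` holds the points of one thin slab of an aligned grain,
#' projected along the grain's length axis onto the (y, z) plane. The
#' constructor computes the 2D convex hull and its area; a profile with
#' fewer than 3 distinct points is flagged invalid.
#'
#' @param points2d Two-column matrix of (y, z) coordinates in mm.
#' @param slab_center_x Slab centre along the grain axis (mm).
#' @return An object of class `slice_profile` with fields `points2d`,
#'   `slab_center_x`, `hull` (hull vertex indices, polygon order),
#'   `hull_area` (mm^2) and `valid`.
#' @export
slice_profile <- function(points2d, slab_center_x = 0) {
  points2d <- unname(as.matrix(points2d))
  stopifnot(ncol(points2d) == 2)
  valid <- nrow(unique(round(points2d, 9))) >= 3
  hull <- integer(0)
  hull_area <- 0
  if (valid) {
    hull <- rev(grDevices::chull(points2d))  # counter-clockwise
    if (length(hull) >= 3) {
      hull_area <- polygon_area(points2d[hull, , drop = FALSE])
    } else {
      valid <- FALSE
    }
  }
  structure(
    list(points2d = points2d, slab_center_x = slab_center_x,
         hull = hull, hull_area = hull_area, valid = valid),
    class = "slice_profile"
  )
}

#' @export
print.slice_profile <- function(x, ...) {
  cat(sprintf(
    "<slice_profile at x = %.2f mm> %d points, hull area %.4f mm^2%s\n",
    x$slab_center_x, nrow(x$points2d), x$hull_area,
    if (x$valid) "" else " (invalid)"
  ))
  invisible(x)
}

polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' Slice a grain along its length
#'
#' Cuts `n_slices` thin slabs perpendicular to the grain's major (x) axis,
#' spaced `interval` mm apart and centred on the grain centre, mirroring the
#' manual sectioning protocol (default: nine slices, 0.4 mm apart, central
#' slice at the grain centre). Each slab's points are projected along x to a
#' (y, z) [slice_profile()].
#'
#' @param cloud An aligned grain cloud ([pca_align()]; x = length axis,
#'   centroid at origin).
#' @param n_slices Number of slices (odd; default 9).
#' @param interval Spacing between slab centres in mm (default 0.4).
#' @param slab_thickness Slab thickness in mm (default 0.4, giving ~100
#'   points per slab at typical scan density).
#' @return A list of `n_slices` `slice_profile` objects, ordered by slab
#'   centre.
#' @export
slice_grain <- function(cloud, n_slices = 9, interval = 0.4,
                        slab_thickness = 0.4) {
  validate_cloud(cloud)
  if (n_slices < 1 || n_slices %% 2 == 0) abort("`n_slices` must be a positive odd count")
  extent <- (n_slices - 1) * interval
  len <- diff(range(cloud$x))
  if (len <= extent) {
    abort(sprintf(
      "grain too short for the slicing extent: length %.2f mm <= %.2f mm",
      len, extent
    ))
  }
  ks <- seq_len(n_slices) - (n_slices + 1) / 2
  centers <- ks * interval
  lapply(centers, function(cx) {
    sel <- abs(cloud$x - cx) <= slab_thickness / 2
    slice_profile(cbind(cloud$y[sel], cloud$z[sel]), slab_center_x = cx)
  })
}

#' Select the maximal cross-section slice
#'
#' Returns the valid profile with the largest convex-hull area; ties go to
#' the slab closest to the grain centre.
#'
#' @param profiles A list of [slice_profile()] objects.
#' @return A single `slice_profile`.
#' @export
select_max_hull_slice <- function(profiles) {
  if (length(profiles) == 0) abort("no profiles given")
  ok <- vapply(profiles, function(p) isTRUE(p$valid), logical(1))
  if (!any(ok)) abort("no valid profiles")
  areas <- vapply(profiles, function(p) p$hull_area, numeric(1))
  areas[!ok] <- -Inf
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    cx <- abs(vapply(profiles[best], function(p) p$slab_center_x, numeric(1)))
    best <- best[which.min(cx)]
  }
  profiles[[best[1]]]
}

# ---- hull pockets ---------------------------------------------------------

# Decompose a star-shaped profile into convexity defects: for each hull edge,
# the boundary points lying angularly between its endpoints form its pocket;
# the pocket depth is the maximal perpendicular distance to the edge line.
hull_pockets <- function(profile) {
  p <- profile$points2d
  hull <- profile$hull
  pole <- colMeans(p[hull, , drop = FALSE])
  ang <- atan2(p[, 2] - pole[2], p[, 1] - pole[1])
  hord <- hull[order(ang[hull])]
  k <- length(hord)
  pockets <- vector("list", k)
  nonhull <- setdiff(seq_len(nrow(p)), hull)
  for (e in seq_len(k)) {
    a <- hord[e]
    b <- hord[if (e == k) 1 else e + 1]
    lo <- ang[a]
    hi <- ang[b]
    if (e == k) {
      inside <- nonhull[ang[nonhull] > lo | ang[nonhull] < hi]
    } else {
      inside <- nonhull[ang[nonhull] > lo & ang[nonhull] < hi]
    }
    depth <- 0
    deepest <- NA_integer_
    if (length(inside)) {
      ab <- p[b, ] - p[a, ]
      len <- sqrt(sum(ab^2))
      if (len > 1e-12) {
        d <- abs((p[inside, 1] - p[a, 1]) * ab[2] -
                   (p[inside, 2] - p[a, 2]) * ab[1]) / len
        depth <- max(d)
        deepest <- inside[which.max(d)]
      }
    }
    pockets[[e]] <- list(a = a, b = b, depth = depth, deepest = deepest,
                         inside = inside)
  }
  pockets
}

deepest_pocket <- function(profile) {
  pockets <- hull_pockets(profile)
  depths <- vapply(pockets, function(q) q$depth, numeric(1))
  pockets[[which.max(depths)]]
}

#' Ventral-sulcus edge points of a slice
#'
#' The two crease lips: the endpoints of the convex-hull edge bridging the
#' deepest concavity of the profile. When the profile has no concavity
#' deeper than `min_pocket_depth` (a convex section), the hull-diameter pair
#' (the two mutually furthest hull vertices, lexicographic tie-break) is
#' returned instead.
#'
#' @param profile A valid [slice_profile()].
#' @param min_pocket_depth Concavity depth (mm) below which the profile is
#'   treated as convex (default 0.05).
#' @return A 2 x 2 matrix; rows are the two edge points (y, z).
#' @export
sulcus_edge_points <- function(profile, min_pocket_depth = 0.05) {
  stopifnot(inherits(profile, "slice_profile"))
  p <- profile$points2d
  hull <- profile$hull
  if (length(unique(hull)) < 2 ||
      nrow(unique(round(p[hull, , drop = FALSE], 9))) < 2) {
    abort("degenerate hull: fewer than 2 distinct vertices")
  }
  pk <- deepest_pocket(profile)
  if (pk$depth >= min_pocket_depth) {
    out <- rbind(p[pk$a, ], p[pk$b, ])
  } else {
    hp <- p[hull, , drop = FALSE]
    d2 <- as.matrix(stats::dist(hp))
    mx <- max(d2)
    cand <- which(d2 >= mx - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic: lexicographically smallest first point, then second
    ordkey <- order(hp[cand[, 1], 1], hp[cand[, 1], 2],
                    hp[cand[, 2], 1], hp[cand[, 2], 2])
    pair <- cand[ordkey[1], ]
    out <- hp[pair, , drop = FALSE]
  }
  if (out[1, 1] > out[2, 1] ||
      (out[1, 1] == out[2, 1] && out[1, 2] > out[2, 2])) {
    out <- out[2:1, , drop = FALSE]
  }
  dimnames(out) <- list(c("p1", "p2"), c("y", "z"))
  out
}

#' RANSAC circle fit to a slice profile
#'
#' Random sample consensus over 3-point circumcircle hypotheses, followed by
#' an algebraic (Kasa) least-squares refit on the consensus set.
#'
#' @param profile A [slice_profile()] (or a 2-column point matrix).
#' @param threshold Inlier distance from the circle, mm (default 0.05).
#' @param iterations RANSAC iterations (default 500).
#' @param seed RNG seed (default 0).
#' @param min_inlier_frac Minimum consensus fraction (default 0.5).
#' @return An object of class `circle_model`: `center` (y, z), `radius`,
#'   `inlier_indices`.
#' @export
fit_sulcus_circle <- function(profile, threshold = 0.05, iterations = 500,
                              seed = 0, min_inlier_frac = 0.5) {
  p <- if (inherits(profile, "slice_profile")) profile$points2d else
    unname(as.matrix(profile))
  n <- nrow(p)
  if (n < 3) abort("need at least 3 points to fit a circle")
  if (collinear2d(p)) abort("collinear points: circle undefined")

  best <- withr::with_seed(seed, {
    best <- list(count = -1L, center = NULL, radius = NULL)
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, 3L)
      cm <- circumcircle(p[idx[1], ], p[idx[2], ], p[idx[3], ])
      if (is.null(cm)) next
      resid <- abs(sqrt((p[, 1] - cm$center[1])^2 + (p[, 2] - cm$center[2])^2) -
                     cm$radius)
      cnt <- sum(resid <= threshold)
      if (cnt > best$count) best <- list(count = cnt, center = cm$center,
                                         radius = cm$radius)
    }
    best
  })
  if (is.null(best$center)) abort("all circle hypotheses degenerate")
  resid <- abs(sqrt((p[, 1] - best$center[1])^2 + (p[, 2] - best$center[2])^2) -
                 best$radius)
  inl <- which(resid <= threshold)
  ls <- kasa_circle(p[inl, , drop = FALSE])
  if (!is.null(ls)) {
    resid <- abs(sqrt((p[, 1] - ls$center[1])^2 + (p[, 2] - ls$center[2])^2) -
                   ls$radius)
    inl2 <- which(resid <= threshold)
    if (length(inl2) >= length(inl)) {
      best <- ls
      inl <- inl2
    }
  }
  if (length(inl) / n < min_inlier_frac) {
    abort(sprintf(
      "no consensus circle: inlier fraction %.2f below minimum %.2f",
      length(inl) / n, min_inlier_frac
    ))
  }
  structure(
    list(center = as.numeric(best$center), radius = best$radius,
         inlier_indices = inl),
    class = "circle_model"
  )
}

#' @export
print.circle_model <- function(x, ...) {
  cat(sprintf("<circle_model> center (%.4f, %.4f), radius %.4f mm, %d inliers\n",
              x$center[1], x$center[2], x$radius, length(x$inlier_indices)))
  invisible(x)
}

collinear2d <- function(p) {
  if (nrow(p) < 3) return(TRUE)
  q <- sweep(p, 2, colMeans(p))
  sv <- svd(q, nu = 0, nv = 0)$d
  sv[2] < 1e-9 * max(sv[1], 1)
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
  uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

kasa_circle <- function(p) {
  if (nrow(p) < 3 || collinear2d(p)) return(NULL)
  A <- cbind(p[, 1], p[, 2], 1)
  b <- -(p[, 1]^2 + p[, 2]^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  ctr <- c(-sol[1] / 2, -sol[2] / 2)
  r2 <- sum(ctr^2) - sol[3]
  if (r2 <= 0) return(NULL)
  list(center = ctr, radius = sqrt(r2))
}

#' Ventral sulcus depth of a slice
#'
#' The perpendicular distance from the sulcus deepest region to the line
#' through the two sulcus edge points ([sulcus_edge_points()]): the mean
#' chord distance of the (up to five) deepest pocket points, which averages
#' scan noise along the fold line the slab contains. The nominal deepest
#' point is the pocket point nearest the centre of the RANSAC-fitted circle
#' ([fit_sulcus_circle()]); when no consensus circle exists the pocket point
#' furthest from the lip chord is used, which coincides for a clean groove.
#' A convex profile (no concavity) has depth ~0. A warning is issued when
#' the lip chord is far from perpendicular to the groove direction.
#'
#' @param profile A valid [slice_profile()].
#' @param circle Optional pre-fitted `circle_model`; by default one is
#'   fitted with `fit_sulcus_circle(profile, ...)` and a failed fit falls
#'   back to the chord-distance rule.
#' @param ... Passed to [fit_sulcus_circle()].
#' @return Depth D in mm (>= 0).
#' @export
sulcus_depth <- function(profile, circle = NULL, min_pocket_depth = 0.05, ...) {
  stopifnot(inherits(profile, "slice_profile"))
  if (!profile$valid) abort("invalid profile: cannot measure depth")
  p <- profile$points2d
  if (is.null(circle)) {
    circle <- tryCatch(fit_sulcus_circle(profile, ...), error = function(e) NULL)
  }
  pk <- deepest_pocket(profile)
  cand <- pk$inside
  if (pk$depth >= min_pocket_depth) {
    a <- p[pk$a, ]
    b <- p[pk$b, ]
  } else {
    # no real concavity: either a convex ring (depth ~ 0) or an open
    # crescent profile, where all points hang off one side of the hull
    # diameter and the depth is measured from that chord
    ep <- sulcus_edge_points(profile, min_pocket_depth = min_pocket_depth)
    a <- ep[1, ]
    b <- ep[2, ]
    ab0 <- b - a
    side <- (p[, 1] - a[1]) * ab0[2] - (p[, 2] - a[2]) * ab0[1]
    tol <- 1e-9 * max(1, max(abs(p)))
    one_sided <- all(side <= tol) || all(side >= -tol)
    if (one_sided) {
      # crescent: the deepest point is the sagitta point of the chord
      ab0 <- b - a
      dd <- abs((p[, 1] - a[1]) * ab0[2] - (p[, 2] - a[2]) * ab0[1]) /
        sqrt(sum(ab0^2))
      deepest <- which.max(dd)
      D <- mean(sort(dd, decreasing = TRUE)[seq_len(min(5L, length(dd)))])
      return(check_chord_angle(p, a, b, deepest, D))
    }
    # closed convex ring: report the (tiny) residual pocket depth
    if (length(cand) == 0 || is.na(pk$deepest)) return(0)
    a <- p[pk$a, ]
    b <- p[pk$b, ]
  }
  if (sqrt(sum((a - b)^2)) < 1e-12) abort("edge points coincide: line undefined")
  deepest <- if (!is.na(pk$deepest) && length(pk$inside)) pk$deepest else cand[1]
  if (!is.null(circle)) {
    dc <- sqrt((p[cand, 1] - circle$center[1])^2 +
                 (p[cand, 2] - circle$center[2])^2)
    deepest <- cand[which.min(dc)]
  }
  ab <- b - a
  len <- sqrt(sum(ab^2))
  dd <- abs((p[cand, 1] - a[1]) * ab[2] - (p[cand, 2] - a[2]) * ab[1]) / len
  # the crease is a ridge along the grain axis, so the slab holds several
  # points of essentially equal true depth: averaging the deepest few
  # suppresses single-point scan noise without eroding the fold
  D <- mean(sort(dd, decreasing = TRUE)[seq_len(min(5L, length(dd)))])
  check_chord_angle(p, a, b, deepest, D)
}

# warn when the lip chord is far from perpendicular to the groove direction
# (an ambiguous section for the edge-point rule), then return the depth
check_chord_angle <- function(p, a, b, deepest, D) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  mid <- (a + b) / 2
  gdir <- p[deepest, ] - mid
  glen <- sqrt(sum(gdir^2))
  if (glen > 1e-9 && len > 1e-9 && D > 0.05) {
    cosang <- abs(sum(gdir * ab)) / (glen * len)
    if (cosang > 0.5) {
      warn("lip chord is not roughly perpendicular to the groove direction")
    }
  }
  D
}

#' Slice perimeter, area and sulcus area
#'
#' Reorders the slab points by polar angle about their centroid (the profile
#' is assumed star-shaped about it; a violation only warns), then measures:
#' `C_c` = perimeter, the summed distances around the closed cycle; `S_c` =
#' slice area, the signed sum of the centroid-fan triangles (shoelace), so
#' concave groove walls subtract correctly; `S_s` = ventral sulcus area, the
#' convex-hull area minus the slice area.
#'
#' @param profile A valid [slice_profile()].
#' @return One-row tibble with `C_c` (mm), `S_c` (mm^2), `S_s` (mm^2) and
#'   `hull_area` (mm^2).
#' @export
slice_measures <- function(profile) {
  stopifnot(inherits(profile, "slice_profile"))
  if (!profile$valid) abort("invalid profile: fewer than 3 distinct points")
  p <- profile$points2d
  ctr <- colMeans(p)
  ang <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])
  ord <- order(ang)
  q <- p[ord, , drop = FALSE]
  n <- nrow(q)
  i2 <- c(2:n, 1)
  seg <- sqrt((q[i2, 1] - q[, 1])^2 + (q[i2, 2] - q[, 2])^2)
  C_c <- sum(seg)
  fan <- (q[, 1] - ctr[1]) * (q[i2, 2] - ctr[2]) -
    (q[i2, 1] - ctr[1]) * (q[, 2] - ctr[2])
  if (any(fan < -1e-9) && any(fan > 1e-9)) {
    warn("profile is not star-shaped about its centroid; slice area is approximate")
  }
  S_c <- abs(sum(fan)) / 2
  if (S_c < 1e-9) abort("degenerate (zero-area) profile")
  tibble(
    C_c = C_c, S_c = S_c,
    S_s = profile$hull_area - S_c,
    hull_area = profile$hull_area
  )
}

#' Plot a slice profile
#'
#' Shows the slab points, convex hull, crease lips and deepest point.
#'
#' @param object A [slice_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot slice_profile
#' @export
autoplot.slice_profile <- function(object, ...) {
  p <- object$points2d
  df <- tibble(y = p[, 1], z = p[, 2])
  hull <- object$hull
  hdf <- tibble(y = p[c(hull, hull[1]), 1], z = p[c(hull, hull[1]), 2])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z)) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::geom_path(data = hdf, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "y (mm)", y = "z (mm)",
      title = sprintf("Slice at x = %.2f mm", object$slab_center_x)
    )
  if (object$valid) {
    ep <- tryCatch(sulcus_edge_points(object), error = function(e) NULL)
    if (!is.null(ep)) {
      gg <- gg + ggplot2::geom_point(
        data = tibble(y = ep[, 1], z = ep[, 2]),
        colour = "red", size = 2
      )
    }
  }
  gg
}
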