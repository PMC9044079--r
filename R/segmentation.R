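#' RANSAC plane fit for the object stage
#'
#' Finds the dominant plane of a scene by random sample consensus: 3-point
#' hypotheses, inlier counting at `distance_threshold`, then a least-squares
#' refit (plane through the inlier centroid, normal = smallest covariance
#' eigenvector) and a final inlier reselection. The normal is oriented so
#' that the majority of off-plane points have positive signed distance (the
#' grain side is "above" the stage).
#'
#' @param cloud A point-cloud tibble with at least 3 points.
#' @param distance_threshold Inlier point-plane distance in mm (default 0.15).
#' @param max_iterations RANSAC iterations (default 1000).
#' @param seed RNG seed making the fit deterministic (default 0).
#' @param min_inlier_frac Minimum inlier fraction for a plane to count as
#'   dominant (default 0.2); below it the fit fails.
#' @return An object of class `plane_model`: unit `normal`, `offset` (signed
#'   distance of the plane from the origin, so the plane is
#'   `normal . p = offset`), and integer `inlier_indices`.
#' @export
fit_stage_plane <- function(cloud, distance_threshold = 0.15,
                            max_iterations = 1000, seed = 0,
                            min_inlier_frac = 0.2) {
  validate_cloud(cloud)
  n <- nrow(cloud)
  if (n < 3) abort("need at least 3 points to fit a plane")
  if (distance_threshold <= 0) abort("`distance_threshold` must be > 0")
  m <- cloud_matrix(cloud)

  best <- withr::with_seed(seed, {
    best <- list(count = -1L, normal = NULL, offset = NULL)
    for (it in seq_len(max_iterations)) {
      idx <- sample.int(n, 3L)
      p1 <- m[idx[1], ]; p2 <- m[idx[2], ]; p3 <- m[idx[3], ]
      nrm <- cross3(p2 - p1, p3 - p1)
      len <- sqrt(sum(nrm^2))
      if (len < 1e-12) next
      nrm <- nrm / len
      off <- sum(nrm * p1)
      cnt <- sum(abs(m %*% nrm - off) <= distance_threshold)
      if (cnt > best$count) best <- list(count = cnt, normal = nrm, offset = off)
    }
    best
  })
  if (is.null(best$normal)) abort("no dominant plane: all RANSAC samples degenerate")

  # least-squares refinement on the consensus set, then reselect inliers
  inl <- which(abs(m %*% best$normal - best$offset) <= distance_threshold)
  sub <- m[inl, , drop = FALSE]
  ctr <- colMeans(sub)
  eg <- eigen(stats::cov(sub), symmetric = TRUE)
  nrm <- eg$vectors[, 3]
  off <- sum(nrm * ctr)
  sdist <- as.numeric(m %*% nrm - off)
  inl <- which(abs(sdist) <= distance_threshold)
  if (length(inl) / n < min_inlier_frac) {
    abort(sprintf(
      "no dominant plane: best inlier fraction %.3f below minimum %.2f",
      length(inl) / n, min_inlier_frac
    ))
  }
  # orient the normal toward the side holding the majority of far points
  far <- sdist[abs(sdist) > distance_threshold]
  if (length(far) > 0 && sum(far > 0) < sum(far < 0)) {
    nrm <- -nrm
    off <- -off
  }
  structure(
    list(normal = as.numeric(nrm), offset = off, inlier_indices = inl,
         distance_threshold = distance_threshold),
    class = "plane_model"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf(
    "<plane_model> normal (%.4f, %.4f, %.4f), offset %.4f mm, %d inliers\n",
    x$normal[1], x$normal[2], x$normal[3], x$offset, length(x$inlier_indices)
  ))
  invisible(x)
}

#' Remove the stage plane from a scene
#'
#' Drops the plane inliers and every point on or below the stage surface
#' (signed distance along the plane normal not exceeding the fit threshold);
#' what remains are the grains.
#'
#' @param cloud The cloud the plane was fitted on.
#' @param plane A `plane_model` from [fit_stage_plane()].
#' @return The cloud restricted to above-stage points (possibly empty).
#' @export
remove_stage <- function(cloud, plane) {
  stopifnot(inherits(plane, "plane_model"))
  validate_cloud(cloud)
  if (nrow(cloud) == 0) return(cloud)
  sdist <- as.numeric(cloud_matrix(cloud) %*% plane$normal - plane$offset)
  cloud[sdist > plane$distance_threshold, , drop = FALSE]
}

#' Per-point normals and surface variation
#'
#' Local PCA over the `k` nearest neighbours of each point: the normal is the
#' smallest-eigenvalue eigenvector and the curvature proxy is the surface
#' variation `lambda_0 / (lambda_0 + lambda_1 + lambda_2)` (0 on a perfect
#' plane, up to 1/3 for isotropic scatter).
#'
#' @param cloud A point-cloud tibble.
#' @param k Neighbourhood size.
#' @return A list with `normals` (n x 3 matrix, unoriented) and `curvature`
#'   (length-n vector).
#' @export
estimate_normals <- function(cloud, k = 30) {
  validate_cloud(cloud)
  m <- cloud_matrix(cloud)
  if (nrow(m) <= k) {
    abort(sprintf("need more than k = %d points to estimate normals", k))
  }
  res <- local_pca3(m, k)
  list(normals = res$normals, curvature = res$curvature, knn = res$knn)
}

#' Region-growing segmentation into single grains
#'
#' Splits a stage-free cloud into grains by growing regions from
#' low-curvature seed points across k-nearest-neighbour links whose normals
#' deviate by less than `angle_threshold`; a visited neighbour continues the
#' front only while its surface variation stays below `curvature_threshold`.
#' Clusters outside `[min_cluster_size, max_cluster_size]` are discarded.
#' Normals are compared by absolute dot product, so their sign convention is
#' irrelevant. Grains in contact are not split further.
#'
#' @param cloud A non-empty point-cloud tibble (stage already removed).
#' @param k_neighbors Neighbour count for normals and connectivity
#'   (default 30).
#' @param angle_threshold Maximum normal deviation between neighbours, in
#'   degrees (default 12).
#' @param curvature_threshold Surface-variation bound for a point to keep
#'   growing the front (default 1, i.e. no curvature gating).
#' @param min_cluster_size,max_cluster_size Cluster size window; clusters
#'   outside it are dropped (defaults 200 and 20000). These are the primary
#'   user knobs when grains are over- or under-split.
#' @return The cloud with an integer `label` column: 1..n_segments, `NA` for
#'   unassigned/discarded points. The number of segments is
#'   `attr(, "n_segments")`. Use [split_segments()] for a per-grain list.
#' @export
segment_grains <- function(cloud, k_neighbors = 30, angle_threshold = 12,
                           curvature_threshold = 1.0,
                           min_cluster_size = 200, max_cluster_size = 20000) {
  validate_cloud(cloud)
  n <- nrow(cloud)
  if (n == 0) abort("cannot segment an empty cloud")
  if (n <= k_neighbors) abort("cloud smaller than the normal-estimation neighbourhood")
  est <- estimate_normals(cloud, k = k_neighbors)
  nrm <- est$normals
  curv <- est$curvature
  adj <- est$knn[, -1, drop = FALSE]
  cos_thr <- cos(angle_threshold * pi / 180)

  label <- rep(NA_integer_, n)
  order_seed <- order(curv)
  next_label <- 0L
  queue <- integer(n)
  for (s in order_seed) {
    if (!is.na(label[s])) next
    next_label <- next_label + 1L
    label[s] <- next_label
    queue[1] <- s
    qlen <- 1L
    while (qlen > 0L) {
      i <- queue[qlen]
      qlen <- qlen - 1L
      nb <- adj[i, ]
      nb <- nb[is.na(label[nb])]
      if (length(nb) == 0) next
      dots <- abs(nrm[nb, , drop = FALSE] %*% nrm[i, ])
      ok <- nb[dots >= cos_thr]
      if (length(ok) == 0) next
      label[ok] <- next_label
      grow <- ok[curv[ok] < curvature_threshold]
      if (length(grow)) {
        queue[qlen + seq_along(grow)] <- grow
        qlen <- qlen + length(grow)
      }
    }
  }

  sizes <- tabulate(label, nbins = next_label)
  keep <- which(sizes >= min_cluster_size & sizes <= max_cluster_size)
  if (length(keep) == 0) {
    warn("all clusters fell outside [min_cluster_size, max_cluster_size]")
  }
  relab <- rep(NA_integer_, next_label)
  relab[keep] <- seq_along(keep)
  out <- cloud
  out$label <- ifelse(is.na(label), NA_integer_, relab[label])
  attr(out, "n_segments") <- length(keep)
  out
}

#' Split a labelled cloud into per-segment clouds
#'
#' @param cloud A cloud with an integer `label` column (e.g. from
#'   [segment_grains()] or [make_scene()]).
#' @param drop Labels to drop (default 0, the stage convention); `NA` labels
#'   are always dropped.
#' @return A named list of point-cloud tibbles, one per remaining label.
#' @export
split_segments <- function(cloud, drop = 0L) {
  if (!"label" %in% names(cloud)) abort("cloud has no `label` column")
  keep <- !is.na(cloud$label) & !(cloud$label %in% drop)
  sub <- cloud[keep, , drop = FALSE]
  split(sub[, c("x", "y", "z")], sub$label)
}
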