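#' Rigid transforms
#'
#' A rigid transform maps raw coordinates `T0` to aligned coordinates
#' `T_A = R (T0 - A)`, where the rows of the rotation `R` are unit vectors
#' (for PCA alignment, the covariance eigenvectors) and `A` is the translation
#' (the centroid). `apply_rigid()` applies it, `invert_rigid()` gives the
#' inverse map as another rigid transform.
#'
#' @param rotation 3x3 orthonormal matrix with `det = +1` (rows = axes).
#' @param translation Numeric length-3 vector (mm), subtracted before rotating.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-8) {
    abort("`rotation` is not orthonormal")
  }
  if (det(rotation) < 0) abort("`rotation` must have det = +1 (no reflection)")
  structure(
    list(rotation = rotation, translation = as.numeric(translation)),
    class = "rigid_transform"
  )
}

#' @rdname rigid_transform
#' @param cloud A point-cloud tibble.
#' @param transform A `rigid_transform`.
#' @export
apply_rigid <- function(cloud, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- sweep(cloud_matrix(cloud), 2, transform$translation) %*% t(transform$rotation)
  out <- cloud
  out$x <- m[, 1]
  out$y <- m[, 2]
  out$z <- m[, 3]
  out
}

#' @rdname rigid_transform
#' @export
invert_rigid <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  # inverse of p -> R (p - A) is q -> R^T q + A, i.e. rotation R^T,
  # translation -R A
  rigid_transform(
    rotation = t(transform$rotation),
    translation = -as.numeric(transform$rotation %*% transform$translation)
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation:", format(x$translation, digits = 6), "\n")
  invisible(x)
}

#' Voxel-grid downsampling
#'
#' Thins a cloud by replacing all points falling in each cubic voxel by their
#' centroid. Voxels are half-open cubes `[i*s, (i+1)*s)` anchored at the
#' global origin, which makes the operation exactly idempotent: a centroid
#' never leaves its voxel, so a second pass at the same size is the identity.
#'
#' @param cloud A point-cloud tibble.
#' @param voxel_size Voxel edge length in mm (> 0); default 0.1 mm, just
#'   under the scanner's nominal 0.16 mm point spacing.
#' @return A point-cloud tibble with at most one point per occupied voxel.
#'   A `label` column, when present, is reduced to the most frequent label in
#'   each voxel.
#' @export
voxel_downsample <- function(cloud, voxel_size = 0.1) {
  validate_cloud(cloud)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (mm)")
  }
  if (nrow(cloud) == 0) return(cloud)
  key <- tibble(
    ix = floor(cloud$x / voxel_size),
    iy = floor(cloud$y / voxel_size),
    iz = floor(cloud$z / voxel_size)
  )
  grp <- dplyr::bind_cols(cloud, key)
  out <- grp |>
    dplyr::group_by(.data$ix, .data$iy, .data$iz) |>
    dplyr::summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      dplyr::across(dplyr::any_of("label"), ~ {
        tt <- table(.x)
        as.integer(names(tt)[which.max(tt)])
      }),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ix, .data$iy, .data$iz) |>
    dplyr::select(-"ix", -"iy", -"iz")
  out
}

#' Statistical outlier removal
#'
#' Drops points whose mean distance to their `k_neighbors` nearest neighbours
#' exceeds the global mean of that statistic by more than `std_ratio`
#' standard deviations.
#'
#' @param cloud A point-cloud tibble with more than `k_neighbors` points.
#' @param k_neighbors Neighbourhood size (default 20).
#' @param std_ratio Cut-off in standard deviations (default 2).
#' @return The filtered cloud (a subset of the input rows).
#' @export
remove_outliers <- function(cloud, k_neighbors = 20, std_ratio = 2.0) {
  validate_cloud(cloud)
  n <- nrow(cloud)
  if (n <= k_neighbors) {
    abort(sprintf(
      "need more than k_neighbors = %d points for neighbourhood statistics (got %d)",
      k_neighbors, n
    ))
  }
  m <- cloud_matrix(cloud)
  nn <- RANN::nn2(m, m, k = k_neighbors + 1L)
  mean_d <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  keep <- mean_d <= mean(mean_d) + std_ratio * sd(mean_d)
  cloud[keep, , drop = FALSE]
}

#' Moving-least-squares surface smoothing
#'
#' Projects every point onto the least-squares plane of its `k` nearest
#' neighbours, suppressing measurement noise normal to the surface (by
#' roughly `1/sqrt(k)`). Used before dimensional measurements, where the
#' extreme-value statistics of raw scanner noise would otherwise inflate
#' min/max extents; it is deliberately *not* applied before crease
#' measurements, since plane projection erodes sharp concave features such
#' as the sulcus fold.
#'
#' @param cloud A point-cloud tibble with more than `k` points.
#' @param k Neighbourhood size (default 8).
#' @return The smoothed cloud (same rows, moved along local normals).
#' @export
smooth_cloud <- function(cloud, k = 8) {
  validate_cloud(cloud)
  m <- cloud_matrix(cloud)
  if (nrow(m) <= k) abort(sprintf("need more than k = %d points to smooth", k))
  res <- local_pca3(m, k)
  m <- m - res$offset * res$normals
  out <- cloud
  out$x <- m[, 1]
  out$y <- m[, 2]
  out$z <- m[, 3]
  out
}

#' PCA alignment of a point cloud
#'
#' Centres the cloud at its centroid and rotates it onto its principal axes:
#' X carries the largest covariance eigenvalue, Z the smallest. The sign of
#' the first two axes is fixed so that each eigenvector's largest-magnitude
#' component is positive, and the third axis is their cross product, so the
#' rotation is deterministic and right-handed. The transform mapping raw to
#' aligned coordinates is stored in the `"transform"` attribute (see
#' [alignment_transform()]).
#'
#' @param cloud A point-cloud tibble with at least 4 non-collinear points.
#' @return The aligned cloud, centroid at the origin; attribute `"transform"`
#'   holds the [rigid_transform()].
#' @examples
#' g <- make_grain(seed = 1)
#' aligned <- pca_align(g$cloud)
#' colMeans(cloud_matrix(aligned))  # ~ (0, 0, 0)
#' @export
pca_align <- function(cloud) {
  validate_cloud(cloud)
  m <- cloud_matrix(cloud)
  if (nrow(m) < 4) abort("need at least 4 points for PCA alignment")
  ctr <- colMeans(m)
  cv <- stats::cov(m)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-12 * max(eg$values[1], 1)) {
    abort("degenerate covariance (rank < 2): points are collinear")
  }
  e1 <- fix_sign(eg$vectors[, 1])
  e2 <- fix_sign(eg$vectors[, 2])
  e3 <- c(
    e1[2] * e2[3] - e1[3] * e2[2],
    e1[3] * e2[1] - e1[1] * e2[3],
    e1[1] * e2[2] - e1[2] * e2[1]
  )
  tf <- rigid_transform(rotation = rbind(e1, e2, e3), translation = ctr)
  out <- apply_rigid(cloud, tf)
  attr(out, "transform") <- tf
  out
}

fix_sign <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

#' @rdname pca_align
#' @param aligned A cloud returned by [pca_align()].
#' @export
alignment_transform <- function(aligned) {
  tf <- attr(aligned, "transform")
  if (is.null(tf)) abort("cloud carries no alignment transform")
  tf
}
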