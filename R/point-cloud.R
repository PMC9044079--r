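#' Point cloud tibbles
#'
#' Throughout grain3d a point cloud is an ordinary tibble with numeric
#' columns `x`, `y`, `z` (coordinates in millimetres) and, optionally, an
#' integer `label` column carrying a per-point segment id (0 is conventionally
#' the stage). `point_cloud()` builds and validates one from a data frame or
#' a numeric matrix with three columns; every pipeline verb accepts any data
#' frame with those columns, so clouds compose naturally with dplyr.
#'
#' @param points A data frame with columns `x`, `y`, `z` (and optionally
#'   `label`), or a numeric matrix with three columns.
#' @param label Optional integer vector of per-point labels, one per point.
#' @return A tibble with columns `x`, `y`, `z` and optionally `label`.
#' @examples
#' point_cloud(matrix(rnorm(30), ncol = 3))
#' @export
point_cloud <- function(points, label = NULL) {
  if (is.matrix(points)) {
    if (ncol(points) != 3) abort("`points` matrix must have 3 columns")
    points <- tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  }
  pts <- as_tibble(points)
  if (!all(c("x", "y", "z") %in% names(pts))) {
    abort("a point cloud needs numeric columns `x`, `y`, `z`")
  }
  if (!is.null(label)) pts$label <- label
  validate_cloud(pts)
  pts[, intersect(c("x", "y", "z", "label"), names(pts))]
}

validate_cloud <- function(cloud) {
  for (col in c("x", "y", "z")) {
    v <- cloud[[col]]
    if (!is.numeric(v)) abort(sprintf("cloud column `%s` must be numeric", col))
    if (anyNA(v) || any(!is.finite(v))) {
      abort(sprintf("cloud column `%s` contains non-finite values", col))
    }
  }
  if ("label" %in% names(cloud) && length(cloud$label) != nrow(cloud)) {
    abort("`label` must have one entry per point")
  }
  invisible(cloud)
}

# n x 3 coordinate matrix view of a cloud
cloud_matrix <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

cloud_from_matrix <- function(m, label = NULL) {
  out <- tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  if (!is.null(label)) out$label <- label
  out
}
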