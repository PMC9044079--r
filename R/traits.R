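#' Assemble the 32-trait record for one grain
#'
#' Combines the 16 basic measures (bounding-box dimensions, mesh volume and
#' surface area, sulcus depth, three projected sections, slice measures and
#' the length/width ratio) into the full 32-trait record: 16 derived ratios
#' and shape indices are computed from the basic ones. `V_obb = l*w*h`;
#' roundness indices use each section's area/perimeter; sphericity uses
#' `V` and `S`.
#'
#' @param l,w,h Grain length, width, thickness (mm).
#' @param V Mesh volume (mm^3).
#' @param S Mesh surface area (mm^2).
#' @param D Ventral sulcus depth (mm).
#' @param outlines Named list of three [projected_outline()] results with
#'   names `yz`, `xz`, `xy` (projections along x, y, z respectively).
#' @param C_c,S_c,S_s Slice perimeter, slice area, sulcus area (from
#'   [slice_measures()]).
#' @param id Optional grain id, kept as first column.
#' @return A one-row tibble with `id` (if given) and the 32 columns of
#'   [trait_names()].
#' @export
assemble_traits <- function(l, w, h, V, S, D, outlines, C_c, S_c, S_s,
                            id = NULL) {
  need <- c("yz", "xz", "xy")
  if (!all(need %in% names(outlines))) {
    abort("`outlines` must be a named list with elements yz, xz, xy")
  }
  basics <- c(
    l = l, w = w, h = h, V = V, S = S, D = D,
    C_yz = outlines$yz$perimeter, S_yz = outlines$yz$area,
    C_xz = outlines$xz$perimeter, S_xz = outlines$xz$area,
    C_xy = outlines$xy$perimeter, S_xy = outlines$xy$area,
    C_c = C_c, S_c = S_c, S_s = S_s
  )
  if (any(!is.finite(basics))) abort("non-finite basic trait value")
  for (nm in c("w", "h", "l", "V", "S_c")) {
    if (basics[[nm]] == 0) {
      abort(sprintf("division by zero: basic trait `%s` is 0", nm))
    }
  }
  rec <- tibble(
    l = l, w = w, h = h, V = V, S = S, D = D,
    C_yz = basics[["C_yz"]], S_yz = basics[["S_yz"]],
    C_xz = basics[["C_xz"]], S_xz = basics[["S_xz"]],
    C_xy = basics[["C_xy"]], S_xy = basics[["S_xy"]],
    C_c = C_c, S_c = S_c, S_s = S_s,
    `l/w` = l / w,
    `l/h` = l / h, `w/h` = w / h, `D/h` = D / h,
    V_obb = l * w * h,
    `S/V` = S / V, `S/l` = S / l, `S/w` = S / w, `S/h` = S / h,
    `V/l` = V / l, `V/w` = V / w, `V/h` = V / h,
    `S_s/S_c` = S_s / S_c,
    c_yz = roundness(outlines$yz),
    c_xz = roundness(outlines$xz),
    c_xy = roundness(outlines$xy),
    E = sphericity(V, S)
  )
  rec <- rec[, trait_names()]
  if (!is.null(id)) rec <- dplyr::bind_cols(tibble(id = id), rec)
  rec
}

#' Full trait extraction for a single grain cloud
#'
#' Runs the per-grain measurement chain: PCA alignment, bounding-box
#' dimensions, surface reconstruction (area + volume), the three projected
#' outlines, slicing with maximal-section selection, sulcus depth and slice
#' measures, then assembles the 32-trait record.
#'
#' @param cloud A single grain's point-cloud tibble (any frame; the grain is
#'   aligned internally).
#' @param id Optional grain id.
#' @param voxel_size Voxel edge for the leading downsampling/denoising pass
#'   in mm ([voxel_downsample()]); `NULL` skips it (e.g. when the cloud was
#'   already downsampled by the scene pipeline). Default 0.1.
#' @param smooth_k Neighbourhood size of the [smooth_cloud()] pass applied
#'   before the dimensional measurements (bounding box, mesh, outlines);
#'   `NULL` disables smoothing. Slicing always uses the unsmoothed points.
#' @param n_slices,interval,slab_thickness Passed to [slice_grain()].
#' @param circle_args List of arguments for [fit_sulcus_circle()] inside
#'   [sulcus_depth()].
#' @return A one-row trait tibble (see [assemble_traits()]).
#' @examples
#' g <- make_grain(n_points = 1500, seed = 2)
#' grain_traits(g$cloud, id = 1)
#' @export
grain_traits <- function(cloud, id = NULL, voxel_size = 0.1, smooth_k = 8,
                         n_slices = 9, interval = 0.4, slab_thickness = 0.4,
                         circle_args = list()) {
  if (!is.null(voxel_size)) cloud <- voxel_downsample(cloud, voxel_size)
  smoothed <- if (!is.null(smooth_k)) smooth_cloud(cloud, k = smooth_k) else cloud
  aligned <- pca_align(smoothed)
  dims <- obb_dimensions(aligned)
  mesh <- reconstruct_surface(aligned)
  S <- surface_area(mesh)
  V <- enclosed_volume(mesh)
  outlines <- list(
    yz = projected_outline(aligned, axis = "x"),
    xz = projected_outline(aligned, axis = "y"),
    xy = projected_outline(aligned, axis = "z")
  )
  # slices keep the unsmoothed points: plane-projection smoothing erodes the
  # sharp crease fold the depth measurement depends on
  raw_aligned <- apply_rigid(cloud, alignment_transform(aligned))
  profiles <- slice_grain(raw_aligned, n_slices = n_slices, interval = interval,
                          slab_thickness = slab_thickness)
  best <- select_max_hull_slice(profiles)
  D <- do.call(sulcus_depth, c(list(best), circle_args))
  sm <- slice_measures(best)
  assemble_traits(
    l = dims$l, w = dims$w, h = dims$h, V = V, S = S, D = D,
    outlines = outlines, C_c = sm$C_c, S_c = sm$S_c, S_s = sm$S_s, id = id
  )
}

#' Agreement metrics between reference and system measurements
#'
#' Mean absolute percentage error, root mean square error and the
#' coefficient of determination between reference values `x` (e.g. manual
#' measurements, or true weights) and system values `y` (e.g. pipeline
#' measurements, or model predictions):
#' `MAPE = 100/n * sum(|x - y| / x)` (percent),
#' `RMSE = sqrt(mean((x - y)^2))`,
#' `R2 = 1 - sum((x - y)^2) / sum((x - ybar)^2)`.
#' By convention here `ybar` is the mean of the *system* values; set
#' `r2_baseline = "reference"` for the textbook definition using the mean of
#' `x`.
#'
#' @param x Reference measurements (strictly nonzero for MAPE).
#' @param y System measurements, same length.
#' @param r2_baseline `"system"` (default) or `"reference"`.
#' @return One-row tibble with `mape` (percent), `rmse`, `r2`.
#' @examples
#' metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
metrics <- function(x, y, r2_baseline = c("system", "reference")) {
  r2_baseline <- match.arg(r2_baseline)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 2) abort("need at least 2 paired measurements")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite measurements")
  if (any(x == 0)) abort("MAPE undefined: some reference value x is 0")
  mape <- 100 * mean(abs(x - y) / abs(x))
  rmse <- sqrt(mean((x - y)^2))
  base <- if (r2_baseline == "system") mean(y) else mean(x)
  denom <- sum((x - base)^2)
  r2 <- if (denom > 0) 1 - sum((x - y)^2) / denom else NA_real_
  tibble(mape = mape, rmse = rmse, r2 = r2)
}

#' Pearson correlation matrix of a trait table
#'
#' Correlates the 32 traits (plus `weight` when present) across grains.
#' Zero-variance columns are flagged with a warning and produce `NA`
#' entries.
#'
#' @param traits A trait tibble with >= 3 rows and no missing values.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(traits) {
  validate_trait_table(traits)
  cols <- intersect(c(trait_names(), "weight"), names(traits))
  m <- as.matrix(traits[, cols])
  if (nrow(m) < 3) abort("need at least 3 grains for a correlation matrix")
  sds <- apply(m, 2, sd)
  flat <- sds == 0
  if (any(flat)) {
    warn(sprintf(
      "zero-variance column(s): %s; their correlations are NA",
      paste(cols[flat], collapse = ", ")
    ))
  }
  out <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(out) <- 1
  out
}

#' Taguchi L9 range analysis
#'
#' For each factor of a balanced L9 (3-level) design, `K[f, i]` is the mean
#' response over the three tests run at level `i` of factor `f`, and the
#' range `R[f] = max(K[f, ]) - min(K[f, ])` ranks factor influence. When the
#' response is an error measure, the best level per factor is the one with
#' the smallest `K`.
#'
#' @param design A design tibble from [read_design_table()] /
#'   [as_design_table()] (9 rows, integer-coded 3-level factors, numeric
#'   `response`), or anything coercible by [as_design_table()].
#' @param response Response column name when coercion is needed.
#' @return An object of class `doe_analysis`: `K` (factor x level matrix),
#'   `R` (named vector), `best_levels` (named integer vector, argmin K) and
#'   `best_labels` (when level labels are known).
#' @export
orthogonal_analysis <- function(design, response = NULL) {
  if (is.null(design$response) || is.null(attr(design, "levels"))) {
    design <- as_design_table(design, response = response)
  }
  lev <- attr(design, "levels")
  factors <- setdiff(names(design), "response")
  K <- matrix(NA_real_, nrow = length(factors), ncol = 3,
              dimnames = list(factors, paste0("K", 1:3)))
  for (f in factors) {
    tab <- tabulate(design[[f]], nbins = 3)
    if (!all(tab == 3)) {
      abort(sprintf("unbalanced design: factor '%s' levels occur %s times",
                    f, paste(tab, collapse = "/")))
    }
    for (i in 1:3) K[f, i] <- mean(design$response[design[[f]] == i])
  }
  R <- apply(K, 1, max) - apply(K, 1, min)
  best <- apply(K, 1, which.min)
  best_labels <- vapply(factors, function(f) lev[[f]][best[[f]]], "")
  structure(
    list(K = K, R = R, best_levels = best, best_labels = best_labels),
    class = "doe_analysis"
  )
}

#' @export
print.doe_analysis <- function(x, digits = 4, ...) {
  cat("L9 range analysis (K = per-level mean response)\n")
  print(round(x$K, digits))
  cat("R (range):", paste(sprintf("%s = %.*f", names(x$R), digits, x$R),
                          collapse = ", "), "\n")
  cat("best levels:",
      paste(sprintf("%s = %s", names(x$best_labels), x$best_labels),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy doe_analysis
#' @export
tidy.doe_analysis <- function(x, ...) {
  K <- x$K
  tibble(
    factor = rep(rownames(K), each = ncol(K)),
    level = rep(seq_len(ncol(K)), times = nrow(K)),
    K = as.vector(t(K))
  ) |>
    dplyr::left_join(
      tibble(factor = names(x$R), R = unname(x$R),
             best_level = unname(x$best_levels)),
      by = "factor"
    )
}
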