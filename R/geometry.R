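#' Triangle meshes
#'
#' A `grain_mesh` holds an `n x 3` vertex coordinate matrix (mm) and an
#' `m x 3` integer face matrix indexing it. Faces must not repeat a vertex
#' and all indices must be in range.
#'
#' @param vertices Numeric matrix `n x 3`.
#' @param faces Integer matrix `m x 3` of 1-based vertex indices.
#' @return An object of class `grain_mesh`.
#' @export
grain_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(matrix(as.integer(as.matrix(faces)), ncol = 3))
  if (ncol(vertices) != 3) abort("`vertices` must have 3 columns")
  if (nrow(faces) > 0) {
    if (max(faces) > nrow(vertices) || min(faces) < 1) {
      abort("face indices out of vertex range")
    }
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3])) {
      abort("a face repeats a vertex")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "grain_mesh")
}

#' @export
print.grain_mesh <- function(x, ...) {
  cat(sprintf("<grain_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Surface reconstruction of a single grain
#'
#' Builds a closed triangle mesh over a grain's surface sample by radial
#' Delaunay triangulation: points are projected to unit directions about the
#' cloud centroid, triangulated on the sphere (stereographic projection from
#' one of the data points + planar Delaunay + cap closure, which equals the
#' convex hull of the directions), and the connectivity is carried back to
#' the original coordinates. For the star-shaped closed surfaces produced by
#' merged grain scans this yields a watertight mesh whose vertices are a
#' subset of the input points. Points sharing a direction to within
#' `dedup_tol` keep only their first representative.
#'
#' @param cloud A point-cloud tibble with at least 4 points spanning 3D.
#' @param dedup_tol Angular deduplication tolerance on unit directions
#'   (default 1e-7).
#' @return A watertight `grain_mesh`, faces oriented outward.
#' @examples
#' g <- make_grain(n_points = 1500, seed = 7)
#' m <- reconstruct_surface(g$cloud)
#' surface_area(m)
#' enclosed_volume(m)
#' @export
reconstruct_surface <- function(cloud, dedup_tol = 1e-7) {
  validate_cloud(cloud)
  m <- cloud_matrix(cloud)
  if (nrow(m) < 4) {
    abort(sprintf("need at least 4 points to reconstruct a surface (got %d)", nrow(m)))
  }
  ctr <- colMeans(m)
  q <- sweep(m, 2, ctr)
  r <- sqrt(rowSums(q^2))
  if (any(r < 1e-12)) {
    keep0 <- r >= 1e-12
    m <- m[keep0, , drop = FALSE]
    q <- q[keep0, , drop = FALSE]
    r <- r[keep0]
  }
  d <- q / r
  keep <- !duplicated(round(d / dedup_tol) * dedup_tol)
  idx_kept <- which(keep)
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 4) abort("fewer than 4 distinct directions; cannot mesh")

  # pole = direction with the most isolated neighbourhood, so stereographic
  # coordinates stay bounded
  ncand <- min(64L, n)
  cand <- unique(round(seq(1L, n, length.out = ncand)))
  nnc <- RANN::nn2(d, d[cand, , drop = FALSE], k = 2L)$nn.dists[, 2]
  pole_i <- cand[which.max(nnc)]
  pole <- d[pole_i, ]

  R <- rotation_to_z(pole)
  dr <- d %*% t(R)
  rest <- setdiff(seq_len(n), pole_i)
  denom <- 1 - dr[rest, 3]
  denom[denom < 1e-12] <- 1e-12
  u <- dr[rest, 1] / denom
  w <- dr[rest, 2] / denom

  tm <- tryCatch(
    interp::tri.mesh(u, w, duplicate = "remove"),
    error = function(e) abort(paste0("triangulation failed: ", conditionMessage(e)))
  )
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  faces <- cbind(rest[tri[, 1]], rest[tri[, 2]], rest[tri[, 3]])
  ch <- interp::convex.hull(tm)
  hidx <- rest[ch$i]
  k <- length(hidx)
  if (k < 3) abort("no triangles produced")
  cap <- cbind(rep(pole_i, k), hidx, hidx[c(2:k, 1)])
  faces <- rbind(faces, cap)
  faces <- matrix(idx_kept[faces], ncol = 3)

  # orient every face outward (positive tetra volume from the centroid)
  v <- m
  a <- v[faces[, 1], , drop = FALSE]
  b <- v[faces[, 2], , drop = FALSE]
  cc <- v[faces[, 3], , drop = FALSE]
  dets <- tet_dets(a, b, cc, ctr)
  flip <- dets < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]

  grain_mesh(v, faces)
}

rotation_to_z <- function(v) {
  z <- c(0, 0, 1)
  axis <- cross3(v, z)
  s <- sqrt(sum(axis^2))
  cth <- sum(v * z)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  axis <- axis / s
  th <- atan2(s, cth)
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

tet_dets <- function(a, b, cc, origin) {
  a <- sweep(a, 2, origin); b <- sweep(b, 2, origin); cc <- sweep(cc, 2, origin)
  a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
}

#' Mesh surface area
#'
#' Sums per-triangle areas. The default uses Heron's formula on the three
#' side lengths (semi-perimeter form); `method = "cross"` uses the
#' cross-product half-norm instead. The two agree to rounding; degenerate
#' triangles whose Heron radicand goes negative from rounding clamp to 0.
#'
#' @param mesh A `grain_mesh`.
#' @param method `"heron"` (default) or `"cross"`.
#' @return Total area in mm^2 (0 for an empty mesh).
#' @export
surface_area <- function(mesh, method = c("heron", "cross")) {
  stopifnot(inherits(mesh, "grain_mesh"))
  method <- match.arg(method)
  F <- mesh$faces
  if (nrow(F) == 0) return(0)
  V <- mesh$vertices
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  if (method == "cross") {
    cr <- cbind(
      e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
      e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
      e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    )
    return(sum(sqrt(rowSums(cr^2))) / 2)
  }
  e3 <- V[F[, 3], , drop = FALSE] - V[F[, 2], , drop = FALSE]
  a <- sqrt(rowSums(e1^2))
  b <- sqrt(rowSums(e2^2))
  cc <- sqrt(rowSums(e3^2))
  p <- (a + b + cc) / 2
  rad <- p * (p - a) * (p - b) * (p - cc)
  sum(sqrt(pmax(rad, 0)))
}

#' Enclosed volume of a closed mesh
#'
#' Checks the mesh is watertight (every edge shared by exactly two faces),
#' fan-filling boundary loops of at most `hole_fill_max_edges` edges first;
#' larger holes are an error naming the open-edge count. Faces are then
#' oriented consistently (propagation across shared edges, global sign fixed
#' so the volume is positive) and the volume is the signed-tetrahedron sum
#' about the centroid -- algebraically identical to summing the prisms of each
#' face over a central plane for a closed oriented mesh.
#'
#' @param mesh A `grain_mesh`.
#' @param hole_fill_max_edges Largest boundary loop that is fan-filled
#'   (default 30 edges).
#' @return Volume in mm^3 (> 0).
#' @export
enclosed_volume <- function(mesh, hole_fill_max_edges = 30) {
  stopifnot(inherits(mesh, "grain_mesh"))
  F <- mesh$faces
  if (nrow(F) == 0) abort("cannot take the volume of an empty mesh")
  V <- mesh$vertices

  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  ekey <- edge_key(edges[, 1], edges[, 2], nrow(V))
  cnt <- table(ekey)
  if (any(cnt > 2)) abort("non-manifold mesh: an edge is shared by more than 2 faces")
  open_keys <- names(cnt)[cnt == 1]
  if (length(open_keys) > 0) {
    F <- rbind(F, fill_holes(edges, ekey, open_keys, hole_fill_max_edges))
    edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    ekey <- edge_key(edges[, 1], edges[, 2], nrow(V))
  }

  # a consistently oriented closed mesh uses every directed edge exactly once
  dkey <- c(F[, 1], F[, 2], F[, 3]) * (nrow(V) + 1) +
    c(F[, 2], F[, 3], F[, 1])
  if (anyDuplicated(dkey)) F <- orient_faces(F, nrow(V))
  ctr <- colMeans(V)
  dets <- tet_dets(
    V[F[, 1], , drop = FALSE], V[F[, 2], , drop = FALSE],
    V[F[, 3], , drop = FALSE], ctr
  )
  abs(sum(dets)) / 6
}

edge_key <- function(i, j, nv) {
  pmin(i, j) * (nv + 1) + pmax(i, j)
}

fill_holes <- function(edges, ekey, open_keys, max_edges) {
  open <- edges[ekey %in% open_keys, , drop = FALSE]
  nxt <- split(open[, 2], open[, 1])
  used <- rep(FALSE, nrow(open))
  start_of <- open[, 1]
  new_faces <- NULL
  remaining <- nrow(open)
  # walk directed boundary edges into loops
  while (remaining > 0) {
    s <- which(!used)[1]
    loop <- open[s, 1]
    cur <- open[s, 2]
    used[s] <- TRUE
    remaining <- remaining - 1
    guard <- 0
    while (cur != loop[1]) {
      loop <- c(loop, cur)
      cand <- which(!used & start_of == cur)
      if (length(cand) == 0) abort("open boundary is not a closed loop; cannot fill")
      used[cand[1]] <- TRUE
      remaining <- remaining - 1
      cur <- open[cand[1], 2]
      guard <- guard + 1
      if (guard > nrow(open)) abort("boundary loop walk failed")
    }
    if (length(loop) > max_edges) {
      abort(sprintf(
        "mesh has a boundary loop of %d open edges (max fillable %d)",
        length(loop), max_edges
      ))
    }
    if (length(loop) >= 3) {
      fan <- cbind(loop[1], loop[2:(length(loop) - 1)], loop[3:length(loop)])
      new_faces <- rbind(new_faces, fan)
    }
  }
  new_faces
}

orient_faces <- function(F, nv) {
  m <- nrow(F)
  ek <- cbind(
    edge_key(F[, 1], F[, 2], nv),
    edge_key(F[, 2], F[, 3], nv),
    edge_key(F[, 3], F[, 1], nv)
  )
  # map edge key -> the (up to 2) incident faces
  keys <- as.vector(ek)
  face_of <- rep(seq_len(m), 3)
  ord <- order(keys)
  keys <- keys[ord]
  face_of <- face_of[ord]
  first <- !duplicated(keys)
  grp <- cumsum(first)
  pair1 <- face_of[first]
  second <- duplicated(keys)
  pair2 <- rep(NA_integer_, max(grp))
  pair2[grp[second]] <- face_of[second]
  key_id <- stats::setNames(seq_along(pair1), keys[first])

  seen <- rep(FALSE, m)
  for (root in seq_len(m)) {
    if (seen[root]) next
    seen[root] <- TRUE
    stack <- root
    while (length(stack)) {
      f <- stack[length(stack)]
      stack <- stack[-length(stack)]
      fe <- rbind(F[f, c(1, 2)], F[f, c(2, 3)], F[f, c(3, 1)])
      for (e in 1:3) {
        kid <- key_id[[as.character(edge_key(fe[e, 1], fe[e, 2], nv))]]
        g <- if (!is.na(pair2[kid]) && pair2[kid] != f) pair2[kid]
             else if (pair1[kid] != f) pair1[kid] else NA_integer_
        if (is.na(g) || seen[g]) next
        # consistent orientation: the shared edge must run in opposite
        # directions in the two faces
        ge <- rbind(F[g, c(1, 2)], F[g, c(2, 3)], F[g, c(3, 1)])
        same_dir <- any(ge[, 1] == fe[e, 1] & ge[, 2] == fe[e, 2])
        if (same_dir) F[g, c(2, 3)] <- F[g, c(3, 2)]
        seen[g] <- TRUE
        stack <- c(stack, g)
      }
    }
  }
  F
}

#' Oriented-bounding-box dimensions of an aligned grain
#'
#' On a PCA-aligned grain the oriented bounding box is the axis-aligned box,
#' so length/width/thickness are the coordinate ranges:
#' `l = x_max - x_min`, `w = y_max - y_min`, `h = z_max - z_min`.
#'
#' @param cloud An aligned point-cloud tibble (see [pca_align()]).
#' @return One-row tibble with columns `l`, `w`, `h` (mm).
#' @export
obb_dimensions <- function(cloud) {
  validate_cloud(cloud)
  if (nrow(cloud) < 4) abort("need at least 4 points for bounding-box dimensions")
  tibble(
    l = diff(range(cloud$x)),
    w = diff(range(cloud$y)),
    h = diff(range(cloud$z))
  )
}

#' Projected outline of a grain
#'
#' Projects the grain along one coordinate axis, triangulates the planar
#' points (Delaunay, then discarding triangles with any side longer than
#' `max_edge`, so concavities such as the crease mouth are respected), and
#' measures the area as the sum of kept-triangle areas and the perimeter as
#' the sum of boundary edges (edges used by exactly one kept triangle).
#'
#' @param cloud An aligned point-cloud tibble.
#' @param axis Projection direction: `"x"` gives the (y,z) cross-section,
#'   `"y"` the (x,z) longitudinal section, `"z"` the (x,y) horizontal
#'   section.
#' @param max_edge Edge-length cut in mm; default `mu` times the 90th
#'   percentile of the Delaunay triangles' longest sides (an alpha-shape
#'   style criterion that is robust to the layer stacking projections
#'   create).
#' @param mu Multiplier for the automatic cut (default 2.5).
#' @return An object of class `grain_outline`: fields `area` (mm^2),
#'   `perimeter` (mm), `axis`.
#' @export
projected_outline <- function(cloud, axis = c("x", "y", "z"),
                              max_edge = NULL, mu = 2.5) {
  validate_cloud(cloud)
  axis <- match.arg(axis)
  keepcols <- setdiff(c("x", "y", "z"), axis)
  u <- cloud[[keepcols[1]]]
  v <- cloud[[keepcols[2]]]
  dup <- duplicated(round(cbind(u, v), 9))
  u <- u[dup == FALSE]
  v <- v[dup == FALSE]
  if (length(u) < 3) abort("need at least 3 distinct projected points")
  if (max(abs(u - mean(u))) < 1e-12 || max(abs(v - mean(v))) < 1e-12) {
    abort("collinear projection: outline undefined")
  }
  tm <- tryCatch(
    interp::tri.mesh(u, v, duplicate = "remove"),
    error = function(e) abort(paste0("collinear projection: ", conditionMessage(e)))
  )
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  p1 <- cbind(u[tri[, 1]], v[tri[, 1]])
  p2 <- cbind(u[tri[, 2]], v[tri[, 2]])
  p3 <- cbind(u[tri[, 3]], v[tri[, 3]])
  l12 <- sqrt(rowSums((p2 - p1)^2))
  l23 <- sqrt(rowSums((p3 - p2)^2))
  l31 <- sqrt(rowSums((p1 - p3)^2))
  lmax <- pmax(l12, l23, l31)
  if (is.null(max_edge)) {
    # alpha-shape style cut: a quantile of the Delaunay edge scale itself,
    # which stays meaningful when projection stacks surface layers and
    # nearest-neighbour spacings collapse
    max_edge <- mu * stats::quantile(lmax, 0.90, names = FALSE)
  }
  keep <- lmax <= max_edge
  if (!any(keep)) abort("no triangles survive the edge-length cut")
  tri <- tri[keep, , drop = FALSE]
  area <- sum(abs(
    (p2[keep, 1] - p1[keep, 1]) * (p3[keep, 2] - p1[keep, 2]) -
      (p3[keep, 1] - p1[keep, 1]) * (p2[keep, 2] - p1[keep, 2])
  )) / 2
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  k <- pmin(ed[, 1], ed[, 2]) * (length(u) + 1) + pmax(ed[, 1], ed[, 2])
  tabk <- table(k)
  bkeys <- as.numeric(names(tabk)[tabk == 1])
  bi <- floor(bkeys / (length(u) + 1))
  bj <- bkeys - bi * (length(u) + 1)
  perimeter <- sum(sqrt((u[bi] - u[bj])^2 + (v[bi] - v[bj])^2))
  structure(
    list(area = area, perimeter = perimeter, axis = axis, n_points = length(u)),
    class = "grain_outline"
  )
}

#' @export
print.grain_outline <- function(x, ...) {
  cat(sprintf("<grain_outline along %s> area %.4f mm^2, perimeter %.4f mm\n",
              x$axis, x$area, x$perimeter))
  invisible(x)
}

#' Roundness of a 2D outline
#'
#' The isoperimetric shape index `c = 4 pi S0 / C^2`: 1 for a circle,
#' `pi/4` for a square, smaller for elongated outlines.
#'
#' @param outline A `grain_outline`, or any list with fields `area` and
#'   `perimeter`.
#' @return Unitless roundness in (0, 1] up to measurement tolerance.
#' @export
roundness <- function(outline) {
  if (is.null(outline$area) || is.null(outline$perimeter)) {
    abort("`outline` needs fields `area` and `perimeter`")
  }
  if (outline$perimeter <= 0) abort("zero perimeter: roundness undefined")
  4 * pi * outline$area / outline$perimeter^2
}

#' Sphericity of a solid
#'
#' The ratio of the surface area of the sphere with the same volume to the
#' actual surface area: `E = pi^(1/3) (6V)^(2/3) / S_a`; 1 for a sphere,
#' ~0.806 for a cube, decreasing with elongation.
#'
#' @param volume Volume in mm^3 (> 0).
#' @param area Surface area in mm^2 (> 0).
#' @return Unitless sphericity in (0, 1] up to measurement tolerance.
#' @export
sphericity <- function(volume, area) {
  if (!is.numeric(volume) || volume <= 0) abort("`volume` must be > 0")
  if (!is.numeric(area) || area <= 0) abort("`area` must be > 0")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}
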