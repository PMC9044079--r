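# Fixture builders and independent oracles used across the suite.

# uniform sample of a sphere surface
sphere_cloud <- function(n = 2000, r = 3, center = c(0, 0, 0), seed = 1,
                         noise_sd = 0) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    m <- r * v + matrix(center, n, 3, byrow = TRUE)
    if (noise_sd > 0) m <- m + matrix(rnorm(3 * n, sd = noise_sd), ncol = 3)
    point_cloud(m)
  })
}

# dense grid sample of the surface of an axis-aligned box centred at origin
box_cloud <- function(dims = c(6, 3, 2.8), spacing = 0.08) {
  hx <- dims[1] / 2; hy <- dims[2] / 2; hz <- dims[3] / 2
  gx <- seq(-hx, hx, by = spacing)
  gy <- seq(-hy, hy, by = spacing)
  gz <- seq(-hz, hz, by = spacing)
  faces <- rbind(
    expand.grid(x = gx, y = gy, z = c(-hz, hz)),
    expand.grid(x = gx, y = c(-hy, hy), z = gz),
    expand.grid(x = c(-hx, hx), y = gy, z = gz)
  )
  point_cloud(unique(as.matrix(faces)))
}

# unit cube [0,1]^3 as 12 consistently oriented (outward) triangles
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # vertices: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) 5:(0,0,1) 6:(1,0,1)
  #           7:(0,1,1) 8:(1,1,1)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # bottom (z = 0), normal -z
    c(5, 6, 8), c(5, 8, 7),   # top
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = 1
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6)    # x = 1
  )
  grain_mesh(v, f)
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    qr_res <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_res)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

rigid_move <- function(cloud, seed = 1, translation = c(5, -3, 2)) {
  R <- random_rotation(seed)
  m <- cloud_matrix_t(cloud) %*% t(R)
  point_cloud(sweep(m, 2, -translation))
}

cloud_matrix_t <- function(cloud) cbind(cloud$x, cloud$y, cloud$z)

# Monte-Carlo volume oracle for a *convex* mesh: a point is inside iff it is
# behind every outward-oriented face plane.
mc_convex_volume <- function(mesh, n = 20000, seed = 1) {
  V <- mesh$vertices
  F <- mesh$faces
  ctr <- colMeans(V)
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  # orient all face normals outward from the centroid
  flip <- rowSums(nrm * (a - matrix(ctr, nrow(a), 3, byrow = TRUE))) < 0
  nrm[flip, ] <- -nrm[flip, ]
  off <- rowSums(nrm * a)
  lo <- apply(V, 2, min)
  hi <- apply(V, 2, max)
  withr::with_seed(seed, {
    pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                 runif(n, lo[3], hi[3]))
    inside <- logical(n)
    for (st in seq(1, n, by = 1000)) {
      en <- min(st + 999, n)
      blk <- pts[st:en, , drop = FALSE] %*% t(nrm)
      inside[st:en] <-
        rowSums(blk > matrix(off, en - st + 1, length(off), byrow = TRUE)) == 0
    }
    mean(inside) * prod(hi - lo)
  })
}

# closed ring profile of an ellipse, optionally with a V-groove carved
# between lips gw apart on the ventral (-z) arc, tip `depth` above the chord
ring_profile <- function(b = 1.6, c = 1.4, n = 400, depth = 0, gw = 1.2,
                         noise_sd = 0, seed = 1) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(b * cos(tt), c * sin(tt))
  if (depth > 0) {
    tl0 <- acos(gw / (2 * b))
    t_L <- pi + tl0
    t_R <- 2 * pi - tl0
    zL <- -c * sin(tl0)
    inC <- tt > t_L & tt < t_R
    tau <- (tt[inC] - t_L) / (t_R - t_L)
    tip <- c(0, zL + depth)
    L <- c(-gw / 2, zL)
    R <- c(gw / 2, zL)
    gpt <- matrix(0, sum(inC), 2)
    lo <- tau <= 0.5
    gpt[lo, ] <- cbind(L[1] + 2 * tau[lo] * (tip[1] - L[1]),
                       L[2] + 2 * tau[lo] * (tip[2] - L[2]))
    gpt[!lo, ] <- cbind(tip[1] + (2 * tau[!lo] - 1) * (R[1] - tip[1]),
                        tip[2] + (2 * tau[!lo] - 1) * (R[2] - tip[2]))
    p[inC, ] <- gpt
  }
  if (noise_sd > 0) {
    p <- withr::with_seed(seed, p + matrix(rnorm(2 * n, sd = noise_sd), ncol = 2))
  }
  p
}

# quick low-density grain for cheap end-to-end tests
quick_grain <- function(seed = 1, n_points = 2000, ...) {
  make_grain(n_points = n_points, seed = seed, ...)
}

# shoelace area of a polygon given as ordered vertices (independent oracle)
polygon_area_oracle <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# near-uniform Fibonacci-lattice sphere sample (evenly spaced, no clumps)
fib_sphere <- function(n = 1500, r = 3) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  point_cloud(r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi)))
}
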