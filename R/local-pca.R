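# Vectorised local PCA over k-nearest neighbourhoods: per-point normal
# (smallest-eigenvalue eigenvector of the neighbourhood covariance) and
# surface variation lambda_min / (lambda_1 + lambda_2 + lambda_3).
# The 3x3 symmetric eigenproblem is solved in closed form (trigonometric
# method) for all points at once; the plane offset of each point from its
# neighbourhood is returned for MLS-style smoothing.
local_pca3 <- function(m, k) {
  n <- nrow(m)
  nn <- RANN::nn2(m, m, k = k + 1L)$nn.idx
  X <- matrix(m[nn, 1], n)
  Y <- matrix(m[nn, 2], n)
  Z <- matrix(m[nn, 3], n)
  mx <- rowMeans(X); my <- rowMeans(Y); mz <- rowMeans(Z)
  a <- rowMeans(X * X) - mx * mx
  b <- rowMeans(Y * Y) - my * my
  cc <- rowMeans(Z * Z) - mz * mz
  d <- rowMeans(X * Y) - mx * my
  e <- rowMeans(X * Z) - mx * mz
  f <- rowMeans(Y * Z) - my * mz

  q <- (a + b + cc) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (cc - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-30
  lam_min <- q
  if (any(ok)) {
    ip <- 1 / p[ok]
    B11 <- (a[ok] - q[ok]) * ip; B22 <- (b[ok] - q[ok]) * ip
    B33 <- (cc[ok] - q[ok]) * ip
    B12 <- d[ok] * ip; B13 <- e[ok] * ip; B23 <- f[ok] * ip
    detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
      B13 * (B12 * B23 - B22 * B13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    lam_min[ok] <- q[ok] + 2 * p[ok] * cos(phi + 2 * pi / 3)
  }
  # eigenvector of the smallest eigenvalue: cross product of two rows of
  # (C - lambda I); pick the largest-norm candidate per point
  r1x <- a - lam_min; r1y <- d;            r1z <- e
  r2x <- d;           r2y <- b - lam_min;  r2z <- f
  r3x <- e;           r3y <- f;            r3z <- cc - lam_min
  v1 <- cbind(r1y * r2z - r1z * r2y, r1z * r2x - r1x * r2z, r1x * r2y - r1y * r2x)
  v2 <- cbind(r1y * r3z - r1z * r3y, r1z * r3x - r1x * r3z, r1x * r3y - r1y * r3x)
  v3 <- cbind(r2y * r3z - r2z * r3y, r2z * r3x - r2x * r3z, r2x * r3y - r2y * r3x)
  n1 <- rowSums(v1^2); n2 <- rowSums(v2^2); n3 <- rowSums(v3^2)
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  nrm <- v1
  nrm[pick == 2, ] <- v2[pick == 2, , drop = FALSE]
  nrm[pick == 3, ] <- v3[pick == 3, , drop = FALSE]
  len <- sqrt(rowSums(nrm^2))
  deg <- len < 1e-20
  if (any(deg)) {
    # isotropic or degenerate neighbourhood: fall back to dense eigen
    for (i in which(deg)) {
      C <- matrix(c(a[i], d[i], e[i], d[i], b[i], f[i], e[i], f[i], cc[i]), 3, 3)
      nrm[i, ] <- eigen(C, symmetric = TRUE)$vectors[, 3]
    }
    len[deg] <- 1
  }
  nrm <- nrm / len
  tot <- a + b + cc
  curv <- ifelse(tot > 0, pmax(lam_min, 0) / tot, 0)
  # signed offset of the point from its neighbourhood plane
  off <- (m[, 1] - mx) * nrm[, 1] + (m[, 2] - my) * nrm[, 2] +
    (m[, 3] - mz) * nrm[, 3]
  list(normals = nrm, curvature = curv, offset = off, knn = nn)
}
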