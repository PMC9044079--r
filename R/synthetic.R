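#' Synthetic grooved-grain point clouds with analytic ground truth
#'
#' `make_grain()` samples the surface of a model wheat grain: a
#' superellipsoid of semi-axes `a >= b >= c` (length/width/thickness
#' direction) whose ventral side carries a longitudinal crease. Each
#' cross-section is an ellipse in which the arc between two lip points
#' (`groove_width` apart) is replaced by a V-fold rising `groove_depth` mm
#' above the lip chord at the grain centre, so the planted depth is exactly
#' the chord-to-tip distance that the sulcus trait measures on the maximal
#' slice. The fold tapers smoothly to nothing beyond 90% of the half-length.
#' Points are sampled area-weighted on the deformed surface by rejection
#' sampling (no pole clustering) and perturbed by isotropic Gaussian noise.
#'
#' Ground-truth length and width are analytic (`l = 2a`, `w = 2b`, `D =
#' groove_depth`); thickness, volume, surface area and the central-slice
#' measures are computed by high-resolution numeric quadrature of the same
#' parameterisation.
#'
#' @param a,b,c Semi-axes in mm (defaults 4, 1.6, 1.4: an 8 x 3.2 x 2.8 mm
#'   grain, mid-range for the 6-10 mm length class).
#' @param groove_depth Crease depth in mm, `0 <= groove_depth < c`
#'   (default 0.5; sub-millimetre like the real sulcus).
#' @param groove_width Crease mouth width in mm (< 2b; default 1.2).
#' @param exponent Superellipse exponent of the length profile (2 =
#'   ellipsoid, larger = blockier; default 2).
#' @param n_points Number of surface points (default 12000: a merged
#'   multi-view cloud at ~0.08 mm effective spacing, a few overlapping views
#'   of a 0.16 mm point-distance scanner).
#' @param noise_sd Isotropic Gaussian noise SD in mm (default 0.02, the
#'   residual noise of a merged multi-view scan under a 0.05 mm single-shot
#'   accuracy).
#' @param seed RNG seed; output is deterministic given it.
#' @return A list with `cloud` (point-cloud tibble) and `truth` (list:
#'   `l`, `w`, `h`, `V`, `S_a`, `D`, `slice_perimeter`, `slice_area`,
#'   `sulcus_area`, plus the parameters).
#' @examples
#' g <- make_grain(seed = 1)
#' nrow(g$cloud)
#' g$truth$l
#' @export
make_grain <- function(a = 4, b = 1.6, c = 1.4, groove_depth = 0.5,
                       groove_width = 1.2, exponent = 2, n_points = 12000,
                       noise_sd = 0.02, seed = 1) {
  if (!(a >= b && b >= c && c > 0)) abort("need semi-axes a >= b >= c > 0")
  if (groove_depth < 0 || groove_depth >= c) abort("need 0 <= groove_depth < c")
  if (groove_width <= 0 || groove_width >= 2 * b) abort("need 0 < groove_width < 2b")
  if (exponent < 1) abort("`exponent` must be >= 1")
  if (n_points < 100) abort("need n_points >= 100")
  par <- list(a = a, b = b, c = c, groove_depth = groove_depth,
              groove_width = groove_width, exponent = exponent)

  cloud <- withr::with_seed(seed, {
    pts <- sample_grain_surface(par, n_points)
    pts + matrix(rnorm(3 * n_points, sd = noise_sd), ncol = 3)
  })
  truth <- grain_ground_truth(par)
  truth$n_points <- n_points
  truth$noise_sd <- noise_sd
  truth$seed <- seed
  list(cloud = cloud_from_matrix(cloud), truth = truth)
}

# Surface point at parameters (u, t): u in (-pi/2, pi/2) runs along the
# length, t in [0, 2pi) around the cross-section.
grain_surface_eval <- function(u, t, par) {
  e <- par$exponent
  su <- sin(u)
  x <- par$a * sign(su) * abs(su)^(2 / e)
  s <- abs(cos(u))^(2 / e)
  yz <- grain_section_eval(t, abs(x) / par$a, par)
  cbind(x, s * yz[, 1], s * yz[, 2])
}

# Unscaled cross-section (Y, Z) at parameter t; q = |x|/a picks the crease
# window. The ellipse arc between the two lips is blended with a V-fold
# whose tip sits groove_depth above the lip chord.
grain_section_eval <- function(t, q, par) {
  b <- par$b
  cc <- par$c
  t <- t %% (2 * pi)
  E <- cbind(b * cos(t), cc * sin(t))
  d <- par$groove_depth
  gw <- par$groove_width
  tl0 <- acos(gw / (2 * b))
  t_L <- pi + tl0
  t_R <- 2 * pi - tl0
  inC <- t > t_L & t < t_R
  if (!any(inC)) return(E)
  win <- crease_window(q)
  if (length(win) == 1) win <- rep(win, length(t))
  zL <- -cc * sin(tl0)
  L <- c(-gw / 2, zL)
  R <- c(gw / 2, zL)
  Tip <- c(0, zL + d)
  tau <- (t[inC] - t_L) / (t_R - t_L)
  G <- matrix(0, sum(inC), 2)
  lo <- tau <= 0.5
  G[lo, 1] <- L[1] + 2 * tau[lo] * (Tip[1] - L[1])
  G[lo, 2] <- L[2] + 2 * tau[lo] * (Tip[2] - L[2])
  G[!lo, 1] <- Tip[1] + (2 * tau[!lo] - 1) * (R[1] - Tip[1])
  G[!lo, 2] <- Tip[2] + (2 * tau[!lo] - 1) * (R[2] - Tip[2])
  w <- win[inC]
  E[inC, 1] <- (1 - w) * E[inC, 1] + w * G[, 1]
  E[inC, 2] <- (1 - w) * E[inC, 2] + w * G[, 2]
  E
}

# smooth taper of the crease along the length: full for |x| <= 0.7a,
# cosine ramp to zero at 0.9a
crease_window <- function(q) {
  w <- numeric(length(q))
  w[q <= 0.7] <- 1
  ramp <- q > 0.7 & q < 0.9
  w[ramp] <- 0.5 * (1 + cos(pi * (q[ramp] - 0.7) / 0.2))
  w
}

# area-weighted rejection sampling of the parameterised surface
sample_grain_surface <- function(par, n_points) {
  jac <- function(u, t) {
    h <- 1e-5
    p0 <- grain_surface_eval(u, t, par)
    pu <- (grain_surface_eval(u + h, t, par) - p0) / h
    pt <- (grain_surface_eval(u, t + h, par) - p0) / h
    cr <- cbind(
      pu[, 2] * pt[, 3] - pu[, 3] * pt[, 2],
      pu[, 3] * pt[, 1] - pu[, 1] * pt[, 3],
      pu[, 1] * pt[, 2] - pu[, 2] * pt[, 1]
    )
    sqrt(rowSums(cr^2))
  }
  gu <- seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = 40)
  gt <- seq(0, 2 * pi, length.out = 80)
  jmax <- 1.2 * max(jac(rep(gu, each = length(gt)), rep(gt, length(gu))))
  out <- matrix(0, 0, 3)
  while (nrow(out) < n_points) {
    m <- ceiling((n_points - nrow(out)) * 2.5)
    u <- runif(m, -pi / 2, pi / 2)
    t <- runif(m, 0, 2 * pi)
    keep <- runif(m) * jmax <= jac(u, t)
    if (any(keep)) {
      out <- rbind(out, grain_surface_eval(u[keep], t[keep], par))
    }
  }
  out[seq_len(n_points), , drop = FALSE]
}

# numeric quadrature of the ground-truth measures
grain_ground_truth <- function(par, nu = 250, nt = 720) {
  a <- par$a
  # thickness + surface area from a fine parameter grid
  gu <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = nu)
  gt <- seq(0, 2 * pi, length.out = nt + 1)[- (nt + 1)]
  P <- grain_surface_eval(rep(gu, each = nt), rep(gt, nu), par)
  h <- max(P[, 3]) - min(P[, 3])
  S_a <- param_grid_area(P, nu, nt)
  # volume: integrate cross-section polygon areas along x
  xs <- seq(-a * (1 - 1e-7), a * (1 - 1e-7), length.out = 400)
  e <- par$exponent
  Avals <- vapply(xs, function(x) {
    s <- (1 - (abs(x) / a)^e)^(1 / e)
    if (s < 1e-9) return(0)
    yz <- s * grain_section_eval(gt, abs(x) / a, par)
    polygon_area(yz)
  }, numeric(1))
  V <- sum((Avals[-1] + Avals[-length(Avals)]) / 2 * diff(xs))
  # central-slice measures
  yz0 <- grain_section_eval(gt, 0, par)
  i2 <- c(2:nrow(yz0), 1)
  slice_perimeter <- sum(sqrt(rowSums((yz0[i2, ] - yz0)^2)))
  slice_area <- polygon_area(yz0)
  hull <- grDevices::chull(yz0)
  hull_area <- polygon_area(yz0[hull, , drop = FALSE])
  list(
    l = 2 * par$a, w = 2 * par$b, h = h, V = V, S_a = S_a,
    D = par$groove_depth,
    slice_perimeter = slice_perimeter, slice_area = slice_area,
    sulcus_area = hull_area - slice_area,
    params = par
  )
}

# total area of a (nu x nt) parameter grid of surface points (t closes)
param_grid_area <- function(P, nu, nt) {
  idx <- function(i, j) (i - 1) * nt + ((j - 1) %% nt) + 1
  i <- rep(seq_len(nu - 1), each = nt)
  j <- rep(seq_len(nt), nu - 1)
  v00 <- P[idx(i, j), , drop = FALSE]
  v10 <- P[idx(i + 1, j), , drop = FALSE]
  v01 <- P[idx(i, j + 1), , drop = FALSE]
  v11 <- P[idx(i + 1, j + 1), , drop = FALSE]
  tri_area <- function(p, q, r) {
    e1 <- q - p
    e2 <- r - p
    cr <- cbind(
      e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
      e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
      e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    )
    sqrt(rowSums(cr^2)) / 2
  }
  sum(tri_area(v00, v10, v11)) + sum(tri_area(v00, v11, v01))
}

# random grain parameters emulating a mixed five-variety sample
random_grain_params <- function() {
  b <- runif(1, 1.4, 1.65)
  list(
    a = runif(1, 3.2, 4.2),
    b = b,
    c = b * runif(1, 0.82, 0.92),
    groove_depth = runif(1, 0.3, 0.7),
    groove_width = runif(1, 1.0, 1.4)
  )
}

#' Synthetic multi-grain stage scene
#'
#' Lays `n_grains` random grains (see [make_grain()]) on a square grid above
#' a planar stage sample at z = 0, each with a random yaw about the vertical
#' and resting on the stage. Per-point labels record the ground truth:
#' 0 = stage, 1..n = grains.
#'
#' @param n_grains Number of grains (default 25, a full tray).
#' @param layout_spacing Grid spacing in mm (default 12; must exceed half
#'   the longest grain).
#' @param stage_extent Side length of the square stage in mm; default covers
#'   the grid plus a margin.
#' @param stage_spacing Stage sampling grid in mm (default 0.4).
#' @param n_points_grain Surface points per grain (default 1500).
#' @param noise_sd Noise SD in mm for grains and stage (default 0.02).
#' @param seed RNG seed.
#' @return A list with `cloud` (labelled point-cloud tibble) and `truth`
#'   (per-grain truths and placements).
#' @export
make_scene <- function(n_grains = 25, layout_spacing = 12, stage_extent = NULL,
                       stage_spacing = 0.4, n_points_grain = 1500,
                       noise_sd = 0.02, seed = 1) {
  if (n_grains < 1) abort("need at least one grain")
  side <- ceiling(sqrt(n_grains))
  withr::with_seed(seed, {
    grains <- vector("list", n_grains)
    truths <- vector("list", n_grains)
    seeds <- sample.int(.Machine$integer.max - 1, n_grains)
    for (i in seq_len(n_grains)) {
      rp <- random_grain_params()
      if (layout_spacing <= rp$a) {
        abort(sprintf(
          "overlapping placement: layout_spacing %.1f mm <= half grain length %.1f mm",
          layout_spacing, rp$a
        ))
      }
      g <- do.call(make_grain, c(rp, list(
        n_points = n_points_grain, noise_sd = noise_sd, seed = seeds[i]
      )))
      yaw <- runif(1, 0, 2 * pi)
      Rz <- matrix(c(cos(yaw), -sin(yaw), 0,
                     sin(yaw), cos(yaw), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
      # half-turn about x lays the grain crease-up, as grains are placed for
      # scanning; the ventral fold must stay visible above the stage
      Rx <- diag(c(1, -1, -1))
      m <- cloud_matrix(g$cloud) %*% t(Rx) %*% t(Rz)
      row <- (i - 1) %/% side
      col <- (i - 1) %% side
      cx <- (col - (side - 1) / 2) * layout_spacing
      cy <- (row - (side - 1) / 2) * layout_spacing
      m[, 1] <- m[, 1] + cx
      m[, 2] <- m[, 2] + cy
      m[, 3] <- m[, 3] - min(m[, 3])   # rest on the stage
      grains[[i]] <- m
      truths[[i]] <- c(g$truth, list(yaw = yaw, center_xy = c(cx, cy)))
    }
    extent <- stage_extent %||% ((side - 1) * layout_spacing + 12)
    gx <- seq(-extent / 2, extent / 2, by = stage_spacing)
    stage <- cbind(
      rep(gx, times = length(gx)),
      rep(gx, each = length(gx)),
      0
    )
    stage[, 3] <- stage[, 3] + rnorm(nrow(stage), sd = noise_sd)
    all <- rbind(stage, do.call(rbind, grains))
    label <- c(
      rep(0L, nrow(stage)),
      rep(seq_len(n_grains), times = vapply(grains, nrow, 0L))
    )
    list(
      cloud = cloud_from_matrix(all, label = label),
      truth = list(grains = truths, n_grains = n_grains,
                   stage_extent = extent, seed = seed)
    )
  })
}

#' Synthetic trait table with known weights
#'
#' Generates `n` random grains, measures each with the real trait pipeline
#' ([grain_traits()]) and attaches a weight column with a planted linear
#' signal on the measured volume: `weight = density * V + N(0, noise_sd_mg)`,
#' landing in the realistic 25-50 mg single-grain range for the defaults.
#'
#' @param n Number of grains (default 500).
#' @param noise_sd_mg Weight noise SD in mg (default 0.5).
#' @param density Kernel density in mg/mm^3 (default 1.2).
#' @param n_points Surface points per grain (default 1200, keeping batch
#'   generation tractable).
#' @param seed RNG seed.
#' @return A trait tibble with `id`, the 32 traits, and `weight` (mg); the
#'   attribute `"truth"` holds the noiseless volumes and weights.
#' @export
make_weight_dataset <- function(n = 500, noise_sd_mg = 0.5, density = 1.2,
                                n_points = 1200, seed = 1) {
  if (n < 20) abort("need n >= 20 grains")
  withr::with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1, n)
    eps <- rnorm(n, sd = noise_sd_mg)
    rows <- vector("list", n)
    vtrue <- numeric(n)
    for (i in seq_len(n)) {
      rp <- random_grain_params()
      g <- do.call(make_grain, c(rp, list(n_points = n_points, seed = seeds[i])))
      rows[[i]] <- grain_traits(g$cloud, id = i)
      vtrue[i] <- g$truth$V
    }
    out <- dplyr::bind_rows(rows)
    # the signal is planted on the measured volume column, so a noiseless
    # table carries an exactly linear relation for the regression harness
    out$weight <- density * out$V + eps
    attr(out, "truth") <- tibble(
      id = seq_len(n), V_true = vtrue, weight_noiseless = density * vtrue
    )
    out
  })
}
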