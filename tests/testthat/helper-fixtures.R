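# Shared fixtures, built in code at test time.

# Torus mesh (genus 1, Euler characteristic 0): parametric grid with wrap.
torus_mesh <- function(n_u = 24L, n_v = 12L, R = 10, r = 3) {
  iu <- rep(0:(n_u - 1L), times = n_v)
  iv <- rep(0:(n_v - 1L), each = n_u)
  u <- 2 * pi * iu / n_u
  v <- 2 * pi * iv / n_v
  verts <- cbind((R + r * cos(v)) * cos(u),
                 (R + r * cos(v)) * sin(u),
                 r * sin(v))
  id <- function(i, j) (i %% n_u) + (j %% n_v) * n_u + 1L
  i <- rep(0:(n_u - 1L), times = n_v)
  j <- rep(0:(n_v - 1L), each = n_u)
  f1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
  f2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  surface_mesh(verts, rbind(f1, f2))
}

# Volume whose intensity is a smooth step along y (white below, grey above),
# world == voxel coordinates (identity affine scaled by voxel size).
step_volume <- function(n = 40L, voxel = 1, edge_y = NULL, width = 0.8,
                        low = 50, high = 150) {
  if (is.null(edge_y)) edge_y <- n * voxel / 4
  yy <- rep(rep(0:(n - 1L), each = n), times = n) * voxel
  vals <- low + (high - low) * pnorm((yy - edge_y) / width)
  mri_volume(array(vals, c(n, n, n)), diag(c(voxel, voxel, voxel, 1)))
}

# Spherical blurred boundary volume centred at `centre`, white inside.
sphere_volume <- function(n = 40L, voxel = 1, centre = c(20, 20, 20),
                          radius = 8, width = 0.8, low = 50, high = 150) {
  ax <- (0:(n - 1L)) * voxel
  px <- rep(ax, times = n * n)
  py <- rep(rep(ax, each = n), times = n)
  pz <- rep(ax, each = n * n)
  rr <- sqrt((px - centre[1])^2 + (py - centre[2])^2 + (pz - centre[3])^2)
  mri_volume(array(low + (high - low) * pnorm((rr - radius) / width),
                   c(n, n, n)),
             diag(c(voxel, voxel, voxel, 1)))
}

# Vertices on the y = edge_y plane of a step volume, normals +y.
plane_vertices <- function(n_pts = 150L, edge_y = 10, lim = c(8, 32),
                           seed = 42L) {
  set.seed(seed)
  pos <- cbind(runif(n_pts, lim[1], lim[2]), edge_y,
               runif(n_pts, lim[1], lim[2]))
  list(positions = pos,
       normals = matrix(rep(c(0, 1, 0), each = n_pts), ncol = 3L))
}

# Small phantom used across driver/metrics tests (fast: ~2.5k vertices).
small_phantom_spec <- function(...) {
  args <- list(subdivisions = 4L, radius = 16, gyr_amplitude = 1.2,
               gyr_frequency = 12, voxel_size = 1.2, margin = 5)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Config for phantom registrations in tests: contrast-matched sampling as in
# the gold-standard harness.
phantom_cfg <- function(...) {
  rbr_config(bbr = bbr_params(projection_distance = 1, slope = 0.05), ...)
}

# Realistic-contrast variant (~20% grey/white contrast, as in vivo): on such
# data the percent-contrast optimum coincides with the geometric boundary, so
# method properties (identity stability, monotone refinement) can be asserted
# without the darkward offset that extreme contrast ratios induce.
lc_phantom_spec <- function(...) {
  small_phantom_spec(intensities = c(white = 100, grey = 120, csf = 106), ...)
}
lc_cfg <- function(...) {
  rbr_config(bbr = bbr_params(projection_distance = 1, slope = 0.2), ...)
}

# Independent barycentric-interpolation oracle for the piecewise-affine
# deformation of a lattice level (vectorised per point, written independently
# of apply_deformation).
barycentric_oracle <- function(points, level, displacements) {
  n <- level$n
  m <- n + 1L
  out <- matrix(0, nrow(points), 3L)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    relu <- (p - level$origin) / level$cell
    ijk <- pmin(pmax(floor(relu), 0), n - 1L)
    u <- relu - ijk
    ord <- order(u, decreasing = TRUE)
    lam <- c(1 - u[ord[1]], u[ord[1]] - u[ord[2]], u[ord[2]] - u[ord[3]],
             u[ord[3]])
    bits <- rbind(c(0, 0, 0), diag(3)[ord[1], ],
                  diag(3)[ord[1], ] + diag(3)[ord[2], ], c(1, 1, 1))
    ids <- apply(bits, 1L, function(b)
      (ijk[1] + b[1]) + (ijk[2] + b[2]) * m + (ijk[3] + b[3]) * m * m + 1)
    rest <- level$node_positions[ids, , drop = FALSE]
    out[i, ] <- colSums(lam * (rest + displacements[ids, , drop = FALSE]))
  }
  out
}
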