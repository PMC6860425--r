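test_that("contrast is zero in a constant volume", {
  vol <- mri_volume(array(100, c(20, 20, 20)))
  pv <- plane_vertices(50, edge_y = 10, lim = c(5, 15))
  q <- sample_contrast(vol, pv$positions, pv$normals)
  expect_equal(q, rep(0, 50))
})

test_that("contrast across a hard step is the closed-form 100", {
  # inner value 50, outer 150, vertex exactly on the step
  n <- 30L
  yy <- rep(rep(0:(n - 1), each = n), times = n)
  vol <- mri_volume(array(ifelse(yy < 10, 50, 150), c(n, n, n)))
  pos <- cbind(15, 10 + 0.5, 15)  # mid-voxel edge between rows 9 and 10
  nrm <- matrix(c(0, 1, 0), 1)
  q <- sample_contrast(vol, pos, nrm, bbr_params(projection_distance = 2))
  expect_equal(as.numeric(q), 100 * (150 - 50) / (0.5 * (150 + 50)),
               tolerance = 1e-12)
})

test_that("contrast matches a direct interpolation oracle on a smooth ramp", {
  vol <- step_volume(n = 40, edge_y = 18, width = 3)
  set.seed(5)
  pos <- cbind(runif(50, 10, 30), runif(50, 14, 22), runif(50, 10, 30))
  nrm <- matrix(rnorm(150), ncol = 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  p <- bbr_params(projection_distance = 1.7)
  q <- sample_contrast(vol, pos, nrm, p)
  w <- sample_volume(vol, pos - 1.7 * nrm)
  g <- sample_volume(vol, pos + 1.7 * nrm)
  expect_equal(q, 100 * (g - w) / (0.5 * (g + w)), tolerance = 1e-6)
})

test_that("contrast_sign flips the sign for T1-like targets", {
  vol <- step_volume()
  pv <- plane_vertices()
  q1 <- sample_contrast(vol, pv$positions, pv$normals,
                        bbr_params(contrast_sign = 1))
  q2 <- sample_contrast(vol, pv$positions, pv$normals,
                        bbr_params(contrast_sign = -1))
  expect_equal(q1, -q2)
})

test_that("sampling entirely outside the volume is an error", {
  vol <- mri_volume(array(1, c(10, 10, 10)))
  expect_error(
    sample_contrast(vol, matrix(c(500, 500, 500), 1), matrix(c(0, 1, 0), 1)),
    "outside")
})

test_that("bbr_cost follows the saturating tanh formula exactly", {
  # oracle: recompute from sampled contrasts with the documented formula
  vol <- step_volume(n = 30, edge_y = 12, width = 2)
  set.seed(9)
  pos <- cbind(runif(40, 8, 22), runif(40, 9, 15), runif(40, 8, 22))
  nrm <- matrix(rnorm(120), ncol = 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  par <- bbr_params(projection_distance = 1.3, slope = 0.37, offset = 4.2)
  q <- sample_contrast(vol, pos, nrm, par)
  oracle <- mean(1 + tanh(0.37 * (4.2 - q) / 2))
  expect_equal(bbr_cost(vol, pos, nrm, par), oracle, tolerance = 1e-12)
  expect_gte(min(oracle, 2), oracle)  # bounded in [0, 2]
  expect_gte(oracle, 0)
})

test_that("cost limits: saturated contrast gives 0, offset contrast gives 1", {
  # all Q equal to the offset -> tanh(0) -> cost exactly 1
  vol <- mri_volume(array(100, c(20, 20, 20)))
  pv <- plane_vertices(30, edge_y = 10, lim = c(5, 15))
  expect_equal(bbr_cost(vol, pv$positions, pv$normals, bbr_params(offset = 0)),
               1, tolerance = 1e-14)
  # strongly positive oriented contrast saturates towards 0
  vol2 <- step_volume(width = 0.5)
  expect_lt(bbr_cost(vol2, pv$positions, pv$normals, bbr_params(slope = 0.5)),
            1e-6)
})

test_that("cost is invariant under simultaneous rigid motion", {
  vol <- sphere_volume()
  m <- icosphere(3, 8)
  m$vertices <- sweep(m$vertices, 2, c(20, 20, 20), "+")
  nrm <- vertex_normals(m)
  par <- bbr_params(projection_distance = 1, slope = 0.1)
  c0 <- bbr_cost(vol, m$vertices, nrm, par)

  # rotate volume and vertices together by 90 degrees about z (exact on the
  # voxel grid for this centred sphere)
  Rz <- rbind(c(0, -1, 0, 40), c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  vol_r <- mri_volume(vol$data, Rz %*% vol$affine)
  v_r <- apply_affine(Rz, m$vertices)
  n_r <- t(Rz[1:3, 1:3] %*% t(nrm))
  expect_equal(bbr_cost(vol_r, v_r, n_r, par), c0, tolerance = 1e-9)
})

test_that("fit recovers a pure y translation within the scan tolerance", {
  vol <- step_volume(n = 40, edge_y = 10, width = 0.8)
  pv <- plane_vertices(200, edge_y = 10, lim = c(6, 34))
  par <- bbr_params(projection_distance = 2, slope = 0.05)
  shifted <- sweep(pv$positions, 2, c(0, 1.5, 0), "+")
  fit <- fit_local_transform(vol, shifted, pv$normals,
                             dof_spec(translate = "y", scale = character(0)),
                             par)
  expect_true(fit$converged)
  # brute-force 1-D scan oracle
  offs <- seq(-3, 3, by = 0.01)
  costs <- vapply(offs, function(dy)
    bbr_cost(vol, sweep(shifted, 2, c(0, dy, 0), "+"), pv$normals, par),
    numeric(1))
  best <- offs[which.min(costs)]
  expect_lt(abs(fit$par - best), 0.1)
  expect_lt(abs(fit$par - (-1.5)), 0.1)
  expect_equal(apply_affine(fit$transform, c(0, 0, 0)),
               matrix(c(0, fit$par, 0), 1), tolerance = 1e-12)
})

test_that("fit recovers a y scale about the centroid within 0.01", {
  # realistic ~20% tissue contrast: the percent-contrast optimum then sits at
  # the geometric boundary (strong contrast ratios bias it darkward)
  vol <- sphere_volume(width = 0.8, low = 100, high = 120)
  m <- icosphere(3, 8)
  m$vertices <- sweep(m$vertices, 2, c(20, 20, 20), "+")
  ctr <- colMeans(m$vertices)
  scaled <- m
  scaled$vertices[, 2] <- ctr[2] + (scaled$vertices[, 2] - ctr[2]) * 1.05
  par <- bbr_params(projection_distance = 1, slope = 0.2)
  dof <- dof_spec(translate = character(0), scale = "y", pivot = ctr)
  fit <- fit_local_transform(vol, scaled$vertices, vertex_normals(scaled),
                             dof, par)
  # oracle: brute-force scan over the scale factor, carrying normals through
  # the candidate scaling (inverse-transpose, renormalised)
  ss <- seq(0.9, 1.1, by = 0.001)
  nrm <- vertex_normals(scaled)
  costs <- vapply(ss, function(s) {
    v <- scaled$vertices
    v[, 2] <- ctr[2] + (v[, 2] - ctr[2]) * s
    n <- nrm
    n[, 2] <- n[, 2] / s
    n <- n / sqrt(rowSums(n^2))
    bbr_cost(vol, v, n, par)
  }, numeric(1))
  best <- ss[which.min(costs)]
  expect_lt(abs((1 + fit$par) - best), 0.01)
})

test_that("zero-contrast volumes return the init transform, non-converged", {
  vol <- mri_volume(array(77, c(20, 20, 20)))
  pv <- plane_vertices(40, edge_y = 10, lim = c(5, 15))
  init <- affine_translation(c(0, 0.25, 0))
  fit <- fit_local_transform(vol, pv$positions, pv$normals,
                             dof_spec(translate = "y", scale = character(0)),
                             bbr_params(), init = init)
  expect_false(fit$converged)
  expect_identical(fit$transform, init)
})

test_that("parameter bounds repel the search", {
  vol <- step_volume(n = 40, edge_y = 10, width = 0.8)
  pv <- plane_vertices(100, edge_y = 10, lim = c(6, 34))
  shifted <- sweep(pv$positions, 2, c(0, 2.5, 0), "+")
  fit <- fit_local_transform(vol, shifted, pv$normals,
                             dof_spec(translate = "y", scale = character(0)),
                             bbr_params(slope = 0.05),
                             bounds = rbind(-1, 1))
  expect_lte(abs(fit$par), 1)
})
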