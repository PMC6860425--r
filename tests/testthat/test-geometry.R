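test_that("surface_mesh validates faces and vertices", {
  v <- diag(3)
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_s3_class(surface_mesh(v, rbind(c(1, 2, 3))), "surface_mesh")
})

test_that("icosphere normals are radial and unit length", {
  m <- icosphere(3, radius = 7)
  n <- vertex_normals(m)
  expect_equal(sqrt(rowSums(n^2)), rep(1, nrow(n)), tolerance = 1e-12)
  u <- m$vertices / sqrt(rowSums(m$vertices^2))
  # outward radial to high accuracy on a sphere
  expect_gt(min(rowSums(n * u)), 1 - 1e-3)
})

test_that("normals point outward even when the winding is inverted on load", {
  m <- icosphere(2, radius = 5)
  flipped <- surface_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  n <- vertex_normals(flipped)
  u <- flipped$vertices / sqrt(rowSums(flipped$vertices^2))
  expect_gt(min(rowSums(n * u)), 1 - 1e-3)
})

test_that("axis-aligned cube face centres have axis normals", {
  # cube [0,1]^3 triangulated with a centre vertex per face
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  faces6 <- list(
    list(centre = c(0.5, 0.5, 0), ids = c(1, 2, 4, 3), n = c(0, 0, -1)),
    list(centre = c(0.5, 0.5, 1), ids = c(5, 7, 8, 6), n = c(0, 0, 1)),
    list(centre = c(0.5, 0, 0.5), ids = c(1, 5, 6, 2), n = c(0, -1, 0)),
    list(centre = c(0.5, 1, 0.5), ids = c(3, 4, 8, 7), n = c(0, 1, 0)),
    list(centre = c(0, 0.5, 0.5), ids = c(1, 3, 7, 5), n = c(-1, 0, 0)),
    list(centre = c(1, 0.5, 0.5), ids = c(2, 6, 8, 4), n = c(1, 0, 0)))
  verts <- corners
  faces <- NULL
  for (fc in faces6) {
    verts <- rbind(verts, fc$centre)
    ci <- nrow(verts)
    ids <- fc$ids
    for (k in seq_along(ids)) {
      a <- ids[k]; b <- ids[k %% 4 + 1]
      ea <- corners[a, ] - fc$centre
      eb <- corners[b, ] - fc$centre
      cr <- c(ea[2] * eb[3] - ea[3] * eb[2],
              ea[3] * eb[1] - ea[1] * eb[3],
              ea[1] * eb[2] - ea[2] * eb[1])
      faces <- rbind(faces,
                     if (sum(cr * fc$n) > 0) c(ci, a, b) else c(ci, b, a))
    }
  }
  mesh <- surface_mesh(verts, faces)
  n <- vertex_normals(mesh)
  for (k in seq_along(faces6))
    expect_equal(n[8 + k, ], faces6[[k]]$n, tolerance = 1e-12)
})

test_that("check_topology classifies sphere, punctured sphere and torus", {
  ico <- icosphere(2)
  tp <- check_topology(ico)
  expect_true(tp$is_closed)
  expect_true(tp$is_manifold)
  expect_identical(tp$euler_characteristic, 2L)
  expect_identical(tp$n_flipped_faces, 0L)

  holed <- surface_mesh(ico$vertices, ico$faces[-1, ])
  expect_false(check_topology(holed)$is_closed)

  expect_identical(check_topology(torus_mesh())$euler_characteristic, 0L)
})

test_that("check_topology counts minority-wound faces", {
  ico <- icosphere(2)
  f <- ico$faces
  flip <- c(3, 17, 40)
  f[flip, ] <- f[flip, c(1, 3, 2)]
  tp <- check_topology(surface_mesh(ico$vertices, f))
  expect_identical(tp$n_flipped_faces, 3L)
})

test_that("world/voxel round-trip is identity to 1e-9 mm", {
  expect_equal(world_to_voxel(mri_volume(array(0, c(4, 4, 4))), c(1, 2, 3)),
               matrix(c(1, 2, 3), 1), tolerance = 1e-15)
  vol2 <- mri_volume(array(0, c(4, 4, 4)), diag(c(2, 2, 2, 1)))
  expect_equal(world_to_voxel(vol2, c(4, 4, 4)), matrix(2, 1, 3),
               tolerance = 1e-15)
  set.seed(7)
  aff <- diag(4)
  aff[1:3, ] <- aff[1:3, ] + matrix(rnorm(12, sd = 0.2), 3)
  vol <- mri_volume(array(0, c(5, 5, 5)), aff)
  pts <- matrix(runif(300, -10, 10), ncol = 3)
  back <- voxel_to_world(vol, world_to_voxel(vol, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("singular affines are rejected", {
  aff <- diag(4); aff[1, 1] <- 0
  expect_error(mri_volume(array(0, c(2, 2, 2)), aff))
  expect_error(affine_transform(aff), "singular")
})

test_that("trilinear sampling interpolates exactly linear fields", {
  n <- 8L
  xx <- rep(0:(n - 1), times = n * n)
  yy <- rep(rep(0:(n - 1), each = n), times = n)
  zz <- rep(0:(n - 1), each = n * n)
  vol <- mri_volume(array(2 * xx - 3 * yy + 0.5 * zz + 7, c(n, n, n)))
  set.seed(11)
  pts <- matrix(runif(150, 0.5, n - 1.5), ncol = 3)
  expect_equal(sample_volume(vol, pts),
               2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 7,
               tolerance = 1e-12)
  # outside the grid: fill value
  expect_identical(sample_volume(vol, c(-5, 0, 0), fill = -1), -1)
})

test_that("apply_affine and constructors behave", {
  tr <- affine_translation(c(1, -2, 0.5))
  expect_equal(apply_affine(tr, c(0, 0, 0)), matrix(c(1, -2, 0.5), 1))
  expect_equal(affine_identity() %*% tr, tr)
})
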