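box <- rbind(c(-4, -4, -4), c(12, 12, 12))

test_that("lattice combinatorics: 8^d cuboids, (2^d + 1)^3 shared nodes", {
  lat <- build_lattice(box, 2)
  for (d in 0:2) {
    lv <- lat$levels[[d + 1]]
    expect_equal(nrow(lv$cuboid_corners), 8^d)
    expect_equal(nrow(lv$node_positions), (2^d + 1)^3)
    # corners of adjacent cuboids share node ids: total distinct ids used
    expect_equal(sort(unique(as.vector(lv$cuboid_corners))),
                 seq_len((2^d + 1)^3))
  }
})

test_that("vertex partition conserves counts and respects the half-open rule", {
  lat <- build_lattice(box, 2)
  lv <- lat$levels[[3]]
  set.seed(3)
  pts <- matrix(runif(900, -4, 12), ncol = 3)
  cub <- partition_vertices(pts, lv)
  expect_identical(length(cub), 300L)
  expect_identical(sum(table(cub)), 300L)
  # all vertices in one octant at depth 1
  lv1 <- lat$levels[[2]]
  oct <- matrix(runif(24, -3.9, 3.9), ncol = 3)  # all below the split at 4
  expect_identical(unique(partition_vertices(oct, lv1)), 1L)
  # a vertex exactly on an internal split plane joins the upper cuboid
  onplane <- matrix(c(4, 0, 0), 1)
  expect_identical(partition_vertices(onplane, lv1), 2L)
  # the box's max face is closed
  expect_identical(partition_vertices(matrix(c(12, 12, 12), 1), lv1), 8L)
  # outside the box errors
  expect_error(partition_vertices(matrix(c(13, 0, 0), 1), lv1), "outside")
})

test_that("corner displacements follow T p - p", {
  lat <- build_lattice(box, 1)
  lv <- lat$levels[[2]]
  corners <- lv$node_positions[lv$cuboid_corners[1, ], ]
  expect_equal(corner_displacements(affine_identity(), corners),
               matrix(0, 8, 3))
  expect_equal(corner_displacements(affine_translation(c(0, 1.5, 0)), corners),
               matrix(rep(c(0, 1.5, 0), each = 8), ncol = 3))
  # y-scale 1.1 about the cuboid centre: antisymmetric vectors of magnitude
  # 0.05 * y-extent
  ctr <- colMeans(corners)
  S <- diag(4); S[2, 2] <- 1.1; S[2, 4] <- -0.1 * ctr[2]
  d <- corner_displacements(S, corners)
  expect_equal(d[, c(1, 3)], matrix(0, 8, 2))
  yext <- diff(range(corners[, 2]))
  expect_equal(sort(unique(round(d[, 2], 10))),
               c(-0.05 * yext, 0.05 * yext))
  expect_equal(sum(d[, 2]), 0, tolerance = 1e-12)
})

test_that("median aggregation is componentwise, robust and permutation-invariant", {
  lat <- build_lattice(rbind(c(0, 0, 0), c(1, 1, 1)), 0)
  lv <- lat$levels[[1]]
  f <- control_point_field(lv)
  push_displacements(f, 1:8, matrix(0, 8, 3))
  push_displacements(f, 1, matrix(c(1, 0, 0), 1))
  push_displacements(f, 1, matrix(c(3, 0, 0), 1))
  push_displacements(f, 1, matrix(c(2, 0, 0), 1))
  agg <- aggregate_control_points(f)
  expect_equal(agg[1, ], c(median(c(0, 1, 3, 2)), 0, 0))
  expect_equal(agg[2, ], c(0, 0, 0))

  # robustness: one gross outlier among 5 consistent vectors
  f2 <- control_point_field(lv)
  push_displacements(f2, 1:8, matrix(0, 8, 3))
  for (k in 1:5) push_displacements(f2, 2, matrix(c(0, 1.5, 0), 1))
  push_displacements(f2, 2, matrix(c(0, 400, 0), 1))
  expect_equal(aggregate_control_points(f2)[2, 2], 1.5, tolerance = 1e-12)

  # permutation invariance of candidate order
  set.seed(8)
  cand <- matrix(rnorm(21), ncol = 3)
  f3 <- control_point_field(lv); push_displacements(f3, 1:8, matrix(0, 8, 3))
  f4 <- control_point_field(lv); push_displacements(f4, 1:8, matrix(0, 8, 3))
  for (i in 1:7) push_displacements(f3, 3, cand[i, , drop = FALSE])
  for (i in sample(7)) push_displacements(f4, 3, cand[i, , drop = FALSE])
  expect_equal(aggregate_control_points(f3), aggregate_control_points(f4))

  # empty node errors unless zero-resolution is requested
  f5 <- control_point_field(lv)
  push_displacements(f5, 1:4, matrix(1, 4, 3))
  expect_error(aggregate_control_points(f5), "no candidate")
  expect_equal(aggregate_control_points(f5, missing = "zero")[5:8, ],
               matrix(0, 4, 3))
})

test_that("neighbour smoothing implements d <- alpha d + (1 - alpha) M(x)", {
  lat <- build_lattice(box, 1)
  lv <- lat$levels[[2]]  # 3x3x3 nodes
  set.seed(2)
  d0 <- matrix(rnorm(27 * 3), ncol = 3)
  # alpha = 1: unchanged
  expect_identical(smooth_control_points(d0, lv, 1), d0)
  # uniform field: unchanged for any alpha
  du <- matrix(rep(c(1, -2, 0.5), each = 27), ncol = 3)
  expect_equal(smooth_control_points(du, lv, 0.3), du)
  # direct substitution: centre node (2,2,2) with own (2,0,0), all others 0
  dc <- matrix(0, 27, 3)
  centre <- 1 + 1 * 3 + 1 * 9 + 1  # 0-based (1,1,1) -> id 14
  dc[centre, ] <- c(2, 0, 0)
  sm <- smooth_control_points(dc, lv, 0.5)
  expect_equal(sm[centre, ], c(1, 0, 0))  # neighbours' mean is 0
  # synchronous update: the +x neighbour of the centre is a boundary node
  # with 5 lattice neighbours, one of which is the centre
  nb <- centre + 1
  expect_equal(sm[nb, 1], 0.5 * 0 + 0.5 * (2 / 5))
})

test_that("Kuhn subdivision tiles the cuboid and matches across faces", {
  bounds <- rbind(c(0, 0, 0), c(2, 3, 5))
  tets <- tetrahedralize(bounds)
  expect_length(tets, 6L)
  vols <- vapply(tets, function(t)
    abs(det(sweep(t$rest[2:4, ], 2, t$rest[1, ]))) / 6, numeric(1))
  expect_equal(vols, rep(prod(c(2, 3, 5)) / 6, 6), tolerance = 1e-12)

  # shared-face triangulations of two adjacent unit cubes agree
  t1 <- tetrahedralize(rbind(c(0, 0, 0), c(1, 1, 1)))
  t2 <- tetrahedralize(rbind(c(1, 0, 0), c(2, 1, 1)))
  face_tris <- function(tets, xval) {
    tri <- list()
    for (t in tets) {
      on <- abs(t$rest[, 1] - xval) < 1e-12
      if (sum(on) == 3)
        tri[[length(tri) + 1]] <- sort(apply(t$rest[on, c(2, 3)], 1,
                                             paste, collapse = ","))
    }
    unique(lapply(tri, sort))
  }
  expect_setequal(face_tris(t1, 1), face_tris(t2, 1))

  # any interior point lies in exactly one tetrahedron (point-location oracle)
  set.seed(12)
  pts <- matrix(runif(300), ncol = 3)
  inside_count <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    sum(vapply(t1, function(t) {
      # barycentric membership with tolerance
      M <- cbind(t(t$rest[2:4, ]) - t$rest[1, ])
      lam <- solve(M, p - t$rest[1, ])
      all(lam > 1e-9) && sum(lam) < 1 - 1e-9
    }, logical(1)))
  }, numeric(1))
  expect_true(all(inside_count == 1))
})

test_that("solve_tetra_affine reproduces corner displacements exactly", {
  tets <- tetrahedralize(rbind(c(0, 0, 0), c(1, 1, 1)))
  t1 <- tets[[1]]
  expect_equal(solve_tetra_affine(t1$rest, t1$rest), diag(4))
  shifted <- t1$rest + matrix(rep(c(0, 2, 0), each = 4), ncol = 3)
  expect_equal(solve_tetra_affine(t1$rest, shifted),
               affine_translation(c(0, 2, 0)))
  set.seed(4)
  for (k in 1:10) {
    displ <- t1$rest + matrix(rnorm(12, sd = 0.1), 4, 3)
    T <- solve_tetra_affine(t1$rest, displ)
    expect_lt(max(abs(apply_affine(T, t1$rest) - displ)), 1e-9)
  }
  degen <- t1$rest; degen[4, ] <- degen[1, ]
  expect_error(solve_tetra_affine(degen, degen), "degenerate")
})

test_that("apply_deformation matches the barycentric oracle and is continuous", {
  lv <- lattice_level(rbind(c(-1, -1, -1), c(7, 7, 7)), 2)
  set.seed(6)
  pts <- matrix(runif(600, -0.9, 6.9), ncol = 3)
  mesh <- surface_mesh(pts, matrix(integer(0), 0, 3), validate = FALSE)
  disp <- matrix(rnorm(nrow(lv$node_positions) * 3, sd = 0.15), ncol = 3)

  # zero field: identity
  out0 <- apply_deformation(mesh, lv, disp * 0)
  expect_equal(out0$vertices, pts)
  # uniform field: exact shift
  du <- matrix(rep(c(0, 1, 0), each = nrow(lv$node_positions)), ncol = 3)
  expect_equal(apply_deformation(mesh, lv, du)$vertices,
               sweep(pts, 2, c(0, 1, 0), "+"))
  # random field: equals the independent barycentric oracle
  out <- apply_deformation(mesh, lv, disp)
  oracle <- barycentric_oracle(pts, lv, disp)
  expect_lt(max(abs(out$vertices - oracle)), 1e-9)
  expect_true(all(attr(out, "jacobians") > 0))

  # continuity across shared internal faces: points on random internal
  # cuboid/tetra faces, displaced from both sides via the barycentric oracle
  # and via apply_deformation with jittered membership
  set.seed(13)
  base <- matrix(runif(3000, 0.05, 0.95), ncol = 3)
  # project onto internal lattice planes (x = 1, 3, 5 etc.) and tetra faces
  # (u_x = u_y etc.) to exercise tie-break boundaries
  face_pts <- rbind(
    cbind(3, base[1:250, 2] * 8 - 1, base[1:250, 3] * 8 - 1),       # cuboid face
    t(apply(base[251:500, ], 1, function(b) {                        # tetra face
      u <- c(b[1], b[1], b[2]) * 2  # u_x == u_y inside cuboid
      lv$origin + (c(0, 0, 0) + u) * lv$cell / 2 + c(2, 2, 2)
    })))
  m2 <- surface_mesh(face_pts, matrix(integer(0), 0, 3), validate = FALSE)
  img <- apply_deformation(m2, lv, disp)$vertices
  # nudging the query to either side must give the same image in the limit:
  # compare against the barycentric oracle evaluated with tiny +/- jitter
  for (eps in c(-1e-10, 1e-10)) {
    jit <- face_pts + eps
    expect_lt(max(abs(barycentric_oracle(jit, lv, disp) - img)), 1e-6)
  }
})
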