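#' Triangulated surface mesh
#'
#' Container for the grey--white boundary surface being registered: vertex
#' positions in world millimetres and triangular faces. Face indices are
#' 1-based inside R; the FreeSurfer and plain-text readers/writers convert
#' from/to the 0-based on-disk convention.
#'
#' @param vertices numeric matrix, n x 3, world mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with consistent
#'   outward winding.
#' @param validate check index ranges and face non-degeneracy (cheap checks;
#'   manifoldness is checked by [check_topology()]).
#' @return An object of class `surface_mesh`: a list with elements `vertices`
#'   and `faces`.
#' @seealso [vertex_normals()], [check_topology()]
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (validate) {
    if (nrow(faces) > 0L) {
      if (min(faces) < 1L || max(faces) > nrow(vertices))
        stop("face indices out of range")
      degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
        faces[, 2L] == faces[, 3L]
      if (any(degen))
        stop(sum(degen), " degenerate face(s) with repeated vertex indices")
    }
    if (anyNA(vertices)) stop("vertices contain NA")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- mesh_bounding_box(x)
  cat(sprintf("  bounding box [mm]: x [%.2f, %.2f], y [%.2f, %.2f], z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return 2 x 3 matrix; row 1 = minima, row 2 = maxima (mm).
#' @export
mesh_bounding_box <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

# Accumulate per-face vectors onto vertices (sum over incident faces).
accumulate_to_vertices <- function(faces, face_vec, n_vertices) {
  out <- matrix(0, n_vertices, 3L)
  for (k in 1:3) {
    for (c in 1:3) {
      sums <- rowsum(face_vec[, c], group = faces[, k], reorder = FALSE)
      out[as.integer(rownames(sums)), c] <- out[as.integer(rownames(sums)), c] + sums
    }
  }
  out
}

#' Outward per-vertex unit normals
#'
#' Area-weighted average of incident face normals, relying on consistent
#' face winding. If the total signed volume of the mesh is negative (majority
#' of faces wound inward) the winding is repaired by flipping all faces before
#' computing normals, so that normals point outward (white matter toward grey).
#'
#' @param mesh a closed [surface_mesh()].
#' @return n x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (mesh_signed_volume(mesh) < 0) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  # cross product rows: area-weighted face normals (norm = 2*area)
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- accumulate_to_vertices(f, fn, nrow(v))
  len <- sqrt(rowSums(n^2))
  if (any(len == 0))
    stop("isolated or degenerate vertices: zero accumulated normal")
  n / len
}

# Signed volume via divergence theorem (positive for outward winding).
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(p1 * cr) / 6
}

#' Topology report for a surface mesh
#'
#' Downstream laminar analysis requires the deformed mesh to remain a
#' topological sphere (closed 2-manifold without holes, Euler characteristic
#' 2). This reports the quantities needed to verify that, without erroring.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `is_closed`, `is_manifold`, `euler_characteristic`,
#'   `n_vertices`, `n_edges`, `n_faces`, `n_flipped_faces` (faces whose
#'   orientation disagrees with the majority winding; `NA` if the mesh is not
#'   an edge-manifold).
#' @export
check_topology <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  nv <- nrow(mesh$vertices)
  # directed edges, 3 per face
  ea <- c(f[, 1L], f[, 2L], f[, 3L])
  eb <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(ea, eb)
  hi <- pmax(ea, eb)
  key <- (as.numeric(lo) - 1) * nv + as.numeric(hi)
  tab <- table(key)
  ne <- length(tab)
  is_manifold <- all(tab <= 2L)
  is_closed <- is_manifold && all(tab == 2L)
  euler <- nv - ne + nf
  n_flipped <- if (is_manifold) count_flipped_faces(f, nv) else NA_integer_
  list(is_closed = is_closed,
       is_manifold = is_manifold,
       euler_characteristic = euler,
       n_vertices = nv, n_edges = ne, n_faces = nf,
       n_flipped_faces = n_flipped)
}

# Count faces disagreeing with the majority orientation, by parity propagation
# over the face adjacency graph (shared undirected edges). Two adjacent faces
# are consistently wound iff they traverse the shared edge in opposite
# directions.
count_flipped_faces <- function(f, nv) {
  nf <- nrow(f)
  if (nf == 0L) return(0L)
  ea <- c(f[, 1L], f[, 2L], f[, 3L])
  eb <- c(f[, 2L], f[, 3L], f[, 1L])
  face_id <- rep.int(seq_len(nf), 3L)
  lo <- pmin(ea, eb)
  hi <- pmax(ea, eb)
  dir_fwd <- ea == lo                      # TRUE if traversed lo -> hi
  key <- (as.numeric(lo) - 1) * nv + as.numeric(hi)
  o <- order(key)
  key <- key[o]; face_id <- face_id[o]; dir_fwd <- dir_fwd[o]
  # pairs of consecutive equal keys are the two faces sharing that edge
  same <- which(key[-1L] == key[-length(key)])
  fa <- face_id[same]; fb <- face_id[same + 1L]
  # consistent winding iff opposite traversal directions
  consistent <- dir_fwd[same] != dir_fwd[same + 1L]
  parity <- rep(NA_integer_, nf)
  adj_from <- c(fa, fb)
  adj_to <- c(fb, fa)
  adj_ok <- c(consistent, consistent)
  ord <- order(adj_from)
  adj_from <- adj_from[ord]; adj_to <- adj_to[ord]; adj_ok <- adj_ok[ord]
  # CSR-style index: first/last adjacency entry per face
  counts <- tabulate(adj_from, nbins = nf)
  ends <- cumsum(counts)
  begins <- ends - counts + 1L
  n_flipped <- 0L
  stack <- integer(nf)
  comp <- integer(nf)
  for (seed in seq_len(nf)) {
    if (!is.na(parity[seed])) next
    parity[seed] <- 0L
    stack[1L] <- seed
    top <- 1L
    ncomp <- 0L
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      ncomp <- ncomp + 1L
      comp[ncomp] <- cur
      if (counts[cur] == 0L) next
      for (i in begins[cur]:ends[cur]) {
        nb <- adj_to[i]
        if (is.na(parity[nb])) {
          parity[nb] <- if (adj_ok[i]) parity[cur] else 1L - parity[cur]
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
    n1 <- sum(parity[comp[seq_len(ncomp)]] == 1L)
    n_flipped <- n_flipped + min(n1, ncomp - n1)
  }
  n_flipped
}

#' 3-D intensity volume with voxel-to-world affine
#'
#' The registration target (an EPI- or FLASH-like image). The affine maps
#' 0-based voxel indices `(i, j, k, 1)` to world millimetres (NIfTI
#' convention); all registration math runs in world mm.
#'
#' @param data 3-D numeric array of intensities.
#' @param affine 4 x 4 voxel-index-to-world matrix, last row `(0,0,0,1)`.
#' @return An object of class `mri_volume` with elements `data`, `affine` and
#'   derived `voxel_size` (mm per axis).
#' @export
mri_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4 x 4")
  if (any(abs(affine[4L, ] - c(0, 0, 0, 1)) > 1e-12))
    stop("affine last row must be (0, 0, 0, 1)")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("affine is singular")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(data = data, affine = affine, voxel_size = vs),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("mri_volume: %s voxels, voxel size %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' World millimetres to continuous voxel coordinates
#'
#' @param volume an [mri_volume()].
#' @param points n x 3 matrix of world-mm positions.
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(volume, points) {
  points <- rbind_points(points)
  inv <- solve(volume$affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4L])
}

#' Voxel coordinates to world millimetres
#'
#' @inheritParams world_to_voxel
#' @param voxels n x 3 matrix of 0-based voxel coordinates.
#' @return n x 3 matrix of world-mm positions.
#' @export
voxel_to_world <- function(volume, voxels) {
  voxels <- rbind_points(voxels)
  t(volume$affine[1:3, 1:3] %*% t(voxels) + volume$affine[1:3, 4L])
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  as.matrix(points)
}

#' Trilinear intensity sampling at world positions
#'
#' Samples outside the grid return `fill` (default 0). Trilinear interpolation
#' is used at non-integer voxel coordinates; it is the minimal smooth scheme
#' the derivative-free cost optimisation needs.
#'
#' @param volume an [mri_volume()].
#' @param points n x 3 world-mm positions.
#' @param fill value returned for samples outside the grid.
#' @return numeric vector of n intensities.
#' @export
sample_volume <- function(volume, points, fill = 0) {
  vc <- world_to_voxel(volume, points)
  d <- dim(volume$data)
  x <- vc[, 1L]; y <- vc[, 2L]; z <- vc[, 3L]
  inside <- x >= 0 & x <= d[1L] - 1L & y >= 0 & y <= d[2L] - 1L &
    z >= 0 & z <= d[3L] - 1L
  out <- rep(fill, nrow(vc))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1L] - 2L); fx <- x - x0
  y0 <- pmin(floor(y), d[2L] - 2L); fy <- y - y0
  z0 <- pmin(floor(z), d[3L] - 2L); fz <- z - z0
  nx <- d[1L]; nxy <- d[1L] * d[2L]
  base <- x0 + y0 * nx + z0 * nxy + 1
  v <- volume$data
  c000 <- v[base];             c100 <- v[base + 1]
  c010 <- v[base + nx];        c110 <- v[base + nx + 1]
  c001 <- v[base + nxy];       c101 <- v[base + nxy + 1]
  c011 <- v[base + nx + nxy];  c111 <- v[base + nx + nxy + 1]
  w00 <- c000 * (1 - fx) + c100 * fx
  w10 <- c010 * (1 - fx) + c110 * fx
  w01 <- c001 * (1 - fx) + c101 * fx
  w11 <- c011 * (1 - fx) + c111 * fx
  out[inside] <- (w00 * (1 - fy) + w10 * fy) * (1 - fz) +
    (w01 * (1 - fy) + w11 * fy) * fz
  out
}

#' Homogeneous affine transform constructors
#'
#' 4 x 4 homogeneous transforms acting on world-mm column vectors: output of
#' each local boundary fit and of each tetrahedron solve.
#'
#' @param matrix a 4 x 4 matrix with last row `(0,0,0,1)`.
#' @return validated 4 x 4 matrix.
#' @export
affine_transform <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L))) stop("affine must be 4 x 4")
  if (any(abs(matrix[4L, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("affine last row must be (0, 0, 0, 1)")
  if (!is.finite(det(matrix)) || abs(det(matrix)) < .Machine$double.eps * 64)
    stop("affine is singular")
  matrix[4L, ] <- c(0, 0, 0, 1)
  matrix
}

#' @rdname affine_transform
#' @export
affine_identity <- function() diag(4)

#' @rdname affine_transform
#' @param offset length-3 translation (mm).
#' @export
affine_translation <- function(offset) {
  m <- diag(4)
  m[1:3, 4L] <- offset
  m
}

#' Apply a homogeneous affine to points
#'
#' @param transform 4 x 4 affine.
#' @param points n x 3 matrix (world mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_affine <- function(transform, points) {
  points <- rbind_points(points)
  t(transform[1:3, 1:3] %*% t(points) + transform[1:3, 4L])
}
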