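#' Recursive cuboid lattice
#'
#' Builds the hierarchy of cuboid neighbourhoods used by the recursion: at
#' depth `d` the bounding box is divided into `2^d` equal cuboids per axis
#' (`8^d` in total), whose corners form a shared `(2^d + 1)^3` control-point
#' grid. Corner nodes shared between adjacent cuboids have identical ids,
#' which is what guarantees continuity of the assembled deformation.
#'
#' @param bounding_box 2 x 3 matrix (row 1 minima, row 2 maxima, mm).
#' @param max_depth deepest level to build (>= 0).
#' @return object of class `rbr_lattice`: list with `box` and `levels`, where
#'   `levels[[d + 1]]` is the [lattice_level()] at depth `d`.
#' @export
build_lattice <- function(bounding_box, max_depth) {
  bounding_box <- as.matrix(bounding_box)
  if (any(bounding_box[2L, ] <= bounding_box[1L, ]))
    stop("bounding box is empty")
  if (max_depth < 0) stop("max_depth must be >= 0")
  levels <- lapply(0:max_depth, function(d) lattice_level(bounding_box, d))
  structure(list(box = bounding_box, levels = levels), class = "rbr_lattice")
}

#' Single depth level of the cuboid lattice
#'
#' @inheritParams build_lattice
#' @param depth level (0 = whole box).
#' @return object of class `lattice_level`: `depth`, `origin`, `cell` (cuboid
#'   edge lengths, mm), `n` (cuboids per axis), `node_positions`
#'   (`(n+1)^3 x 3`, node id = row), `cuboid_corners` (`n^3 x 8` node ids).
#' @export
lattice_level <- function(bounding_box, depth) {
  n <- 2L^depth
  origin <- bounding_box[1L, ]
  cell <- (bounding_box[2L, ] - bounding_box[1L, ]) / n
  m <- n + 1L
  g <- 0:(m - 1L)
  node_positions <- cbind(
    origin[1L] + rep(g, times = m * m) * cell[1L],
    origin[2L] + rep(rep(g, each = m), times = m) * cell[2L],
    origin[3L] + rep(g, each = m * m) * cell[3L])
  ci <- 0:(n - 1L)
  i <- rep(ci, times = n * n)
  j <- rep(rep(ci, each = n), times = n)
  k <- rep(ci, each = n * n)
  corner <- function(cx, cy, cz) {
    as.integer((i + cx) + (j + cy) * m + (k + cz) * m * m + 1L)
  }
  # corner order: index c in 1..8 has offsets cx = (c-1) %% 2,
  # cy = ((c-1) %/% 2) %% 2, cz = (c-1) %/% 4
  cuboid_corners <- cbind(
    corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(0L, 1L, 0L),
    corner(1L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
    corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  structure(list(depth = depth, origin = origin, cell = cell, n = n,
                 node_positions = node_positions,
                 cuboid_corners = cuboid_corners),
            class = "lattice_level")
}

#' @export
print.rbr_lattice <- function(x, ...) {
  cat(sprintf("rbr_lattice: depths 0..%d\n", length(x$levels) - 1L))
  for (lv in x$levels)
    cat(sprintf("  depth %d: %d cuboids (%s mm), %d control points\n",
                lv$depth, lv$n^3L,
                paste(signif(lv$cell, 3), collapse = " x "),
                nrow(lv$node_positions)))
  invisible(x)
}

#' Cuboid bounds at a level
#'
#' @param level a [lattice_level()].
#' @param cuboid_id linear cuboid index (1-based).
#' @return 2 x 3 matrix of min/max corners (mm).
#' @export
cuboid_bounds <- function(level, cuboid_id) {
  n <- level$n
  c0 <- cuboid_id - 1L
  ijk <- c(c0 %% n, (c0 %/% n) %% n, c0 %/% (n * n))
  lo <- level$origin + ijk * level$cell
  rbind(min = lo, max = lo + level$cell)
}

#' Assign mesh vertices to cuboids (half-open rule)
#'
#' Each vertex belongs to exactly one cuboid per depth. Cuboids are half-open:
#' a vertex exactly on an internal split plane belongs to the higher-index
#' cuboid; the upper boundary is closed only on the box's max faces.
#'
#' @param mesh a [surface_mesh()] (or an n x 3 position matrix).
#' @param level a [lattice_level()].
#' @return integer vector of linear cuboid ids (1-based), one per vertex.
#' @export
partition_vertices <- function(mesh, level) {
  pos <- if (inherits(mesh, "surface_mesh")) mesh$vertices else rbind_points(mesh)
  n <- level$n
  rel <- sweep(pos, 2L, level$origin)
  tol <- 1e-9 * max(level$cell) * n
  if (any(rel < -tol) || any(sweep(rel, 2L, level$cell * n) > tol))
    stop("vertex outside the lattice bounding box; build the box from the mesh")
  ijk <- floor(sweep(rel, 2L, level$cell, "/"))
  ijk <- pmin(pmax(ijk, 0L), n - 1L)   # close the box's max faces
  as.integer(ijk[, 1L] + ijk[, 2L] * n + ijk[, 3L] * n * n + 1L)
}

#' Displacement vectors a transform induces at cuboid corners
#'
#' For each corner position `p` of the neighbourhood, the vector `T p - p`.
#'
#' @param transform 4 x 4 affine.
#' @param corner_positions 8 x 3 matrix of corner positions (mm).
#' @return 8 x 3 matrix of displacement vectors (mm).
#' @export
corner_displacements <- function(transform, corner_positions) {
  apply_affine(transform, corner_positions) - corner_positions
}

#' Control-point displacement accumulator
#'
#' Per lattice node, a list of candidate displacement vectors contributed by
#' all adjacent neighbourhood fits (and zero vectors for skipped or
#' non-converged regions, so the node median sees the "no change" vote).
#' Implemented as an environment so pushes do not copy.
#'
#' @param level a [lattice_level()].
#' @return object of class `control_point_field`.
#' @export
control_point_field <- function(level) {
  e <- new.env(parent = emptyenv())
  e$level <- level
  e$n_nodes <- nrow(level$node_positions)
  e$node_chunks <- list()
  e$disp_chunks <- list()
  class(e) <- "control_point_field"
  e
}

#' @rdname control_point_field
#' @param field a `control_point_field`.
#' @param node_ids integer vector of node ids.
#' @param displacements matrix (length(node_ids) x 3) of candidate vectors.
#' @export
push_displacements <- function(field, node_ids, displacements) {
  k <- length(field$node_chunks) + 1L
  field$node_chunks[[k]] <- as.integer(node_ids)
  field$disp_chunks[[k]] <- rbind_points(displacements)
  invisible(field)
}

#' Componentwise median aggregation of control-point candidates
#'
#' The median over all candidate vectors accumulated at each node, taken
#' separately per component; robust to isolated misregistrations among the
#' adjacent neighbourhood fits.
#'
#' @param field a [control_point_field()] with at least one candidate per node.
#' @param missing `"error"` to require a candidate at every node, `"zero"` to
#'   resolve untouched nodes (nodes none of whose adjacent cuboids contains
#'   mesh vertices) to zero displacement.
#' @return `n_nodes x 3` matrix of resolved displacements (mm).
#' @export
aggregate_control_points <- function(field, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  nodes <- unlist(field$node_chunks, use.names = FALSE)
  if (length(nodes) == 0L) stop("no displacement candidates accumulated")
  disp <- do.call(rbind, field$disp_chunks)
  present <- tabulate(nodes, nbins = field$n_nodes)
  if (any(present == 0L) && missing == "error")
    stop(sum(present == 0L), " control point(s) received no candidate vector")
  out <- matrix(0, field$n_nodes, 3L)
  ord <- order(nodes)
  nodes <- nodes[ord]
  disp <- disp[ord, , drop = FALSE]
  ends <- cumsum(present)
  begins <- ends - present + 1L
  single <- present == 1L
  out[single, ] <- disp[begins[single], , drop = FALSE]
  for (id in which(present > 1L)) {
    rows <- begins[id]:ends[id]
    out[id, ] <- c(stats::median(disp[rows, 1L]),
                   stats::median(disp[rows, 2L]),
                   stats::median(disp[rows, 3L]))
  }
  out
}

#' Neighbour smoothing of resolved control-point displacements
#'
#' One synchronous update of `d <- alpha * d + (1 - alpha) * M(x)`, where
#' `M(x)` is the mean resolved displacement of the node's 6-connected lattice
#' neighbours (boundary nodes average over their existing neighbours). `alpha`
#' balances local matching (1) against global smoothness (0).
#'
#' @param displacements `n_nodes x 3` resolved displacements.
#' @param level the [lattice_level()] the nodes belong to.
#' @param alpha smoothing weight in `[0, 1]`.
#' @param iterations number of synchronous updates (default 1).
#' @return smoothed `n_nodes x 3` matrix.
#' @export
smooth_control_points <- function(displacements, level, alpha, iterations = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 1 || iterations < 1L) return(displacements)
  m <- level$n + 1L
  dims <- c(m, m, m)
  for (it in seq_len(iterations)) {
    smoothed <- displacements
    for (comp in 1:3) {
      a <- array(displacements[, comp], dims)
      s <- array(0, dims)
      cnt <- array(0, dims)
      if (m > 1L) {
        s[-1L, , ] <- s[-1L, , ] + a[-m, , ]; cnt[-1L, , ] <- cnt[-1L, , ] + 1
        s[-m, , ] <- s[-m, , ] + a[-1L, , ]; cnt[-m, , ] <- cnt[-m, , ] + 1
        s[, -1L, ] <- s[, -1L, ] + a[, -m, ]; cnt[, -1L, ] <- cnt[, -1L, ] + 1
        s[, -m, ] <- s[, -m, ] + a[, -1L, ]; cnt[, -m, ] <- cnt[, -m, ] + 1
        s[, , -1L] <- s[, , -1L] + a[, , -m]; cnt[, , -1L] <- cnt[, , -1L] + 1
        s[, , -m] <- s[, , -m] + a[, , -1L]; cnt[, , -m] <- cnt[, , -m] + 1
        smoothed[, comp] <- alpha * displacements[, comp] +
          (1 - alpha) * as.vector(s / cnt)
      }
    }
    displacements <- smoothed
  }
  displacements
}

# Kuhn subdivision: six tetrahedra sharing the main diagonal (local corners 1
# and 8). Rows: tetrahedron; columns: the 4 local corner indices (1..8, bit
# convention of lattice_level). Tet t corresponds to the coordinate ordering
# listed in TET_ORDERINGS (axes sorted by decreasing local coordinate).
TET_CORNERS <- rbind(
  c(1L, 2L, 4L, 8L),  # x >= y >= z
  c(1L, 2L, 6L, 8L),  # x >= z >  y
  c(1L, 3L, 4L, 8L),  # y >  x >= z
  c(1L, 3L, 7L, 8L),  # y >= z >  x
  c(1L, 5L, 6L, 8L),  # z >  x >= y
  c(1L, 5L, 7L, 8L))  # z >  y >  x

#' Six-tetrahedra subdivision of a cuboid
#'
#' The fixed, globally consistent Kuhn split: every cuboid is divided into six
#' tetrahedra sharing the main diagonal, so the induced triangulation of each
#' face agrees with the adjacent cuboid's and the assembled piecewise-affine
#' deformation is continuous across cells.
#'
#' @param bounds 2 x 3 matrix (min / max corners of the cuboid, mm).
#' @return list of 6 tetrahedra, each a list with `corners` (local corner
#'   indices in 1..8) and `rest` (4 x 3 corner positions).
#' @export
tetrahedralize <- function(bounds) {
  if (any(bounds[2L, ] <= bounds[1L, ])) stop("degenerate cuboid")
  cp <- corner_grid(bounds)
  lapply(seq_len(6L), function(t) {
    idx <- TET_CORNERS[t, ]
    list(corners = idx, rest = cp[idx, , drop = FALSE])
  })
}

# 8 x 3 corner positions of a cuboid in the local bit order
corner_grid <- function(bounds) {
  cx <- c(0, 1, 0, 1, 0, 1, 0, 1)
  cy <- c(0, 0, 1, 1, 0, 0, 1, 1)
  cz <- c(0, 0, 0, 0, 1, 1, 1, 1)
  cbind(bounds[1L, 1L] + cx * (bounds[2L, 1L] - bounds[1L, 1L]),
        bounds[1L, 2L] + cy * (bounds[2L, 2L] - bounds[1L, 2L]),
        bounds[1L, 3L] + cz * (bounds[2L, 3L] - bounds[1L, 3L]))
}

# Tetrahedron index (1..6) for local unit-cube coordinates (n x 3 matrix in
# [0,1]^3), matching TET_CORNERS. Deterministic tie-break: the orderings are
# tested with the >= / > pattern encoded in the comments above, which
# partitions ties consistently on both sides of a shared face.
locate_tetrahedron <- function(u) {
  x <- u[, 1L]; y <- u[, 2L]; z <- u[, 3L]
  out <- integer(nrow(u))
  out[x >= y & y >= z] <- 1L
  sel <- out == 0L & x >= z & z > y;  out[sel] <- 2L
  sel <- out == 0L & y > x & x >= z;  out[sel] <- 3L
  sel <- out == 0L & y >= z & z > x;  out[sel] <- 4L
  sel <- out == 0L & z > x & x >= y;  out[sel] <- 5L
  sel <- out == 0L;                   out[sel] <- 6L
  out
}

#' Exact affine for a displaced tetrahedron
#'
#' The unique 4 x 4 affine mapping the four rest corners onto their displaced
#' positions: the determined per-tetrahedron system that replaces the
#' overdetermined 8-corner cuboid fit and guarantees continuity across
#' adjacent tetrahedra.
#'
#' @param rest 4 x 3 matrix of rest corner positions (non-degenerate).
#' @param displaced 4 x 3 matrix of displaced corner positions.
#' @return 4 x 4 affine transform.
#' @export
solve_tetra_affine <- function(rest, displaced) {
  M <- rbind(t(rest), 1)
  if (abs(det(M)) < 1e-12 * max(abs(rest), 1)^3)
    stop("degenerate tetrahedron: singular system")
  D <- rbind(t(displaced), 1)
  T <- D %*% solve(M)
  T[4L, ] <- c(0, 0, 0, 1)
  T
}

#' Apply a resolved control-point field to a mesh
#'
#' Each vertex is located in its cuboid and containing tetrahedron and moved
#' by that tetrahedron's exact affine. Because adjacent tetrahedra share their
#' face corners (and corner nodes are stored once), the deformation is
#' globally continuous; faces are untouched. Vertices that fall marginally
#' outside the box for numerical reasons are snapped to the nearest cell with
#' a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param level a [lattice_level()] whose box contains the mesh.
#' @param displacements `n_nodes x 3` resolved node displacements (mm).
#' @return deformed [surface_mesh()] with attribute `jacobians`: the linear
#'   determinant of every tetrahedron affine that was applied (negative values
#'   flag local folds, i.e. topology risk).
#' @export
apply_deformation <- function(mesh, level, displacements) {
  pos <- mesh$vertices
  n <- level$n
  rel <- sweep(pos, 2L, level$origin)
  u_all <- sweep(rel, 2L, level$cell, "/")
  snap_tol <- 1e-6
  if (any(u_all < -snap_tol) || any(u_all > n + snap_tol))
    warning("vertices outside the lattice box snapped to the nearest cell")
  u_all <- pmin(pmax(u_all, 0), n)
  ijk <- pmin(pmax(floor(u_all), 0L), n - 1L)
  cub <- as.integer(ijk[, 1L] + ijk[, 2L] * n + ijk[, 3L] * n * n + 1L)
  u <- u_all - ijk
  tet <- locate_tetrahedron(u)
  key <- (cub - 1L) * 6L + tet
  groups <- split(seq_len(nrow(pos)), key)
  newpos <- pos
  jac <- numeric(length(groups))
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    k <- key[g[1L]]
    cid <- (k - 1L) %/% 6L + 1L
    tid <- (k - 1L) %% 6L + 1L
    node_ids <- level$cuboid_corners[cid, TET_CORNERS[tid, ]]
    rest <- level$node_positions[node_ids, , drop = FALSE]
    displ <- rest + displacements[node_ids, , drop = FALSE]
    T <- solve_tetra_affine(rest, displ)
    newpos[g, ] <- apply_affine(T, pos[g, , drop = FALSE])
    jac[gi] <- det(T[1:3, 1:3])
  }
  out <- surface_mesh(newpos, mesh$faces, validate = FALSE)
  attr(out, "jacobians") <- jac
  out
}
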