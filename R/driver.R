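#' Configuration for recursive boundary registration
#'
#' All tunables of the recursion. Defaults follow the reference analysis:
#' translation plus scale along the phase-encoding axis (y), smoothing weight
#' `alpha = 0.9` (strongly weighted towards local matching), minimum cuboid
#' edge of 4 voxels and minimum of 100 vertices per fitted region, with an
#' initialising whole-mesh linear boundary registration.
#'
#' @param dof a [dof_spec()]; the pivot is overridden per region with the
#'   vertex centroid.
#' @param alpha control-point smoothing weight in `[0, 1]`; 1 disables
#'   smoothing, lower values trade specificity for robustness.
#' @param min_voxel_size minimum cuboid edge, in voxels of the target volume;
#'   the recursion stops at the depth where any axis falls below it.
#' @param min_vertices minimum number of vertices for a region to be fitted;
#'   smaller regions keep the identity transform ("no change" vote).
#' @param max_depth optional hard cap on the depth (default: governed by
#'   `min_voxel_size` alone).
#' @param bbr a [bbr_params()].
#' @param seed integer recorded in logs/manifests; the pipeline itself is
#'   deterministic.
#' @param init_linear run a whole-mesh linear boundary registration first
#'   (recommended: the recursion corrects subtle non-linear residuals, not
#'   gross misalignment).
#' @param linear_dof `"rigid"` (6 degrees of freedom) or `"affine"`
#'   (9: translation, rotation and scale) for the initialisation.
#' @param smooth_iterations synchronous applications of the neighbour
#'   smoothing per depth.
#' @param bounded_fits constrain each local fit to a trust region
#'   (translations up to half the cuboid edge, rotations up to 0.3 rad, scale
#'   in `[2/3, 4/3]`), guarding the simplex search against degenerate local
#'   optima.
#' @param lattice_box `"volume"` (default) subdivides the target volume's
#'   world bounding box, so the 4-voxel stopping rule reflects the volume;
#'   `"mesh"` subdivides the current mesh's bounding box padded by
#'   `pad_voxels`, rebuilt at each depth.
#' @param pad_voxels padding of the `"mesh"` lattice bounding box, in voxels.
#' @param maxit,reltol Nelder--Mead iteration cap (default `200 * n_par`) and
#'   relative tolerance.
#' @param verbose print per-depth progress.
#' @return object of class `rbr_config`.
#' @export
rbr_config <- function(dof = dof_spec(translate = "y", scale = "y"),
                       alpha = 0.9,
                       min_voxel_size = 4,
                       min_vertices = 100,
                       max_depth = NULL,
                       bbr = bbr_params(),
                       seed = 1L,
                       init_linear = TRUE,
                       linear_dof = c("rigid", "affine"),
                       smooth_iterations = 1L,
                       bounded_fits = TRUE,
                       lattice_box = c("volume", "mesh"),
                       pad_voxels = 1,
                       maxit = NULL,
                       reltol = 1e-9,
                       verbose = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (min_vertices < 4) stop("min_vertices must be >= 4")
  if (min_voxel_size < 1) stop("min_voxel_size must be >= 1")
  structure(list(dof = dof, alpha = alpha, min_voxel_size = min_voxel_size,
                 min_vertices = min_vertices, max_depth = max_depth,
                 bbr = bbr, seed = as.integer(seed),
                 init_linear = init_linear,
                 linear_dof = match.arg(linear_dof),
                 smooth_iterations = smooth_iterations,
                 bounded_fits = isTRUE(bounded_fits),
                 lattice_box = match.arg(lattice_box),
                 pad_voxels = pad_voxels, maxit = maxit, reltol = reltol,
                 verbose = verbose),
            class = "rbr_config")
}

# params with per-vertex weights subset to a region
subset_params <- function(params, idx) {
  if (!is.null(params$weights)) params$weights <- params$weights[idx]
  params
}

#' Fit a neighbourhood and its six half-splits
#'
#' Fits the full vertex set of the neighbourhood plus the six subregions
#' obtained by halving it separately along x, y and z; repeating the
#' registration on subregions makes the corner-median aggregation robust to
#' individual misfits. Regions below `min_vertices` are omitted; the full
#' region below `min_vertices` yields no fits at all (the caller contributes
#' the identity vote instead). Optimizer failures never raise; they are
#' returned flagged non-converged with the identity transform.
#'
#' @param volume target [mri_volume()].
#' @param positions,normals vertex positions and outward normals of the
#'   neighbourhood's vertices (n x 3 each).
#' @param bounds 2 x 3 cuboid bounds (used to halve the vertex set).
#' @param cfg an [rbr_config()].
#' @return list of fits; each has `region` (one of `"full"`, `"x_lo"`,
#'   `"x_hi"`, ..., `"z_hi"`), plus the [fit_local_transform()] fields.
#' @export
fit_neighbourhood <- function(volume, positions, normals, bounds, cfg) {
  n <- nrow(positions)
  if (n < cfg$min_vertices) return(list())
  mid <- (bounds[1L, ] + bounds[2L, ]) / 2
  regions <- list(full = seq_len(n))
  ax_names <- c("x", "y", "z")
  for (a in 1:3) {
    lo <- which(positions[, a] < mid[a])
    hi <- which(positions[, a] >= mid[a])
    regions[[paste0(ax_names[a], "_lo")]] <- lo
    regions[[paste0(ax_names[a], "_hi")]] <- hi
  }
  fits <- list()
  bounds <- if (isTRUE(cfg$bounded_fits)) region_bounds(cfg$dof, bounds) else NULL
  for (rn in names(regions)) {
    idx <- regions[[rn]]
    if (length(idx) < cfg$min_vertices) next
    dof <- cfg$dof
    dof$pivot <- colMeans(positions[idx, , drop = FALSE])
    fit <- fit_local_transform(volume, positions[idx, , drop = FALSE],
                               normals[idx, , drop = FALSE],
                               dof = dof, params = subset_params(cfg$bbr, idx),
                               maxit = cfg$maxit, reltol = cfg$reltol,
                               bounds = bounds)
    fit$region <- rn
    fit$n_vertices <- length(idx)
    fits[[rn]] <- fit
  }
  fits
}

#' One depth level of the recursion
#'
#' Fits every cuboid at the given level on the current (already coarsely
#' deformed) mesh, accumulates corner displacement candidates (zero vectors
#' for skipped regions), takes the componentwise median per control point,
#' smooths with the 6-neighbour stencil, solves the per-tetrahedron affines
#' and deforms the mesh.
#'
#' @param volume target [mri_volume()].
#' @param mesh current [surface_mesh()].
#' @param level a [lattice_level()] whose box contains the mesh.
#' @param cfg an [rbr_config()].
#' @return list: `mesh` (deformed), `displacements` (resolved, smoothed node
#'   displacements), `log` (per-depth summary: regions fitted / skipped /
#'   non-converged, costs, mean |displacement|, negative-Jacobian count).
#' @export
depth_pass <- function(volume, mesh, level, cfg) {
  normals <- vertex_normals(mesh)
  cub <- partition_vertices(mesh, level)
  by_cuboid <- split(seq_len(nrow(mesh$vertices)), cub)
  field <- control_point_field(level)
  n_cuboids <- level$n^3L
  fitted_ids <- integer(0)
  n_fits <- 0L
  n_nonconv <- 0L
  cost_before <- numeric(0)
  cost_after <- numeric(0)
  for (cid_chr in names(by_cuboid)) {
    cid <- as.integer(cid_chr)
    vids <- by_cuboid[[cid_chr]]
    if (length(vids) < cfg$min_vertices) next
    bounds <- cuboid_bounds(level, cid)
    fits <- fit_neighbourhood(volume, mesh$vertices[vids, , drop = FALSE],
                              normals[vids, , drop = FALSE], bounds,
                              subset_cfg_weights(cfg, vids))
    if (length(fits) == 0L) next
    fitted_ids <- c(fitted_ids, cid)
    node_ids <- level$cuboid_corners[cid, ]
    corner_pos <- level$node_positions[node_ids, , drop = FALSE]
    for (fit in fits) {
      n_fits <- n_fits + 1L
      if (!fit$converged) n_nonconv <- n_nonconv + 1L
      cost_before <- c(cost_before, fit$cost_init)
      cost_after <- c(cost_after, fit$cost_final)
      push_displacements(field, node_ids,
                         corner_displacements(fit$transform, corner_pos))
    }
  }
  # identity vote: cuboids that contain vertices but were not fitted (below
  # min_vertices, or with no fittable region) keep the identity transform and
  # vote zero displacement at their corners. Cuboids without any vertex are
  # not part of the mesh partition and do not vote; nodes untouched by any
  # region resolve to zero below.
  occupied <- as.integer(names(by_cuboid))
  skipped <- setdiff(occupied, fitted_ids)
  if (length(skipped)) {
    ids <- unique(as.vector(level$cuboid_corners[skipped, , drop = FALSE]))
    push_displacements(field, ids, matrix(0, length(ids), 3L))
  }
  resolved <- aggregate_control_points(field, missing = "zero")
  resolved <- smooth_control_points(resolved, level, cfg$alpha,
                                    cfg$smooth_iterations)
  newmesh <- apply_deformation(mesh, level, resolved)
  jac <- attr(newmesh, "jacobians")
  log <- list(depth = level$depth,
              n_cuboids = n_cuboids,
              n_cuboids_fitted = length(fitted_ids),
              n_region_fits = n_fits,
              n_non_converged = n_nonconv,
              mean_cost_before = if (n_fits) mean(cost_before) else NA_real_,
              mean_cost_after = if (n_fits) mean(cost_after) else NA_real_,
              mean_abs_displacement = mean(sqrt(rowSums(resolved^2))),
              n_negative_jacobian = sum(jac < 0),
              n_positive_jacobian = sum(jac > 0))
  list(mesh = newmesh, displacements = resolved, log = log)
}

# Trust region for a local fit: translations up to half the cuboid edge,
# rotations up to 0.3 rad, scale within [2/3, 4/3]. Keeps the derivative-free
# search away from degenerate transforms (cf. the recommendation to bound the
# descent when the landscape is rough).
region_bounds <- function(dof, cuboid_bounds) {
  edge <- cuboid_bounds[2L, ] - cuboid_bounds[1L, ]
  lo <- c(-0.5 * edge, rep(-0.3, 3), rep(-1 / 3, 3))
  hi <- c(0.5 * edge, rep(0.3, 3), rep(1 / 3, 3))
  rbind(lo[which(dof$mask)], hi[which(dof$mask)])
}

subset_cfg_weights <- function(cfg, idx) {
  if (!is.null(cfg$bbr$weights)) cfg$bbr$weights <- cfg$bbr$weights[idx]
  cfg
}

#' Recursive boundary registration
#'
#' Registers a grey--white boundary mesh to a distorted volume by recursively
#' applying boundary-based registration to an octree of cuboid neighbourhoods,
#' from the whole mesh (depth 0) down to cuboids of `min_voxel_size` voxels.
#' An optional whole-mesh linear boundary registration initialises the
#' recursion. The mesh is deformed through a shared control-point lattice
#' (median aggregation, neighbour smoothing, per-tetrahedron affines), so the
#' result is continuous and, for positive local Jacobians, topology
#' preserving. Only vertex positions change; the face array is returned
#' untouched.
#'
#' @param volume target [mri_volume()]; its bounding box must intersect the
#'   mesh's.
#' @param mesh a [surface_mesh()] (a topological sphere).
#' @param cfg an [rbr_config()].
#' @return object of class `rbr_result`: `mesh` (registered), `init_transform`
#'   (4 x 4 of the linear initialisation, identity if disabled), `fields`
#'   (per-depth resolved node displacements with their lattice levels), `log`
#'   (per-depth summaries plus the linear stage), `config`.
#' @export
rbr <- function(volume, mesh, cfg = rbr_config()) {
  check_overlap(volume, mesh)
  logs <- list()
  init_transform <- affine_identity()
  if (isTRUE(cfg$init_linear)) {
    ax <- c("x", "y", "z")
    dof <- if (cfg$linear_dof == "rigid") {
      dof_spec(translate = ax, rotate = ax, scale = character(0))
    } else {
      dof_spec(translate = ax, rotate = ax, scale = ax)
    }
    dof$pivot <- colMeans(mesh$vertices)
    fit <- fit_local_transform(volume, mesh$vertices, vertex_normals(mesh),
                               dof = dof, params = cfg$bbr,
                               maxit = cfg$maxit, reltol = cfg$reltol)
    init_transform <- fit$transform
    mesh <- surface_mesh(apply_affine(fit$transform, mesh$vertices),
                         mesh$faces, validate = FALSE)
    logs$linear <- list(converged = fit$converged,
                        cost_before = fit$cost_init,
                        cost_after = fit$cost_final,
                        par = fit$par)
    if (cfg$verbose)
      message(sprintf("linear init: cost %.4f -> %.4f",
                      fit$cost_init, fit$cost_final))
  }
  fields <- list()
  depth_logs <- list()
  d <- 0L
  repeat {
    if (!is.null(cfg$max_depth) && d > cfg$max_depth) break
    box <- if (cfg$lattice_box == "volume") volume_box(volume)
           else padded_box(mesh, volume, cfg$pad_voxels)
    cell <- (box[2L, ] - box[1L, ]) / 2^d
    if (any(cell / volume$voxel_size < cfg$min_voxel_size)) break
    level <- lattice_level(box, d)
    pass <- depth_pass(volume, mesh, level, cfg)
    mesh <- pass$mesh
    fields[[d + 1L]] <- list(level = level, displacements = pass$displacements)
    depth_logs[[d + 1L]] <- pass$log
    if (cfg$verbose)
      message(sprintf(
        "depth %d: %d/%d cuboids fitted, %d fits (%d non-converged), mean |d| %.3f mm",
        d, pass$log$n_cuboids_fitted, pass$log$n_cuboids,
        pass$log$n_region_fits, pass$log$n_non_converged,
        pass$log$mean_abs_displacement))
    d <- d + 1L
    if (d > 14L) break  # safety: 8^14 cells can never be intended
  }
  logs$depths <- depth_logs
  structure(list(mesh = mesh, init_transform = init_transform,
                 fields = fields, log = logs, config = cfg),
            class = "rbr_result")
}

padded_box <- function(mesh, volume, pad_voxels) {
  bb <- mesh_bounding_box(mesh)
  pad <- pad_voxels * volume$voxel_size
  rbind(bb[1L, ] - pad, bb[2L, ] + pad)
}

# world-space bounding box of the volume grid (voxel centres padded by half a
# voxel on each side)
volume_box <- function(volume) {
  d <- dim(volume$data)
  corners <- as.matrix(expand.grid(c(-0.5, d[1L] - 0.5), c(-0.5, d[2L] - 0.5),
                                   c(-0.5, d[3L] - 0.5)))
  wc <- voxel_to_world(volume, corners)
  rbind(apply(wc, 2L, min), apply(wc, 2L, max))
}

check_overlap <- function(volume, mesh) {
  d <- dim(volume$data)
  corners <- as.matrix(expand.grid(c(0, d[1L] - 1), c(0, d[2L] - 1),
                                   c(0, d[3L] - 1)))
  wc <- voxel_to_world(volume, corners)
  vol_lo <- apply(wc, 2L, min)
  vol_hi <- apply(wc, 2L, max)
  bb <- mesh_bounding_box(mesh)
  if (any(bb[1L, ] > vol_hi) || any(bb[2L, ] < vol_lo))
    stop("mesh and volume bounding boxes do not overlap")
  invisible(TRUE)
}

#' @export
print.rbr_result <- function(x, ...) {
  cat("rbr_result\n")
  if (!is.null(x$log$linear))
    cat(sprintf("  linear init: cost %.4f -> %.4f\n",
                x$log$linear$cost_before, x$log$linear$cost_after))
  for (l in x$log$depths)
    cat(sprintf(
      "  depth %d: %d/%d cuboids fitted, mean |d| = %.3f mm, neg. Jacobians: %d\n",
      l$depth, l$n_cuboids_fitted, l$n_cuboids,
      l$mean_abs_displacement, l$n_negative_jacobian))
  cat(sprintf("  final mesh: %d vertices\n", nrow(x$mesh$vertices)))
  invisible(x)
}
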