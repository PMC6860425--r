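# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto the sphere; the base
#' closed, consistently wound triangulation used by the phantom generator.
#' Subdivision level `k` gives `10 * 4^k + 2` vertices.
#'
#' @param subdivisions number of 1-to-4 face subdivisions (>= 0).
#' @param radius sphere radius (mm).
#' @return a [surface_mesh()] with outward winding.
#' @export
icosphere <- function(subdivisions = 0L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    lo <- pmin(e[, 1L], e[, 2L])
    hi <- pmax(e[, 1L], e[, 2L])
    key <- (as.numeric(lo) - 1) * nrow(v) + hi
    ukey <- unique(key)
    mid_id <- match(key, ukey) + nrow(v)
    first <- match(ukey, key)
    mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1L], m12, m31),
               cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m31, m23),
               cbind(m12, m23, m31))
  }
  mesh <- surface_mesh(v * radius, f)
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Specification of a cortical-like phantom
#'
#' A gyrified sphere standing in for the grey--white boundary, plus a volume
#' rendered from it with distinct white / grey / CSF intensities. The boundary
#' radius along unit direction `u` is
#' `r(u) = radius + amplitude * (sin(f ux) + sin(f uy) + sin(f uz)) / sqrt(3)`
#' (smooth, closed, star-shaped: it cannot self-intersect while
#' `amplitude * sqrt(3) < radius`). Intensities follow an analytic
#' partial-volume profile of width `boundary_blur` across each tissue
#' interface, emulating the scanner point-spread; `boundary_blur = 0` renders
#' a hard 3-valued classification.
#'
#' Defaults give several folds per registration neighbourhood at the middle
#' lattice depths, as on real cortex, so that within any fitted region the
#' outward normals are tilted both towards and away from the distortion axis.
#' Grey matter is thick enough that the outer boundary sample is not
#' influenced by the grey/CSF edge, and the polarity is T2*-like (grey
#' brighter than white).
#'
#' @param radius base sphere radius, mm.
#' @param gyr_amplitude radial fold amplitude, mm.
#' @param gyr_frequency angular frequency `f` of the folds (dimensionless).
#' @param subdivisions icosphere subdivision level of the mesh.
#' @param intensities named vector: `white`, `grey`, `csf` mean intensities.
#' @param grey_thickness radial grey-matter thickness, mm.
#' @param boundary_blur partial-volume (point-spread) width, mm.
#' @param noise_sd additive Gaussian noise SD (0 = noiseless).
#' @param voxel_size isotropic voxel size, mm.
#' @param margin world-space padding of the volume beyond the pial surface, mm.
#' @param seed RNG seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(radius = 25, gyr_amplitude = 1.5, gyr_frequency = 20,
                         subdivisions = 6L,
                         intensities = c(white = 50, grey = 150, csf = 80),
                         grey_thickness = 4.5, boundary_blur = 0.5,
                         noise_sd = 0, voxel_size = 0.9, margin = 6,
                         seed = 1L) {
  if (!(radius > grey_thickness && grey_thickness > 0))
    stop("need radius > grey_thickness > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gyr_amplitude < 0) stop("gyr_amplitude must be >= 0")
  if (gyr_amplitude * sqrt(3) >= radius)
    stop("gyrification amplitude too large: surface would self-intersect")
  stopifnot(all(c("white", "grey", "csf") %in% names(intensities)))
  structure(list(radius = radius, gyr_amplitude = gyr_amplitude,
                 gyr_frequency = gyr_frequency,
                 subdivisions = as.integer(subdivisions),
                 intensities = intensities, grey_thickness = grey_thickness,
                 boundary_blur = boundary_blur, noise_sd = noise_sd,
                 voxel_size = voxel_size, margin = margin,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Radial fold profile as a function of unit directions (n x 3): superposition
# of three plane waves, RMS-normalised. Folds are present over the whole
# sphere (no quiet caps on the distortion axis), so every neighbourhood of a
# few fold wavelengths contains normals tilted both towards and away from any
# given axis - as on real cortex.
gyrification_profile <- function(u, spec) {
  (sin(spec$gyr_frequency * u[, 1L]) +
     sin(spec$gyr_frequency * u[, 2L]) +
     sin(spec$gyr_frequency * u[, 3L])) / sqrt(3)
}

#' Generate a phantom surface and rendered volume
#'
#' The mesh is the exact grey--white boundary of the rendered volume: white
#' mean inside it, grey mean in a radial shell of the stated thickness, CSF
#' mean beyond, partial-volume blended over `boundary_blur` and salted with
#' seeded Gaussian noise if `noise_sd > 0`.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `rbr_phantom`: `mesh` (a topological sphere),
#'   `volume` (an [mri_volume()] centred on the origin), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  mesh <- icosphere(spec$subdivisions, radius = 1)
  u <- mesh$vertices
  rb <- spec$radius + spec$gyr_amplitude * gyrification_profile(u, spec)
  mesh$vertices <- u * rb

  h <- spec$radius + sqrt(3) * spec$gyr_amplitude + spec$grey_thickness +
    spec$margin
  nvox <- ceiling(2 * h / spec$voxel_size) + 1L
  offset <- -(nvox - 1) / 2 * spec$voxel_size
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  affine[1:3, 4L] <- offset

  ax <- offset + (0:(nvox - 1L)) * spec$voxel_size
  px <- rep(ax, times = nvox * nvox)
  py <- rep(rep(ax, each = nvox), times = nvox)
  pz <- rep(ax, each = nvox * nvox)
  rho <- sqrt(px^2 + py^2 + pz^2)
  safe_rho <- pmax(rho, .Machine$double.eps)
  uvox <- cbind(px, py, pz) / safe_rho
  rbv <- spec$radius + spec$gyr_amplitude * gyrification_profile(uvox, spec)
  sdist <- rho - rbv   # signed radial distance to the grey-white boundary
  iw <- spec$intensities[["white"]]
  ig <- spec$intensities[["grey"]]
  ic <- spec$intensities[["csf"]]
  if (spec$boundary_blur > 0) {
    vals <- iw + (ig - iw) * stats::pnorm(sdist / spec$boundary_blur) +
      (ic - ig) * stats::pnorm((sdist - spec$grey_thickness) / spec$boundary_blur)
  } else {
    vals <- ifelse(sdist < 0, iw, ifelse(sdist < spec$grey_thickness, ig, ic))
  }
  vol <- mri_volume(array(vals, dim = rep(nvox, 3L)), affine)
  if (spec$noise_sd > 0) vol <- salt_volume(vol, spec$noise_sd, spec$seed)
  structure(list(mesh = mesh, volume = vol, spec = spec),
            class = "rbr_phantom")
}

#' Specification of a smooth synthetic displacement field
#'
#' Emulates a field-map-derived voxel displacement map (VDM): a smooth random
#' scalar displacement along one axis (the phase-encoding direction),
#' generated by trilinear interpolation of seeded Gaussian values on a coarse
#' control grid. An optional cubic-root taper compresses unrealistically large
#' displacements and pushes small ones away from zero, making the displacement
#' distribution bimodal about zero; the field is then rescaled so the mean
#' absolute displacement over the mesh vertices hits `target_mean_abs`.
#'
#' @param axis distortion axis, one of `"x"`, `"y"`, `"z"` (default y,
#'   anterior--posterior).
#' @param control_spacing control grid spacing, mm (default 35: field-map-derived
#'   distortion fields are heavily smoothed, varying over several centimetres).
#' @param amplitude raw scale (mm) of the Gaussian control values before
#'   taper/calibration.
#' @param taper apply the cubic-root taper.
#' @param target_mean_abs calibrated mean |displacement| over mesh vertices,
#'   mm (`NULL` to keep the raw amplitude). Default 2.56 mm, the magnitude of
#'   the gold-standard distortion experiment.
#' @param seed RNG seed of the control values.
#' @return object of class `distortion_spec`.
#' @export
distortion_spec <- function(axis = "y", control_spacing = 40, amplitude = 1,
                            taper = TRUE, target_mean_abs = 2.56,
                            seed = 2L) {
  if (!axis %in% c("x", "y", "z")) stop("axis must be x, y or z")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(axis = axis, control_spacing = control_spacing,
                 amplitude = amplitude, taper = taper,
                 target_mean_abs = target_mean_abs, seed = as.integer(seed)),
            class = "distortion_spec")
}

#' Generate a smooth displacement field (synthetic VDM)
#'
#' @param spec a [distortion_spec()].
#' @param volume the [mri_volume()] whose grid the field is sampled on.
#' @param mesh optional [surface_mesh()]; if given (recommended), the
#'   `target_mean_abs` calibration is computed over its vertices, otherwise
#'   over all voxels.
#' @return object of class `rbr_distortion`: `field` (an [mri_volume()] of
#'   scalar mm displacements on the volume's grid), `axis`, `spec`.
#' @export
make_distortion <- function(spec, volume, mesh = NULL) {
  d <- dim(volume$data)
  corners <- as.matrix(expand.grid(c(0, d[1L] - 1), c(0, d[2L] - 1),
                                   c(0, d[3L] - 1)))
  wc <- voxel_to_world(volume, corners)
  lo <- apply(wc, 2L, min) - spec$control_spacing
  hi <- apply(wc, 2L, max) + spec$control_spacing
  ncp <- ceiling((hi - lo) / spec$control_spacing) + 1L
  cp_affine <- diag(c(rep(spec$control_spacing, 3), 1))
  cp_affine[1:3, 4L] <- lo
  cp_vals <- with_seed(spec$seed,
                       stats::rnorm(prod(ncp), sd = spec$amplitude))
  control <- mri_volume(array(cp_vals, dim = ncp), cp_affine)

  # field values at the target volume's voxel centres
  idx <- cbind(rep(0:(d[1L] - 1L), times = d[2L] * d[3L]),
               rep(rep(0:(d[2L] - 1L), each = d[1L]), times = d[3L]),
               rep(0:(d[3L] - 1L), each = d[1L] * d[2L]))
  w <- sample_volume(control, voxel_to_world(volume, idx))
  if (isTRUE(spec$taper)) w <- sign(w) * abs(w)^(1 / 3)
  field <- mri_volume(array(w, dim = d), volume$affine)
  if (!is.null(spec$target_mean_abs)) {
    ref <- if (is.null(mesh)) abs(w) else
      abs(sample_volume(field, mesh$vertices))
    m <- mean(ref)
    if (m == 0) stop("cannot calibrate an all-zero field")
    field$data <- field$data * (spec$target_mean_abs / m)
  }
  structure(list(field = field, axis = spec$axis, spec = spec),
            class = "rbr_distortion")
}

#' Displace a mesh along the distortion axis
#'
#' Each vertex is moved along the distortion axis by the field value
#' interpolated at its position; faces are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param distortion the result of [make_distortion()] (or an [mri_volume()] of scalar
#'   displacements, in which case `axis` is used).
#' @param axis axis override when a bare field volume is given.
#' @return displaced [surface_mesh()].
#' @export
distort_mesh <- function(mesh, distortion, axis = NULL) {
  if (inherits(distortion, "rbr_distortion")) {
    field <- distortion$field
    axis <- distortion$axis
  } else {
    field <- distortion
    if (is.null(axis)) stop("axis required for a bare field volume")
  }
  ai <- match(axis, c("x", "y", "z"))
  disp <- sample_volume(field, mesh$vertices)
  v <- mesh$vertices
  v[, ai] <- v[, ai] + disp
  surface_mesh(v, mesh$faces, validate = FALSE)
}

#' Add seeded Gaussian noise to a volume
#'
#' @param volume an [mri_volume()].
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return a new [mri_volume()]; the input is unchanged.
#' @export
salt_volume <- function(volume, noise_sd, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(volume)
  noise <- with_seed(seed, stats::rnorm(length(volume$data), sd = noise_sd))
  volume$data <- volume$data + array(noise, dim = dim(volume$data))
  volume
}
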