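FS_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read and write surface meshes
#'
#' Two formats are supported: the FreeSurfer binary triangle format
#' (big-endian, magic `0xFFFFFE`, float32 vertices, 0-based int32 faces) and a
#' plain-text format (`#`-comment lines, a `<n_vertices> <n_faces>` header
#' line, vertex rows, then 0-based face rows). Vertices round-trip to the
#' float32 precision of the FreeSurfer format and exactly in text; face
#' arrays round-trip exactly. Face indices are converted to R's 1-based
#' convention on read.
#'
#' @param path file path.
#' @param format `"auto"` (by magic bytes / content), `"freesurfer"` or
#'   `"text"`.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("surface file not found: ", path)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 3L)
    format <- if (length(head) == 3L && identical(head, FS_TRIANGLE_MAGIC))
      "freesurfer" else "text"
  }
  switch(format,
         freesurfer = read_fs_surface(path),
         text = read_text_surface(path))
}

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (!identical(magic, FS_TRIANGLE_MAGIC))
    stop(sprintf("bad magic at byte 0 of %s: not a FreeSurfer triangle file",
                 path))
  # comment ends with "\n\n"
  comment <- raw(0)
  prev_nl <- FALSE
  offset <- 3L
  repeat {
    b <- readBin(con, "raw", n = 1L)
    offset <- offset + 1L
    if (length(b) == 0L)
      stop(sprintf("truncated header at byte %d of %s", offset, path))
    if (b == as.raw(0x0a)) {
      if (prev_nl) break
      prev_nl <- TRUE
    } else {
      prev_nl <- FALSE
    }
    comment <- c(comment, b)
    if (offset > 4096L)
      stop(sprintf("unterminated comment at byte %d of %s", offset, path))
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L))
    stop(sprintf("truncated counts at byte %d of %s", offset, path))
  nv <- counts[1L]; nf <- counts[2L]
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop("truncated vertex/face data in ", path)
  surface_mesh(matrix(v, ncol = 3L, byrow = TRUE),
               matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

read_text_surface <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty text surface file: ", path)
  counts <- suppressWarnings(as.integer(strsplit(lines[1L], "\\s+")[[1L]]))
  if (length(counts) != 2L || anyNA(counts))
    stop("text surface header must be '<n_vertices> <n_faces>': ", path)
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 1L + nv + nf) stop("truncated text surface: ", path)
  v <- matrix(scan(text = lines[2:(1L + nv)], quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- matrix(as.integer(scan(text = lines[(2L + nv):(1L + nv + nf)],
                              quiet = TRUE)),
              ncol = 3L, byrow = TRUE)
  surface_mesh(v, f + 1L)
}

#' @rdname read_surface
#' @param mesh a [surface_mesh()].
#' @param comment comment stored in the FreeSurfer header.
#' @export
write_surface <- function(mesh, path, format = c("freesurfer", "text"),
                          comment = "created by rbreg") {
  format <- match.arg(format)
  if (format == "freesurfer") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(FS_TRIANGLE_MAGIC, con)
    writeBin(c(charToRaw(comment), as.raw(c(0x0a, 0x0a))), con)
    writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4L,
             endian = "big")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
    writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  } else {
    lines <- c(sprintf("# %s", comment),
               sprintf("%d %d", nrow(mesh$vertices), nrow(mesh$faces)),
               apply(mesh$vertices, 1L, function(r)
                 paste(formatC(r, format = "g", digits = 17), collapse = " ")),
               apply(mesh$faces - 1L, 1L, paste, collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving the voxel-to-world affine (stored as
#' the sform) to float precision. Both plain `.nii` and gzipped `.nii.gz`
#' files are handled.
#'
#' @param path file path.
#' @return an [mri_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop("expected a 3-D volume, got dimensions ", paste(d, collapse = "x"))
    d <- d[1:3]
  }
  mri_volume(array(as.numeric(img), dim = d),
             structure(RNifti::xform(img), code = NULL, imagedim = NULL))
}

#' @rdname read_volume
#' @param volume an [mri_volume()] (or a 4-D displacement-field array wrapped
#'   in one, see [write_field()]).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a resolved control-point field
#'
#' Writes the per-depth resolved displacement field either as a 4-D NIfTI (3
#' vector components in the 4th dimension, sampled on the given volume's
#' grid by the piecewise-affine deformation) or as a plain-text control-point
#' table (one node per row: position and displacement).
#'
#' @param field one element of an [rbr()] result's `fields` list.
#' @param path output path (`.nii`/`.nii.gz` or `.txt` by extension).
#' @param volume reference [mri_volume()] (required for NIfTI output).
#' @return the path, invisibly.
#' @export
write_field <- function(field, path, volume = NULL) {
  if (grepl("\\.txt$", path)) {
    tab <- cbind(field$level$node_positions, field$displacements)
    colnames(tab) <- c("x", "y", "z", "dx", "dy", "dz")
    utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (is.null(volume)) stop("a reference volume is required for NIfTI output")
  d <- dim(volume$data)
  idx <- cbind(rep(0:(d[1L] - 1L), times = d[2L] * d[3L]),
               rep(rep(0:(d[2L] - 1L), each = d[1L]), times = d[3L]),
               rep(0:(d[3L] - 1L), each = d[1L] * d[2L]))
  pts <- voxel_to_world(volume, idx)
  lv <- field$level
  n <- lv$n
  rel <- sweep(pts, 2L, lv$origin)
  u <- sweep(rel, 2L, lv$cell * n, "/")
  inside <- rowSums(u >= 0 & u <= 1) == 3L
  out <- matrix(0, nrow(pts), 3L)
  if (any(inside)) {
    probe <- surface_mesh(pts[inside, , drop = FALSE],
                          matrix(integer(0), 0L, 3L), validate = FALSE)
    moved <- apply_deformation(probe, lv, field$displacements)
    out[inside, ] <- moved$vertices - pts[inside, , drop = FALSE]
  }
  img <- RNifti::asNifti(array(out, dim = c(d, 3L)))
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write registration configuration as YAML
#'
#' The configuration file is a flat key/value mapping mirroring
#' [rbr_config()] and [bbr_params()]: `dof_translate`, `dof_rotate`,
#' `dof_scale` (strings like `"y"` or `"xyz"`), `alpha`, `min_voxel_size`,
#' `min_vertices`, `max_depth`, `projection_distance`, `slope`, `offset`,
#' `contrast_sign`, `seed`, `init_linear`, `linear_dof`, `smooth_iterations`,
#' `pad_voxels`. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return an [rbr_config()].
#' @export
read_rbr_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  axes <- function(s) if (is.null(s) || !nzchar(s)) character(0) else
    strsplit(s, "")[[1L]]
  defaults <- rbr_config()
  dof <- dof_spec(
    translate = if (is.null(y$dof_translate)) "y" else axes(y$dof_translate),
    rotate = if (is.null(y$dof_rotate)) character(0) else axes(y$dof_rotate),
    scale = if (is.null(y$dof_scale)) "y" else axes(y$dof_scale))
  pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  bbr <- bbr_params(
    projection_distance = pick("projection_distance", 2),
    slope = pick("slope", 0.5),
    offset = pick("offset", 0),
    contrast_sign = pick("contrast_sign", 1))
  rbr_config(dof = dof,
             alpha = pick("alpha", defaults$alpha),
             min_voxel_size = pick("min_voxel_size", defaults$min_voxel_size),
             min_vertices = pick("min_vertices", defaults$min_vertices),
             max_depth = y$max_depth,
             bbr = bbr,
             seed = pick("seed", defaults$seed),
             init_linear = pick("init_linear", defaults$init_linear),
             linear_dof = pick("linear_dof", defaults$linear_dof),
             smooth_iterations = pick("smooth_iterations",
                                      defaults$smooth_iterations),
             pad_voxels = pick("pad_voxels", defaults$pad_voxels))
}

#' @rdname read_rbr_config
#' @param cfg an [rbr_config()].
#' @export
write_rbr_config <- function(cfg, path) {
  ax <- c("x", "y", "z")
  mask <- cfg$dof$mask
  y <- list(
    dof_translate = paste(ax[mask[1:3]], collapse = ""),
    dof_rotate = paste(ax[mask[4:6]], collapse = ""),
    dof_scale = paste(ax[mask[7:9]], collapse = ""),
    alpha = cfg$alpha,
    min_voxel_size = cfg$min_voxel_size,
    min_vertices = cfg$min_vertices,
    projection_distance = cfg$bbr$projection_distance,
    slope = cfg$bbr$slope,
    offset = cfg$bbr$offset,
    contrast_sign = cfg$bbr$contrast_sign,
    seed = cfg$seed,
    init_linear = cfg$init_linear,
    linear_dof = cfg$linear_dof,
    smooth_iterations = cfg$smooth_iterations,
    pad_voxels = cfg$pad_voxels)
  if (!is.null(cfg$max_depth)) y$max_depth <- cfg$max_depth
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run manifest
#'
#' A serialisable record sufficient to re-run a registration bit-identically:
#' configuration snapshot, input file hashes, seeds, per-depth summaries and
#' the package version.
#'
#' @param cfg an [rbr_config()].
#' @param inputs named character vector of input file paths (hashed).
#' @param result an [rbr()] result (optional; adds per-depth summaries).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(cfg, inputs = character(0), result = NULL) {
  ax <- c("x", "y", "z")
  mask <- cfg$dof$mask
  m <- list(
    software = list(package = "rbreg",
                    version = as.character(utils::packageVersion("rbreg"))),
    config = list(
      dof_translate = paste(ax[mask[1:3]], collapse = ""),
      dof_rotate = paste(ax[mask[4:6]], collapse = ""),
      dof_scale = paste(ax[mask[7:9]], collapse = ""),
      alpha = cfg$alpha, min_voxel_size = cfg$min_voxel_size,
      min_vertices = cfg$min_vertices,
      max_depth = cfg$max_depth,
      projection_distance = cfg$bbr$projection_distance,
      slope = cfg$bbr$slope, offset = cfg$bbr$offset,
      contrast_sign = cfg$bbr$contrast_sign,
      init_linear = cfg$init_linear, linear_dof = cfg$linear_dof,
      smooth_iterations = cfg$smooth_iterations,
      pad_voxels = cfg$pad_voxels),
    seed = cfg$seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  if (!is.null(result)) m$depths <- result$log$depths
  if (!is.null(result) && !is.null(result$log$linear))
    m$linear <- result$log$linear
  structure(m, class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
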