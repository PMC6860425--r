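#' Boundary-based registration sampling and cost parameters
#'
#' Contrast is sampled a fixed distance along the outward vertex normal on
#' each side of the grey--white boundary. The cost passes the percent contrast
#' through a saturating tanh non-linearity so that individual vertices with
#' very large (or pathological) contrast cannot dominate the fit.
#'
#' `slope` controls where the non-linearity saturates: a vertex contributes
#' appreciable gradient only while `slope * |Q - offset| / 2` is of order 1.
#' The reference default (0.5) is tuned to the 10--20 percent grey/white
#' contrast of in-vivo T2*-weighted images; for targets with much stronger
#' contrast a proportionally smaller slope keeps the cost sensitive (see the
#' methods vignette).
#'
#' @param projection_distance mm sampled along the normal on each side
#'   (default 2).
#' @param slope dimensionless saturation slope of the tanh non-linearity
#'   (default 0.5).
#' @param offset target percent contrast Q0 (default 0).
#' @param contrast_sign +1 if the outer (grey) sample is expected brighter
#'   than the inner (white) sample, as in T2*-weighted targets; -1 for
#'   T1-like targets.
#' @param weights optional per-vertex weights.
#' @return object of class `bbr_params`.
#' @export
bbr_params <- function(projection_distance = 2, slope = 0.5, offset = 0,
                       contrast_sign = 1, weights = NULL) {
  if (projection_distance <= 0) stop("projection_distance must be > 0")
  if (slope <= 0) stop("slope must be > 0")
  if (!contrast_sign %in% c(-1, 1)) stop("contrast_sign must be +1 or -1")
  structure(list(projection_distance = projection_distance, slope = slope,
                 offset = offset, contrast_sign = contrast_sign,
                 weights = weights),
            class = "bbr_params")
}

#' Degrees-of-freedom specification for a local affine fit
#'
#' Selects which of the nine parameters (translation, rotation, scale along
#' x/y/z) a local boundary fit may use, and the pivot about which rotation and
#' scaling act. EPI distortion is concentrated along the phase-encoding axis,
#' so the registration default is translation plus scale in y only.
#'
#' @param translate,rotate,scale character vectors drawn from
#'   `c("x","y","z")` naming enabled axes.
#' @param pivot world point (mm) about which rotation/scaling act. The driver
#'   overrides this with each fitted region's vertex centroid.
#' @return object of class `dof_spec`.
#' @export
dof_spec <- function(translate = "y", rotate = character(0), scale = "y",
                     pivot = c(0, 0, 0)) {
  ax <- c("x", "y", "z")
  bad <- setdiff(c(translate, rotate, scale), ax)
  if (length(bad)) stop("unknown axes: ", paste(bad, collapse = ", "))
  mask <- c(t = ax %in% translate, r = ax %in% rotate, s = ax %in% scale)
  if (!any(mask)) stop("at least one degree of freedom must be enabled")
  structure(list(mask = mask, pivot = as.numeric(pivot)), class = "dof_spec")
}

n_dof <- function(dof) sum(dof$mask)

# Parameter vector (enabled subset of t_xyz [mm], r_xyz [radians], s_xyz
# [scale - 1, so 0 is the identity]) -> 4x4 affine. Rotation order
# Rz %*% Ry %*% Rx; rotation and scale act about dof$pivot. Parameterising
# scale as a deviation keeps the Nelder-Mead initial simplex under the control
# of the parameter scales (optim's step is proportional to nonzero values).
dof_to_affine <- function(par, dof) {
  full <- numeric(9)
  full[which(dof$mask)] <- par
  tr <- full[1:3]; rot <- full[4:6]; sc <- 1 + full[7:9]
  R <- diag(3)
  if (any(rot != 0)) {
    cx <- cos(rot[1]); sx <- sin(rot[1])
    cy <- cos(rot[2]); sy <- sin(rot[2])
    cz <- cos(rot[3]); sz <- sin(rot[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
  }
  A <- R %*% diag(sc, 3L)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4L] <- tr + dof$pivot - A %*% dof$pivot
  m
}

dof_identity_par <- function(dof) numeric(n_dof(dof))

# Deterministic initial Nelder-Mead simplex: 0.5 mm steps for translations,
# 0.02 rad for rotations, 0.02 for scale deviations. optim() builds the
# simplex with steps of 0.1 * parscale around a zero start, hence the
# factor 10.
dof_parscale <- function(dof) {
  full <- 10 * c(rep(0.5, 3), rep(0.02, 3), rep(0.02, 3))
  full[which(dof$mask)]
}

#' Percent contrast across the boundary at each vertex
#'
#' For each vertex, intensity is sampled at `position - d * normal` (inner,
#' white side, `w`) and `position + d * normal` (outer, grey side, `g`), with
#' `d` the projection distance. The percent contrast is
#' `Q = 100 * (g - w) / (0.5 * (g + w))` (0 where `g + w = 0`), returned as
#' `contrast_sign * Q` so that a correctly placed boundary yields large
#' positive values regardless of the target's contrast polarity.
#'
#' @param volume an [mri_volume()].
#' @param positions n x 3 world-mm vertex positions.
#' @param normals n x 3 outward unit normals.
#' @param params a [bbr_params()].
#' @return numeric vector of n signed percent contrasts.
#' @export
sample_contrast <- function(volume, positions, normals, params = bbr_params()) {
  positions <- rbind_points(positions)
  normals <- rbind_points(normals)
  if (nrow(positions) != nrow(normals))
    stop("positions and normals must have the same length")
  d <- params$projection_distance
  w <- sample_volume(volume, positions - d * normals, fill = NA_real_)
  g <- sample_volume(volume, positions + d * normals, fill = NA_real_)
  if (all(is.na(w)) && all(is.na(g)))
    stop("degenerate sampling: all boundary samples fall outside the volume")
  w[is.na(w)] <- 0
  g[is.na(g)] <- 0
  s <- 0.5 * (g + w)
  q <- ifelse(s == 0, 0, 100 * (g - w) / s)
  params$contrast_sign * q
}

#' Boundary-based registration cost
#'
#' `cost = (1/N) * sum w_i * (1 + tanh(slope * (offset - Q_i) / 2))`, where
#' `Q_i` is the signed percent contrast from [sample_contrast()] (positive =
#' correct polarity). The cost lies in `[0, 2]` for unit weights, equals 1
#' when every `Q_i` equals the offset, and tends to 0 as the oriented contrast
#' grows; lower is better.
#'
#' @inheritParams sample_contrast
#' @return scalar cost.
#' @export
bbr_cost <- function(volume, positions, normals, params = bbr_params()) {
  q <- sample_contrast(volume, positions, normals, params)
  n <- length(q)
  if (n == 0L) stop("no vertices to compute cost over")
  w <- params$weights
  if (is.null(w)) w <- rep(1, n)
  sum(w * (1 + tanh(params$slope * (params$offset - q) / 2))) / n
}

#' Fit a constrained local affine by boundary contrast
#'
#' Minimises [bbr_cost()] of the transformed vertex positions over the enabled
#' degrees of freedom using a derivative-free Nelder--Mead simplex search
#' (the behaviour of MATLAB's `fminsearch`), with a deterministic initial
#' simplex derived from parameter scales. Normals are carried through the
#' linear part of the candidate transform (inverse-transpose, renormalised).
#'
#' If the search cannot improve on the initial cost (e.g. a contrast-free
#' region) the initial transform is returned unchanged and flagged
#' non-converged: this is the identity fallback the recursion relies on in
#' low-contrast regions.
#'
#' @inheritParams sample_contrast
#' @param dof a [dof_spec()].
#' @param init 4 x 4 initial affine (already applied conceptually; the result
#'   is composed with it).
#' @param maxit maximum Nelder--Mead iterations (default `200 * n_par`).
#' @param reltol relative convergence tolerance of the simplex search.
#' @param bounds optional 2-row matrix (lower/upper) over the enabled
#'   parameters (translations in mm, rotations in rad, scales as deviation
#'   from 1); candidate transforms outside the bounds are rejected. `NULL`
#'   leaves the search unconstrained.
#' @return list of class `bbr_fit`: `transform` (4 x 4, composed with `init`),
#'   `converged`, `cost_init`, `cost_final`, `par`.
#' @export
fit_local_transform <- function(volume, positions, normals, dof = dof_spec(),
                                params = bbr_params(), init = affine_identity(),
                                maxit = NULL, reltol = 1e-9, bounds = NULL) {
  positions <- rbind_points(positions)
  normals <- rbind_points(normals)
  if (nrow(positions) < 1L) stop("at least one vertex is required")
  p0 <- apply_affine(init, positions)
  n0 <- transform_normals(init, normals)
  npar <- n_dof(dof)
  if (is.null(maxit)) maxit <- 200L * npar

  objective <- function(par) {
    if (!is.null(bounds) &&
        (any(par < bounds[1L, ]) || any(par > bounds[2L, ])))
      return(4)  # out of the trust region: repels the simplex
    m <- dof_to_affine(par, dof)
    val <- tryCatch(
      bbr_cost(volume, apply_affine(m, p0), transform_normals(m, n0), params),
      error = function(e) NA_real_)
    if (!is.finite(val)) 4 else val  # above the [0,2] range: repels simplex
  }

  par_init <- dof_identity_par(dof)
  cost_init <- objective(par_init)
  non_converged <- function() {
    structure(list(transform = init, converged = FALSE,
                   cost_init = cost_init, cost_final = cost_init,
                   par = par_init),
              class = "bbr_fit")
  }
  if (cost_init >= 4) return(non_converged())

  res <- tryCatch(
    suppressWarnings(stats::optim(
      par_init, objective, method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = reltol,
                     parscale = dof_parscale(dof)))),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) ||
      res$value >= cost_init - 1e-12) {
    return(non_converged())
  }
  structure(list(transform = dof_to_affine(res$par, dof) %*% init,
                 converged = TRUE,
                 cost_init = cost_init, cost_final = res$value,
                 par = res$par),
            class = "bbr_fit")
}

# Normals transform with the inverse-transpose of the linear part,
# renormalised (exact for rigid motion; handles anisotropic scaling).
transform_normals <- function(transform, normals) {
  A <- transform[1:3, 1:3]
  if (identical(A, diag(3))) return(normals)
  n <- normals %*% solve(A)      # rows n_i %*% A^{-1} == (A^{-T} n)^T
  n / sqrt(rowSums(n^2))
}
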