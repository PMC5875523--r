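#' Rigid transform (translation + Euler rotation about a pivot)
#'
#' Maps a fixed-space point `x` to the moving-space point
#' `R (x - pivot) + pivot + translation`, where `R` is the rotation built
#' from Euler angles applied in x, y, z order. Used backward for
#' resampling: the moving image is sampled at the mapped point.
#'
#' @param translation Numeric length-3, mm.
#' @param rotation Numeric length-3, Euler angles in radians.
#' @param pivot Numeric length-3, rotation centre in world mm (typically
#'   the fixed image's world centre).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation = c(0, 0, 0),
                            pivot = c(0, 0, 0)) {
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 pivot = as.numeric(pivot)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, angles = (%s) deg\n",
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Apply a rigid transform to world-space points
#' @param transform A [rigid_transform()].
#' @param points Length-3 vector or n x 3 matrix of world mm points.
#' @return Points of the same shape, mapped into moving space.
#' @export
transform_point <- function(transform, points) {
  single <- is.null(dim(points))
  if (single) points <- matrix(points, ncol = 3L)
  r <- rotation_matrix(transform$rotation)
  out <- sweep(points, 2L, transform$pivot) %*% t(r)
  out <- sweep(out, 2L, transform$pivot + transform$translation, "+")
  if (single) drop(out) else out
}

volume_center <- function(vol) {
  vol$origin + (grid_dim(vol) - 1) * vol$spacing / 2
}

#' Resample a volume onto a reference grid under a rigid transform
#'
#' Equivalent to [warp()] with the constant-plus-rotation field induced by
#' the transform: each reference voxel centre is mapped into moving space
#' and the volume sampled there trilinearly.
#'
#' @param transform A [rigid_transform()].
#' @param vol The moving [scalar_volume()].
#' @param reference [scalar_volume()] supplying the output grid.
#' @return A [scalar_volume()] on the reference grid.
#' @export
apply_rigid <- function(transform, vol, reference) {
  pts <- transform_point(transform, grid_world(reference))
  vals <- sample_trilinear(vol, pts)
  scalar_volume(array(vals, grid_dim(reference)),
                reference$spacing, reference$origin)
}

#' Convert a rigid transform to a dense deformation field
#' @param transform A [rigid_transform()].
#' @param reference Grid for the field.
#' @return A [deformation_field()] with `d(x) = T(x) - x`.
#' @export
rigid_to_field <- function(transform, reference) {
  pts <- grid_world(reference)
  vec <- transform_point(transform, pts) - pts
  deformation_field(array(vec, c(grid_dim(reference), 3L)),
                    reference$spacing, reference$origin)
}

msd_cost <- function(par, fixed_pts, fixed_vals, moving, pivot, dof) {
  tr <- rigid_transform(par[1:3],
                        if (dof == 6L) par[4:6] else c(0, 0, 0),
                        pivot)
  pts <- transform_point(tr, fixed_pts)
  mean((sample_trilinear(moving, pts) - fixed_vals)^2)
}

#' Automatic rigid registration by multi-scale intensity matching
#'
#' Minimises the mean squared intensity difference between the fixed image
#' and the rigidly resampled moving image over a 3-level pyramid: a coarse
#' exhaustive search over translations, then Nelder-Mead refinement
#' (adding rotations when `dof = 6`) at each level. Both scans are assumed
#' to share a modality (non-contrast CT), which is what makes the MSD
#' metric appropriate.
#'
#' @param fixed,moving [scalar_volume()] objects that overlap in world space.
#' @param dof 3 (translation only) or 6 (translation + rotation).
#' @param search_mm Half-width of the coarse translation search (mm).
#' @param init Optional [rigid_transform()] seeding the search (e.g. a
#'   manual offset); skips the exhaustive stage.
#' @return A [rigid_transform()] with pivot at the fixed image centre.
#' @export
register_rigid <- function(fixed, moving, dof = c(3, 6), search_mm = 30,
                           init = NULL) {
  dof <- as.integer(dof[1])
  if (!dof %in% c(3L, 6L)) abort("`dof` must be 3 or 6.")
  flo <- fixed$origin; fhi <- fixed$origin + (grid_dim(fixed) - 1) * fixed$spacing
  mlo <- moving$origin; mhi <- moving$origin + (grid_dim(moving) - 1) * moving$spacing
  if (any(pmin(fhi, mhi) <= pmax(flo, mlo)))
    abort("fixed and moving volumes do not overlap in world space.")
  pivot <- volume_center(fixed)

  factors <- c(4L, 2L, 1L)
  factors <- factors[vapply(factors,
                            function(f) all(grid_dim(fixed) / f >= 4), TRUE)]
  if (length(factors) == 0L) factors <- 1L
  par <- c(if (is.null(init)) c(0, 0, 0) else init$translation,
           if (is.null(init)) c(0, 0, 0) else init$rotation)

  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- downsample(fixed, f)
    mv <- downsample(moving, f)
    fixed_pts <- grid_world(fx)
    fixed_vals <- as.numeric(fx$data)
    if (li == 1L && is.null(init)) {
      step <- max(fx$spacing)
      grid1 <- seq(-search_mm, search_mm, by = step)
      best <- c(0, 0, 0); best_cost <- Inf
      for (tz in grid1) for (ty in grid1) for (tx in grid1) {
        cost <- msd_cost(c(tx, ty, tz), fixed_pts, fixed_vals, mv, pivot, 3L)
        if (cost < best_cost) { best_cost <- cost; best <- c(tx, ty, tz) }
      }
      par[1:3] <- best
    }
    p0 <- if (dof == 6L) par else par[1:3]
    opt <- stats::optim(p0, msd_cost, fixed_pts = fixed_pts,
                        fixed_vals = fixed_vals, moving = mv, pivot = pivot,
                        dof = dof, method = "Nelder-Mead",
                        control = list(maxit = 400,
                                       reltol = 1e-8,
                                       parscale = c(rep(max(fx$spacing), 3),
                                                    rep(0.02, dof - 3L))))
    par <- c(opt$par, if (dof == 3L) par[4:6])
  }
  # never worse than identity on the full-resolution objective
  fixed_pts <- grid_world(fixed)
  fixed_vals <- as.numeric(fixed$data)
  if (msd_cost(c(par[1:3], par[4:6]), fixed_pts, fixed_vals, moving,
               pivot, 6L) >
      msd_cost(rep(0, 6), fixed_pts, fixed_vals, moving, pivot, 6L))
    par <- rep(0, 6)
  rigid_transform(par[1:3], par[4:6], pivot)
}

#' Write a rigid transform as JSON
#' @param transform A [rigid_transform()].
#' @param path Output path.
#' @export
write_rigid <- function(transform, path) {
  jsonlite::write_json(list(translation_mm = transform$translation,
                            rotation_rad = transform$rotation,
                            pivot_mm = transform$pivot),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path Path written by [write_rigid()].
#' @return A [rigid_transform()].
#' @export
read_rigid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$translation_mm, j$rotation_rad, j$pivot_mm)
}
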