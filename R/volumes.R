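#' Scalar image volume
#'
#' The basic image container: a 3-D intensity grid (HU for CT, SUV for PET)
#' with anisotropic voxel spacing and a world-space origin. The world
#' coordinate (mm) of 0-based voxel index `i` is `origin + i * spacing`,
#' with axes ordered (x, y, z) as in NIfTI RAS.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing Numeric length-3, mm per voxel, all positive.
#' @param origin Numeric length-3, world position (mm) of the centre of
#'   voxel (0, 0, 0).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    abort("`data` must be a 3-D array.", class = "thoraxreg_dim_error")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 positive finite values (mm).")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("`origin` must be 3 finite values (mm).")
  if (any(dim(data) < 2L))
    abort("volume must have at least 2 voxels per axis.")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Boolean region mask
#'
#' Same geometry contract as [scalar_volume()], but the grid is logical.
#' Used for fractional-SUVmax contours.
#'
#' @param data 3-D logical array.
#' @inheritParams scalar_volume
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- scalar_volume(array(as.logical(data), dim(data)), spacing, origin)
  class(v) <- c("region_mask", "scalar_volume")
  v
}

#' Dense deformation field
#'
#' Per-voxel 3-D displacement vectors in mm on a fixed-image grid, stored
#' backward: a fixed-grid point `x` samples the moving image at `x + d(x)`.
#'
#' @param vectors 4-D numeric array, dims `(nx, ny, nz, 3)`; last dimension
#'   is the (x, y, z) displacement component in mm.
#' @inheritParams scalar_volume
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    abort("`vectors` must be a 4-D array with 3 components in the last dim.")
  if (any(!is.finite(vectors)))
    abort("deformation vectors must be finite everywhere.")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    abort("`spacing` must be 3 positive values (mm).")
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "deformation_field")
}

#' Zero deformation field on the grid of a reference volume
#' @param reference A [scalar_volume()] supplying grid geometry.
#' @return A [deformation_field()] of all-zero displacements.
#' @export
zero_field <- function(reference) {
  d <- dim(reference$data)
  deformation_field(array(0, c(d, 3L)), reference$spacing, reference$origin)
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat(sprintf("<deformation_field> %s voxels, spacing (%s) mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", ")))
  cat(sprintf("  |d| mean %.3f mm, max %.3f mm\n", mean(mag), max(mag)))
  invisible(x)
}

#' Axis-aligned bounding box in world coordinates
#' @param lower,upper Numeric length-3 world corners (mm), `upper > lower`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(upper <= lower))
    abort("`upper` must exceed `lower` on every axis.")
  structure(list(lower = lower, upper = upper), class = "bounding_box")
}

grid_dim <- function(x) {
  if (inherits(x, "deformation_field")) dim(x$vectors)[1:3] else dim(x$data)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of every voxel centre
#' @return n-voxel x 3 matrix of world mm coordinates, fastest along x.
#' @noRd
grid_world <- function(x) {
  d <- grid_dim(x)
  cbind(
    rep(x$origin[1] + (seq_len(d[1]) - 1) * x$spacing[1], times = d[2] * d[3]),
    rep(rep(x$origin[2] + (seq_len(d[2]) - 1) * x$spacing[2], each = d[1]),
        times = d[3]),
    rep(x$origin[3] + (seq_len(d[3]) - 1) * x$spacing[3], each = d[1] * d[2])
  )
}

world_to_index <- function(x, pts) {
  sweep(sweep(pts, 2L, x$origin, "-"), 2L, x$spacing, "/")
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_geometry <- function(img) {
  aff <- RNifti::xform(img)
  if (max(abs(aff[1:3, 1:3] - diag(RNifti::pixdim(img)[1:3]))) > 1e-3)
    warn("NIfTI affine has rotation/shear; only spacing and origin are kept.")
  list(spacing = abs(diag(aff[1:3, 1:3, drop = FALSE])),
       origin = as.numeric(aff[1:3, 4]))
}

#' Read a scalar volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file with a 3-D image.
#' @return A [scalar_volume()]; spacing and origin come from the affine.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "thoraxreg_io_error")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    abort(sprintf("expected a 3-D image, got %d dims", length(dim(img))),
          class = "thoraxreg_dim_error")
  g <- nifti_geometry(img)
  scalar_volume(array(as.numeric(img), dim(img)), g$spacing, g$origin)
}

#' Read a deformation field from a 3-component NIfTI
#' @param path Path to a 4-D NIfTI whose 4th dimension holds the (x, y, z)
#'   displacement components in mm.
#' @return A [deformation_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "thoraxreg_io_error")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    abort("expected a 4-D NIfTI with 3 components",
          class = "thoraxreg_dim_error")
  g <- nifti_geometry(img)
  deformation_field(array(as.numeric(img), dim(img)), g$spacing, g$origin)
}

#' Write a volume, mask, or deformation field as NIfTI
#'
#' Masks are written as 0/1, fields as a 4-D image with the displacement
#' component in the last dimension (mm). Geometry goes into the qform/sform.
#'
#' @param vol A [scalar_volume()], [region_mask()], or [deformation_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "deformation_field")) vol$vectors
         else array(as.numeric(vol$data), dim(vol$data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L) c(vol$spacing, 1)
                         else vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# ---- Landmark CSV ----------------------------------------------------------

#' Read a landmark table
#'
#' Expects columns `name,x_mm,y_mm,z_mm`; an optional `near_tumor` logical
#' column is carried through when present.
#'
#' @param path CSV path.
#' @return A tibble with one row per landmark.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "thoraxreg_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    abort(sprintf("landmark CSV must have columns %s",
                  paste(need, collapse = ", ")))
  if (anyDuplicated(df$name))
    abort("landmark names must be unique within a scan.")
  as_tibble(df)
}

#' Write a landmark table as CSV
#' @param landmarks Tibble with `name,x_mm,y_mm,z_mm` (and optional extras).
#' @param path Output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Pair pre- and post-scan landmarks by name
#'
#' @param pre,post Landmark tibbles as returned by [read_landmarks()]; the
#'   `near_tumor` flag, if present on either table, is kept.
#' @return Tibble with columns `name`, `pre_x..pre_z`, `post_x..post_z`,
#'   `near_tumor`.
#' @export
pair_landmarks <- function(pre, post) {
  common <- intersect(pre$name, post$name)
  if (length(common) == 0L) abort("no landmark names shared between scans.")
  pre <- pre[match(common, pre$name), ]
  post <- post[match(common, post$name), ]
  near <- if (!is.null(pre$near_tumor)) as.logical(pre$near_tumor)
          else if (!is.null(post$near_tumor)) as.logical(post$near_tumor)
          else rep(FALSE, length(common))
  tibble(name = common,
         pre_x = pre$x_mm, pre_y = pre$y_mm, pre_z = pre$z_mm,
         post_x = post$x_mm, post_y = post$y_mm, post_z = post$z_mm,
         near_tumor = near)
}

# ---- Sampling, warping, smoothing ------------------------------------------

#' Trilinear interpolation at world-space points
#'
#' @param vol A [scalar_volume()].
#' @param points Numeric length-3 vector or n x 3 matrix of world mm points.
#' @param oob Out-of-bounds policy: `"clamp"` (nearest edge, the default) or
#'   `"constant"`.
#' @param fill Fill value for `oob = "constant"`.
#' @return Numeric vector of interpolated intensities.
#' @export
sample_trilinear <- function(vol, points, oob = c("clamp", "constant"),
                             fill = 0) {
  oob <- match.arg(oob)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  idx <- world_to_index(vol, points)
  cpp_trilinear(as.numeric(vol$data), dim(vol$data), idx,
                oob == "clamp", fill)
}

#' Sample a deformation field at world-space points
#' @return n x 3 matrix of displacement vectors (mm).
#' @noRd
sample_field <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  idx <- world_to_index(field, points)
  d <- dim(field$vectors)
  vapply(1:3, function(c3)
    cpp_trilinear(as.numeric(field$vectors[, , , c3]), d[1:3], idx,
                  TRUE, 0),
    numeric(nrow(points)))
}

#' Warp a moving image through a deformation field
#'
#' The output lives on the field's (fixed-image) grid: the voxel at
#' fixed-grid point `x` takes the value of the moving image at `x + d(x)`
#' (backward warping, trilinear interpolation, nearest-edge clamping).
#'
#' @param moving A [scalar_volume()].
#' @param field A [deformation_field()] on the desired output grid.
#' @return A [scalar_volume()] on the field's grid.
#' @export
warp <- function(moving, field) {
  pts <- grid_world(field) + matrix(field$vectors, ncol = 3L)
  vals <- sample_trilinear(moving, pts)
  scalar_volume(array(vals, grid_dim(field)), field$spacing, field$origin)
}

#' Gaussian smoothing of a volume or deformation field
#'
#' Separable Gaussian convolution with standard deviation given in mm and
#' converted to voxels per axis; vector fields are smoothed componentwise.
#'
#' @param x A [scalar_volume()] or [deformation_field()].
#' @param sigma Standard deviation in mm; scalar or length-3.
#' @return Object of the same class as `x`.
#' @export
gaussian_smooth <- function(x, sigma) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  UseMethod("gaussian_smooth")
}

#' @export
gaussian_smooth.scalar_volume <- function(x, sigma) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  x$data <- cpp_gaussian_blur(as.numeric(x$data), dim(x$data),
                              sigma / x$spacing)
  x
}

#' @export
gaussian_smooth.deformation_field <- function(x, sigma) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  d <- dim(x$vectors)
  for (c3 in 1:3)
    x$vectors[, , , c3] <- cpp_gaussian_blur(as.numeric(x$vectors[, , , c3]),
                                             d[1:3], sigma / x$spacing)
  x
}

#' Downsample a volume by an integer factor
#'
#' Gaussian anti-aliasing (sigma = 0.5 * factor * spacing) followed by
#' subsampling every `factor`-th voxel; spacing is multiplied by `factor`
#' and the origin is unchanged (voxel 0 is retained).
#'
#' @param vol A [scalar_volume()].
#' @param factor Positive integer decimation factor.
#' @return A [scalar_volume()] on the coarser grid.
#' @export
downsample <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) abort("`factor` must be >= 1.")
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  keep <- lapply(d, function(n) seq(1L, n, by = factor))
  if (any(lengths(keep) < 2L))
    abort("downsampling would leave fewer than 2 voxels on an axis",
          class = "thoraxreg_scale_skip")
  sm <- gaussian_smooth(vol, 0.5 * factor * vol$spacing)
  scalar_volume(sm$data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
                vol$spacing * factor, vol$origin)
}

#' Crop a volume to an expanded bounding box
#'
#' Returns the sub-volume covering `box` expanded by `margin` mm on all six
#' faces, clipped to the volume extent; the origin is updated so retained
#' voxels keep their world coordinates.
#'
#' @param vol A [scalar_volume()].
#' @param box A [bounding_box()] in world mm.
#' @param margin Isotropic expansion in mm (default 20, the registration
#'   VOI margin around the PTV box).
#' @return A [scalar_volume()].
#' @export
crop_voi <- function(vol, box, margin = 20) {
  d <- dim(vol$data)
  lo_w <- box$lower - margin
  hi_w <- box$upper + margin
  lo <- pmax(0L, pmin(d - 1L, floor((lo_w - vol$origin) / vol$spacing)))
  hi <- pmin(d - 1L, pmax(0L, ceiling((hi_w - vol$origin) / vol$spacing)))
  if (any(hi <= lo) ||
      any(hi_w < vol$origin) ||
      any(lo_w > vol$origin + (d - 1) * vol$spacing))
    abort("expanded box does not intersect the volume.")
  out <- vol$data[(lo[1] + 1):(hi[1] + 1),
                  (lo[2] + 1):(hi[2] + 1),
                  (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  v <- scalar_volume(out, vol$spacing, vol$origin + lo * vol$spacing)
  if (inherits(vol, "region_mask")) class(v) <- class(vol)
  v
}

#' Resample a deformation field onto a new grid
#'
#' Trilinear interpolation of each displacement component at the new grid's
#' voxel centres; vectors stay in mm so no rescaling is needed.
#'
#' @param field A [deformation_field()].
#' @param reference A [scalar_volume()] (or any object with grid geometry)
#'   defining the target grid.
#' @return A [deformation_field()] on the reference grid.
#' @export
resample_field <- function(field, reference) {
  pts <- grid_world(reference)
  vec <- sample_field(field, pts)
  deformation_field(array(vec, c(grid_dim(reference), 3L)),
                    reference$spacing, reference$origin)
}
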