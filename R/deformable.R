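#' Deformable registration configuration
#'
#' The registration variants under study: Demons or Morphons forces, 10 or
#' 20 iterations per scale, weighted-sum or diffeomorphic accumulation of
#' the update field, in a factor-2 multi-resolution schedule with Gaussian
#' regularization proportional to the voxel size.
#'
#' @param algorithm `"demons"` (intensity-difference force) or `"morphons"`
#'   (local-phase force from a quadrature filter bank).
#' @param iterations_per_scale Iterations at every pyramid level (10 or 20
#'   in the studied variants; any positive integer is accepted).
#' @param n_scales Number of factor-2 resolution scales, finest last.
#' @param accumulation `"weighted_sum"` or `"diffeomorphic"`.
#' @param regularization_factor Gaussian sigma for field regularization, as
#'   a multiple of the voxel size (default 1.5).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(algorithm = c("demons", "morphons"),
                                iterations_per_scale = 10L,
                                n_scales = 8L,
                                accumulation = c("weighted_sum",
                                                 "diffeomorphic"),
                                regularization_factor = 1.5) {
  algorithm <- match.arg(algorithm)
  accumulation <- match.arg(accumulation)
  iterations_per_scale <- as.integer(iterations_per_scale)
  n_scales <- as.integer(n_scales)
  if (iterations_per_scale < 1L || n_scales < 1L)
    abort("iteration and scale counts must be positive.")
  if (regularization_factor < 0)
    abort("`regularization_factor` must be non-negative.")
  structure(list(algorithm = algorithm,
                 iterations_per_scale = iterations_per_scale,
                 n_scales = n_scales,
                 accumulation = accumulation,
                 regularization_factor = regularization_factor),
            class = "registration_config")
}

#' @export
print.registration_config <- function(x, ...) {
  cat(sprintf(
    "<registration_config> %s, %d it/scale, %d scales, %s, reg %.2gx voxel\n",
    x$algorithm, x$iterations_per_scale, x$n_scales, x$accumulation,
    x$regularization_factor))
  invisible(x)
}

#' The eight registration variants of the comparison study
#' @return A named list of [registration_config()] objects covering
#'   {demons, morphons} x {10, 20 iterations} x {weighted_sum,
#'   diffeomorphic}.
#' @export
variant_configs <- function() {
  out <- list()
  for (alg in c("demons", "morphons"))
    for (it in c(10L, 20L))
      for (acc in c("weighted_sum", "diffeomorphic"))
        out[[sprintf("%s_%s_%d", alg,
                     ifelse(acc == "weighted_sum", "W", "D"), it)]] <-
          registration_config(alg, it, 8L, acc)
  out
}

# Central-difference gradient along one axis, one-sided at the borders,
# in units of intensity per mm.
array_gradient <- function(arr, spacing, axis) {
  d <- dim(arr)
  n <- d[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  h <- (ip - im) * spacing[axis]
  idx <- function(ix) switch(axis,
                             arr[ix, , , drop = FALSE],
                             arr[, ix, , drop = FALSE],
                             arr[, , ix, drop = FALSE])
  g <- (idx(ip) - idx(im))
  hperm <- switch(axis,
                  array(rep(h, times = d[2] * d[3]), d),
                  array(rep(rep(h, each = d[1]), times = d[3]), d),
                  array(rep(h, each = d[1] * d[2]), d))
  g / hperm
}

#' Demons force update
#'
#' Thirion's passive force: per voxel
#' `u = (f - m_w) grad(f) / (|grad f|^2 + kappa^2 (f - m_w)^2)`, with the
#' fixed-image gradient in 1/mm and `kappa = 1/mean(spacing)` stabilising
#' flat regions. The update magnitude is intrinsically bounded by
#' `mean(spacing)/2` per iteration.
#'
#' @param fixed Fixed [scalar_volume()].
#' @param warped_moving Moving image already warped onto the fixed grid.
#' @return A [deformation_field()] of raw (unregularised) updates in mm.
#' @export
demons_update <- function(fixed, warped_moving) {
  if (!same_geometry(fixed, warped_moving))
    abort("fixed and warped moving images must share a grid.")
  f <- fixed$data
  diffi <- f - warped_moving$data
  gx <- array_gradient(f, fixed$spacing, 1L)
  gy <- array_gradient(f, fixed$spacing, 2L)
  gz <- array_gradient(f, fixed$spacing, 3L)
  kappa2 <- 1 / mean(fixed$spacing)^2
  denom <- gx^2 + gy^2 + gz^2 + kappa2 * diffi^2
  scale <- ifelse(denom < 1e-9, 0, diffi / denom)
  vec <- array(0, c(dim(f), 3L))
  vec[, , , 1] <- scale * gx
  vec[, , , 2] <- scale * gy
  vec[, , , 3] <- scale * gz
  deformation_field(vec, fixed$spacing, fixed$origin)
}

# ---- Morphons quadrature filters -------------------------------------------

#' Build the Morphons quadrature filter bank
#'
#' Six log-normal quadrature filters along icosahedron-derived directions,
#' centre frequency pi/3 rad/voxel, relative bandwidth 2 octaves, realised
#' as 9^3 complex spatial stencils (designed on an oversampled frequency
#' grid, Hamming-windowed, and DC-corrected so the response to a constant
#' image is exactly zero). Filters act in voxel (index) space; displacement
#' estimates are converted to mm per component downstream.
#'
#' @param spacing Voxel spacing of the images the bank will be applied to
#'   (recorded for bookkeeping; the stencils themselves are defined on the
#'   index grid).
#' @param center_frequency Radial centre frequency, rad/voxel.
#' @param bandwidth Relative bandwidth in octaves.
#' @param size Odd stencil edge length.
#' @return An object of class `quadrature_filter_bank`.
#' @export
build_filter_bank <- function(spacing = c(1, 1, 1),
                              center_frequency = pi / 3,
                              bandwidth = 2,
                              size = 9L) {
  phi <- (1 + sqrt(5)) / 2
  orient <- rbind(c(0, 1, phi), c(0, -1, phi), c(1, phi, 0),
                  c(-1, phi, 0), c(phi, 0, 1), c(phi, 0, -1))
  orient <- orient / sqrt(rowSums(orient^2))

  ncap <- 32L
  fr <- 2 * pi * c(0:(ncap / 2 - 1), -(ncap / 2):-1) / ncap
  ux <- array(rep(fr, times = ncap * ncap), rep(ncap, 3))
  uy <- array(rep(rep(fr, each = ncap), times = ncap), rep(ncap, 3))
  uz <- array(rep(fr, each = ncap * ncap), rep(ncap, 3))
  rho <- sqrt(ux^2 + uy^2 + uz^2)
  radial <- array(0, rep(ncap, 3))
  nz <- rho > 0
  radial[nz] <- exp(-4 / (bandwidth^2 * log(2)) *
                      log(rho[nz] / center_frequency)^2)

  half <- (size - 1L) / 2L
  ctr <- ncap / 2 + 1L
  keep <- (ctr - half):(ctr + half)
  wt <- 0.54 + 0.46 * cos(pi * (-half:half) / half)
  w3 <- outer(outer(wt, wt), wt)
  shift_idx <- c((ncap / 2 + 1):ncap, 1:(ncap / 2))

  kernels <- lapply(seq_len(nrow(orient)), function(k) {
    n <- orient[k, ]
    cosang <- (ux * n[1] + uy * n[2] + uz * n[3])
    dir <- array(0, rep(ncap, 3))
    pos <- nz & cosang > 0
    dir[pos] <- (cosang[pos] / rho[pos])^2
    fresp <- radial * dir
    h <- fft(fresp, inverse = TRUE) / ncap^3
    h <- h[shift_idx, shift_idx, shift_idx]      # centre the impulse response
    h <- h[keep, keep, keep] * w3
    h - mean(h)                                   # exact zero-DC
  })

  structure(list(orientations = orient,
                 center_frequency = center_frequency,
                 bandwidth = bandwidth,
                 spacing = as.numeric(spacing),
                 kernels = kernels),
            class = "quadrature_filter_bank")
}

# Embed each spatial stencil into a dims-sized array (wrap-around) and
# pre-compute its DFT so filtering is one forward and one inverse FFT.
bank_ffts <- function(bank, dims) {
  lapply(bank$kernels, function(h) {
    hs <- dim(h)
    half <- (hs - 1L) / 2L
    big <- array(0 + 0i, dims)
    ix <- ((-half[1]:half[1]) %% dims[1]) + 1L
    iy <- ((-half[2]:half[2]) %% dims[2]) + 1L
    iz <- ((-half[3]:half[3]) %% dims[3]) + 1L
    for (c3 in seq_len(hs[3]))
      big[ix, iy, iz[c3]] <- big[ix, iy, iz[c3]] + h[, , c3]
    fft(big)
  })
}

filter_responses <- function(arr, hf) {
  fa <- fft(arr)
  n <- length(arr)
  lapply(hf, function(h) fft(fa * h, inverse = TRUE) / n)
}

#' Apply the quadrature filter bank to a volume
#' @param vol A [scalar_volume()].
#' @param bank A [build_filter_bank()] result.
#' @return List of complex response arrays, one per orientation.
#' @export
quadrature_responses <- function(vol, bank) {
  filter_responses(vol$data, bank_ffts(bank, dim(vol$data)))
}

morphons_core <- function(qf, qm, bank, spacing, origin) {
  rho0 <- bank$center_frequency
  dims <- dim(qf[[1]])
  a11 <- a12 <- a13 <- a22 <- a23 <- a33 <- array(0, dims)
  b1 <- b2 <- b3 <- array(0, dims)
  ctot <- array(0, dims)
  for (k in seq_along(qf)) {
    qq <- qf[[k]] * Conj(qm[[k]])
    dphi <- Arg(qq)
    ck <- sqrt(Mod(qq)) * cos(dphi / 2)^2
    dk <- dphi / rho0                 # voxels along the orientation
    n <- bank$orientations[k, ]
    a11 <- a11 + ck * n[1] * n[1]; a12 <- a12 + ck * n[1] * n[2]
    a13 <- a13 + ck * n[1] * n[3]; a22 <- a22 + ck * n[2] * n[2]
    a23 <- a23 + ck * n[2] * n[3]; a33 <- a33 + ck * n[3] * n[3]
    cd <- ck * dk
    b1 <- b1 + cd * n[1]; b2 <- b2 + cd * n[2]; b3 <- b3 + cd * n[3]
    ctot <- ctot + ck
  }
  # closed-form 3x3 solve via the adjugate; singular systems give u = 0
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  eps <- 1e-8 * max(mean(ctot), 1e-30)^3
  inv_ok <- det > eps
  invdet <- ifelse(inv_ok, 1 / pmax(det, eps), 0)
  ux <- invdet * ((a22 * a33 - a23^2) * b1 +
                    (a13 * a23 - a12 * a33) * b2 +
                    (a12 * a23 - a13 * a22) * b3)
  uy <- invdet * ((a13 * a23 - a12 * a33) * b1 +
                    (a11 * a33 - a13^2) * b2 +
                    (a12 * a13 - a11 * a23) * b3)
  uz <- invdet * ((a12 * a23 - a13 * a22) * b1 +
                    (a12 * a13 - a11 * a23) * b2 +
                    (a11 * a22 - a12^2) * b3)
  vec <- array(0, c(dims, 3L))
  vec[, , , 1] <- ux * spacing[1]
  vec[, , , 2] <- uy * spacing[2]
  vec[, , , 3] <- uz * spacing[3]
  list(field = deformation_field(vec, spacing, origin),
       certainty = ctot / length(qf))
}

#' Morphons phase-difference update
#'
#' For each filter orientation the local phase difference between fixed and
#' warped moving responses estimates a displacement along that direction
#' with an associated certainty; the vector update solves the
#' certainty-weighted least-squares system per voxel. Phase is insensitive
#' to slowly varying intensity offsets, which is what distinguishes the
#' Morphons force from the Demons force.
#'
#' @inheritParams demons_update
#' @param bank A [build_filter_bank()] result.
#' @return List with `field` (a [deformation_field()], mm) and `certainty`
#'   (3-D array, the mean filter certainty).
#' @export
morphons_update <- function(fixed, warped_moving, bank) {
  if (!same_geometry(fixed, warped_moving))
    abort("fixed and warped moving images must share a grid.")
  hf <- bank_ffts(bank, dim(fixed$data))
  qf <- filter_responses(fixed$data, hf)
  qm <- filter_responses(warped_moving$data, hf)
  morphons_core(qf, qm, bank, fixed$spacing, fixed$origin)
}

# d_out(x) = b(x) + a(x + b(x)): composition of displacement fields.
compose_fields <- function(a, b) {
  pts <- grid_world(b) + matrix(b$vectors, ncol = 3L)
  add <- sample_field(a, pts)
  deformation_field(b$vectors + array(add, dim(b$vectors)),
                    b$spacing, b$origin)
}

#' Accumulate an update into the running deformation field
#'
#' `weighted_sum`: the regularised update is added to the field and the sum
#' regularised again (fluid- plus diffusion-like smoothing). `diffeomorphic`:
#' the regularised update is exponentiated by scaling and squaring and
#' composed with the field, keeping the accumulated map smooth and
#' invertible.
#'
#' @param current,update [deformation_field()] objects on the same grid.
#' @param mode `"weighted_sum"` or `"diffeomorphic"`.
#' @param sigma Regularization sigma in mm (length 3 or scalar).
#' @return The accumulated [deformation_field()].
#' @export
accumulate_field <- function(current, update,
                             mode = c("weighted_sum", "diffeomorphic"),
                             sigma) {
  mode <- match.arg(mode)
  if (!same_geometry(current, update))
    abort("field and update must share a grid.")
  if (mode == "weighted_sum") {
    us <- gaussian_smooth(update, sigma)
    out <- current
    out$vectors <- out$vectors + us$vectors
    return(gaussian_smooth(out, sigma))
  }
  us <- gaussian_smooth(update, sigma)
  maxmag <- sqrt(max(rowSums(matrix(us$vectors, ncol = 3L)^2)))
  if (maxmag > 0) {
    steps <- max(2L, ceiling(log2(maxmag / (0.5 * min(current$spacing)))))
    e <- us
    e$vectors <- e$vectors / 2^steps
    for (i in seq_len(steps)) e <- compose_fields(e, e)
    out <- compose_fields(current, e)
  } else {
    out <- current
  }
  gaussian_smooth(out, sigma)
}

#' Multi-resolution deformable registration
#'
#' Runs the configured force (Demons or Morphons) and accumulation scheme
#' over a factor-2 pyramid, coarse to fine; every level executes a fixed
#' number of warp / update / accumulate iterations with Gaussian
#' regularization of `regularization_factor` times that level's voxel
#' size. Pyramid levels where any axis would fall below 4 voxels are
#' skipped. The inputs are expected to be rigidly pre-aligned and cropped
#' to a shared volume of interest.
#'
#' @param fixed,moving [scalar_volume()] objects.
#' @param config A [registration_config()].
#' @param verbose Emit per-scale progress messages.
#' @return A backward [deformation_field()] on the fixed image's grid.
#' @export
register_deformable <- function(fixed, moving,
                                config = registration_config(),
                                verbose = FALSE) {
  flo <- fixed$origin
  fhi <- fixed$origin + (grid_dim(fixed) - 1) * fixed$spacing
  mlo <- moving$origin
  mhi <- moving$origin + (grid_dim(moving) - 1) * moving$spacing
  if (any(pmin(fhi, mhi) <= pmax(flo, mlo)))
    abort("fixed and moving volumes do not overlap in world space.")
  if (diff(range(fixed$data)) == 0)
    abort("fixed image is constant; registration is degenerate.")

  field <- NULL
  for (s in rev(seq_len(config$n_scales) - 1L)) {
    factor <- 2L^s
    dims_s <- lengths(lapply(grid_dim(fixed),
                             function(n) seq(1L, n, by = factor)))
    if (any(dims_s < 4L)) next
    fixed_s <- downsample(fixed, factor)
    moving_s <- downsample(moving, factor)
    field <- if (is.null(field)) zero_field(fixed_s)
             else resample_field(field, fixed_s)
    sigma <- config$regularization_factor * fixed_s$spacing
    if (config$algorithm == "morphons") {
      bank <- build_filter_bank(fixed_s$spacing)
      hf <- bank_ffts(bank, dim(fixed_s$data))
      qf <- filter_responses(fixed_s$data, hf)
    }
    for (it in seq_len(config$iterations_per_scale)) {
      mw <- warp(moving_s, field)
      u <- if (config$algorithm == "demons") {
        demons_update(fixed_s, mw)
      } else {
        qm <- filter_responses(mw$data, hf)
        morphons_core(qf, qm, bank, fixed_s$spacing, fixed_s$origin)$field
      }
      field <- accumulate_field(field, u, config$accumulation, sigma)
    }
    if (verbose)
      message(sprintf("scale 1/%d (%s voxels): done", factor,
                      paste(dims_s, collapse = "x")))
  }
  if (is.null(field))
    abort("all pyramid levels degenerate; volume too small.")
  field
}

#' Jacobian determinant of the mapping induced by a deformation field
#'
#' Computes `det(I + grad d)` per voxel by central differences in world
#' units. Positive everywhere means the map `x + d(x)` is locally
#' invertible (orientation-preserving).
#'
#' @param field A [deformation_field()].
#' @return A [scalar_volume()] of determinant values on the field grid.
#' @export
jacobian_determinant <- function(field) {
  j <- vector("list", 9L)
  dim(j) <- c(3L, 3L)
  for (ci in 1:3)
    for (ax in 1:3)
      j[[ci, ax]] <- array_gradient(field$vectors[, , , ci],
                                    field$spacing, ax) +
        (ci == ax)
  det <- j[[1, 1]] * (j[[2, 2]] * j[[3, 3]] - j[[2, 3]] * j[[3, 2]]) -
    j[[1, 2]] * (j[[2, 1]] * j[[3, 3]] - j[[2, 3]] * j[[3, 1]]) +
    j[[1, 3]] * (j[[2, 1]] * j[[3, 2]] - j[[2, 2]] * j[[3, 1]])
  scalar_volume(det, field$spacing, field$origin)
}
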