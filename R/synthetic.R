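#' Phantom specification
#'
#' Parameters of the synthetic thorax phantom: a CT-like pre-treatment
#' volume (body, lungs, tumour, vessel-bifurcation and calcification
#' landmark substrates), a follow-up volume derived from it through a
#' known smooth invertible deformation with radial tumour shrinkage, and
#' co-registered PET volumes with an FDG-like hotspot. Scenarios set the
#' deformation regime the registration has to cope with:
#' `recoverable` (large but smooth motion), `small-motion`,
#' `new-hotspot` (recoverable motion but a spatially new uptake focus on
#' the follow-up PET), and `large-mismatch` (motion beyond the capture
#' range: large amplitude on short spatial wavelengths).
#'
#' @param scenario One of `"recoverable"`, `"small-motion"`,
#'   `"new-hotspot"`, `"large-mismatch"`.
#' @param seed Integer RNG seed; the phantom is deterministic given it.
#' @param ct_dim,ct_spacing CT grid size and spacing (mm); default
#'   96 x 96 x 60 at 1 x 1 x 3 mm, in the clinical spacing range.
#' @param pet_spacing PET voxel size, default 5.3 x 5.3 x 5 mm.
#' @param tumor_center,tumor_radius Tumour sphere, world mm (centre
#'   defaults to the right lung).
#' @param deformation_amplitude Maximum displacement magnitude in mm;
#'   default set by scenario (12 / 4 / 12 / 25).
#' @param rbf_width_range Range (mm) of the Gaussian radial-basis widths
#'   carrying the deformation; default set by scenario (broad for
#'   recoverable motion, short for `large-mismatch`).
#' @param n_control Number of radial-basis control points (8 for
#'   `large-mismatch`, where sign-alternating short-wavelength bumps put
#'   the motion beyond the registration capture range; 4 otherwise).
#' @param shrinkage Tumour radial shrinkage factor in (0, 1].
#' @param noise_ct,noise_pet Additive Gaussian noise SD (HU / SUV).
#' @param landmark_noise_mm Annotation jitter SD per axis (mm) applied to
#'   the recorded pre and post landmark positions independently,
#'   emulating observer click precision on thick slices; the underlying
#'   substrate geometry stays exact. Default 1.
#' @param n_landmarks Total landmarks (10-30 sensible), `n_near_tumor` of
#'   them inside or directly surrounding the tumour.
#' @param n_near_tumor See above.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(scenario = c("recoverable", "small-motion",
                                      "new-hotspot", "large-mismatch"),
                         seed = 1L,
                         ct_dim = c(96L, 96L, 60L),
                         ct_spacing = c(1, 1, 3),
                         pet_spacing = c(5.3, 5.3, 5),
                         tumor_center = c(22, 5, 0),
                         tumor_radius = 15,
                         deformation_amplitude = NULL,
                         rbf_width_range = NULL,
                         n_control = NULL,
                         shrinkage = 0.85,
                         noise_ct = 20,
                         noise_pet = 0.2,
                         landmark_noise_mm = 1,
                         n_landmarks = 30L,
                         n_near_tumor = 10L) {
  scenario <- match.arg(scenario)
  if (is.null(deformation_amplitude))
    deformation_amplitude <- switch(scenario,
                                    "recoverable" = 12,
                                    "small-motion" = 4,
                                    "new-hotspot" = 12,
                                    "large-mismatch" = 25)
  if (is.null(rbf_width_range))
    rbf_width_range <- if (scenario == "large-mismatch") c(16, 20)
                       else c(35, 50)
  if (is.null(n_control))
    n_control <- if (scenario == "large-mismatch") 8L else 4L
  if (shrinkage <= 0 || shrinkage > 1)
    abort("`shrinkage` must be in (0, 1].")
  # displacement-gradient bound: a Gaussian bump of amplitude A and width w
  # has max gradient A / (w sqrt(e)); require the total comfortably below 1
  if (deformation_amplitude / (min(rbf_width_range) * sqrt(exp(1))) > 0.95)
    abort("deformation amplitude too large for the RBF widths; the ground-truth field would not be invertible.")
  structure(list(scenario = scenario, seed = as.integer(seed),
                 ct_dim = as.integer(ct_dim), ct_spacing = ct_spacing,
                 pet_spacing = pet_spacing,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 deformation_amplitude = deformation_amplitude,
                 rbf_width_range = rbf_width_range,
                 n_control = as.integer(n_control),
                 shrinkage = shrinkage,
                 noise_ct = noise_ct, noise_pet = noise_pet,
                 landmark_noise_mm = landmark_noise_mm,
                 n_landmarks = as.integer(n_landmarks),
                 n_near_tumor = as.integer(n_near_tumor)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

centered_origin <- function(dm, sp) -(dm - 1) * sp / 2

# World-coordinate component arrays for a grid.
coord_arrays <- function(dm, sp, org) {
  list(x = array(rep(org[1] + (seq_len(dm[1]) - 1) * sp[1],
                     times = dm[2] * dm[3]), dm),
       y = array(rep(rep(org[2] + (seq_len(dm[2]) - 1) * sp[2],
                         each = dm[1]), times = dm[3]), dm),
       z = array(rep(org[3] + (seq_len(dm[3]) - 1) * sp[3],
                     each = dm[1] * dm[2]), dm))
}

stamp_ball <- function(arr, sp, org, center, radius, value) {
  dm <- dim(arr)
  lo <- pmax(1L, floor((center - radius - org) / sp) + 1L)
  hi <- pmin(dm, ceiling((center + radius - org) / sp) + 1L)
  if (any(hi < lo)) return(arr)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  wx <- org[1] + (ix - 1) * sp[1] - center[1]
  wy <- org[2] + (iy - 1) * sp[2] - center[2]
  wz <- org[3] + (iz - 1) * sp[3] - center[3]
  d2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
  sub <- arr[ix, iy, iz, drop = FALSE]
  sub[d2 <= radius^2] <- pmax(sub[d2 <= radius^2], value)
  arr[ix, iy, iz] <- sub
  arr
}

stamp_tube <- function(arr, sp, org, from, direction, length, radius, value) {
  for (t in seq(0, length, by = min(sp) / 2))
    arr <- stamp_ball(arr, sp, org, from + t * direction, radius, value)
  arr
}

# Evaluate the ground-truth backward displacement at world points (n x 3).
eval_truth <- function(pts, truth) {
  d <- matrix(0, nrow(pts), 3L)
  for (j in seq_len(nrow(truth$centers))) {
    r2 <- rowSums(sweep(pts, 2L, truth$centers[j, ])^2)
    w <- exp(-r2 / (2 * truth$widths[j]^2))
    d <- d + outer(w, truth$amps[j, ])
  }
  rel <- sweep(pts, 2L, truth$tumor_center)
  r2 <- rowSums(rel^2)
  shrink_gain <- (1 / truth$shrinkage - 1) *
    exp(-r2 / (2 * truth$tumor_radius^2))
  d + rel * shrink_gain
}

# Solve x + d(x) = target for x (the post-scan point corresponding to a
# pre-scan point under the backward map), by fixed-point iteration on the
# stored (trilinearly interpolated) field, so landmark correspondences are
# exact with respect to the discretised ground truth.
invert_field_point <- function(target, field, iters = 100L) {
  x <- matrix(target, ncol = 3L)
  for (i in seq_len(iters)) {
    xn <- matrix(target, ncol = 3L) - sample_field(field, x)
    if (max(abs(xn - x)) < 1e-8) { x <- xn; break }
    x <- xn
  }
  drop(x)
}

#' Generate a synthetic thorax phantom case
#'
#' Builds the pre-treatment CT (body at ~0 HU, lungs at -800 HU, tumour at
#' +30 HU, calcifications and Y-shaped vessel bifurcations as landmark
#' substrates), derives the follow-up CT by warping it through a known
#' smooth invertible backward deformation (sum of Gaussian radial-basis
#' displacements plus radial tumour contraction), adds independent
#' Gaussian noise to both, and produces co-registered PET volumes with an
#' uptake hotspot (peak ~8 SUV pre, residual ~4 SUV post, placed per
#' scenario). Landmark pairs satisfy the ground-truth correspondence to
#' numerical precision.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_case` list: `pre_ct`, `post_ct`, `pre_pet`,
#'   `post_pet` ([scalar_volume()]s), `true_field`
#'   ([deformation_field()] on the post grid), `landmarks` (paired
#'   tibble), `ptv_box` ([bounding_box()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dm <- spec$ct_dim; sp <- spec$ct_spacing
    org <- centered_origin(dm, sp)
    cc <- coord_arrays(dm, sp, org)
    tc <- spec$tumor_center; tr <- spec$tumor_radius

    ct <- array(-1000, dm)                                   # air
    body <- (cc$x / 44)^2 + (cc$y / 40)^2 <= 1
    ct[body] <- 0                                            # soft tissue
    lungR <- ((cc$x - 22) / 16)^2 + ((cc$y - 5) / 24)^2 +
      (cc$z / 70)^2 <= 1
    lungL <- ((cc$x + 22) / 16)^2 + ((cc$y - 5) / 24)^2 +
      (cc$z / 70)^2 <= 1
    ct[lungR | lungL] <- -800
    tum <- (cc$x - tc[1])^2 + (cc$y - tc[2])^2 + (cc$z - tc[3])^2 <= tr^2
    ct[tum] <- 30

    in_lung <- function(p)
      ((p[1] - 22) / 16)^2 + ((p[2] - 5) / 24)^2 + (p[3] / 70)^2 <= 0.95 ||
      ((p[1] + 22) / 16)^2 + ((p[2] - 5) / 24)^2 + (p[3] / 70)^2 <= 0.95

    # ground-truth backward deformation: draw RBF configurations until one
    # is comfortably invertible at the requested amplitude (superpositions
    # of several bumps can locally exceed the single-bump gradient bound)
    pts <- grid_world(list(data = array(0, dm), spacing = sp, origin = org))
    rel <- sweep(pts, 2L, tc)
    shrink_part <- rel * ((1 / spec$shrinkage - 1) *
                            exp(-rowSums(rel^2) / (2 * tr^2)))
    true_field <- NULL
    for (attempt in 1:25) {
      centers <- sweep(matrix(runif(spec$n_control * 3, -25, 25),
                              ncol = 3L), 2L, tc, "+")
      widths <- runif(spec$n_control, spec$rbf_width_range[1],
                      spec$rbf_width_range[2])
      amps <- matrix(rnorm(spec$n_control * 3), ncol = 3L)
      amps <- amps / sqrt(rowSums(amps^2)) *
        runif(spec$n_control, 0.6, 1)
      if (spec$scenario == "large-mismatch" && spec$n_control >= 2L) {
        # alternate directions so coarse scales see little net motion
        flip <- rep(c(1, -1), length.out = spec$n_control)
        amps <- amps * flip
      }
      truth <- list(centers = centers, widths = widths, amps = amps,
                    tumor_center = tc, tumor_radius = tr,
                    shrinkage = spec$shrinkage)
      draw <- eval_truth(pts, truth)
      # rescale the RBF part so the maximum total displacement hits the
      # requested amplitude (the shrinkage term is kept as-is)
      rbf_part <- draw - shrink_part
      scale <- spec$deformation_amplitude /
        max(sqrt(rowSums(rbf_part^2)))
      truth$amps <- truth$amps * scale
      dvec <- eval_truth(pts, truth)
      cand <- deformation_field(array(dvec, c(dm, 3L)), sp, org)
      if (min(jacobian_determinant(cand)$data) > 0.05) {
        true_field <- cand
        break
      }
    }
    if (is.null(true_field))
      abort("deformation amplitude too large for the RBF widths: no invertible ground-truth field found.")

    # landmark substrate positions: n_near_tumor inside/around the tumour,
    # the rest spread over the VOI. Pre positions are the substrate
    # centres; post positions solve x + d(x) = pre under the backward
    # field. Both must stay inside the registration VOI (PTV box + 20 mm)
    # and clear of the grid border, enforced by rejection sampling.
    grid_lo <- org + 4; grid_hi <- org + (dm - 1) * sp - 4
    ok_pos <- function(p) all(p >= pmax(tc - 38, grid_lo) &
                                p <= pmin(tc + 38, grid_hi))
    pos <- matrix(0, spec$n_landmarks, 3L)
    post_pos <- matrix(0, spec$n_landmarks, 3L)
    k <- 0L
    while (k < spec$n_landmarks) {
      p <- if (k < spec$n_near_tumor) {
        u <- rnorm(3); tc + runif(1, 4, tr + 8) * (u / sqrt(sum(u^2)))
      } else {
        tc + runif(3, -26, 26)
      }
      if (k >= spec$n_near_tumor && sqrt(sum((p - tc)^2)) <= tr + 8) next
      q <- invert_field_point(p, true_field)
      if (!ok_pos(p) || !ok_pos(q)) next
      k <- k + 1L
      pos[k, ] <- p
      post_pos[k, ] <- q
    }
    near <- sqrt(rowSums(sweep(pos, 2L, tc)^2)) <= tr + 10

    for (i in seq_len(spec$n_landmarks)) {
      p <- pos[i, ]
      use_calc <- !in_lung(p) || i %% 2L == 0L
      if (use_calc) {
        ct <- stamp_ball(ct, sp, org, p, 2.2, 300)
      } else {
        for (j in 1:3) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          ct <- stamp_tube(ct, sp, org, p, u, 12, 1.8, 0)
        }
        ct <- stamp_ball(ct, sp, org, p, 2.4, 60)   # visible node
      }
    }
    pre_clean <- gaussian_smooth(scalar_volume(ct, sp, org), 0.5 * sp)

    post_clean <- warp(pre_clean, true_field)
    pre_ct <- pre_clean
    pre_ct$data <- pre_ct$data + array(rnorm(prod(dm), 0, spec$noise_ct), dm)
    post_ct <- post_clean
    post_ct$data <- post_ct$data + array(rnorm(prod(dm), 0, spec$noise_ct), dm)

    # annotated positions: substrate geometry is exact, but the recorded
    # coordinates carry independent per-axis observer jitter
    jit <- function(m) m + matrix(rnorm(length(m), 0, spec$landmark_noise_mm),
                                  ncol = 3L)
    pos_a <- jit(pos); post_a <- jit(post_pos)
    lm <- tibble(name = sprintf("L%02d", seq_len(spec$n_landmarks)),
                 pre_x = pos_a[, 1], pre_y = pos_a[, 2], pre_z = pos_a[, 3],
                 post_x = post_a[, 1], post_y = post_a[, 2],
                 post_z = post_a[, 3],
                 near_tumor = near)

    # PET grids, centred on the same world frame
    pet_dim <- pmax(4L, as.integer(floor((dm - 1) * sp / spec$pet_spacing)) + 1L)
    pet_org <- centered_origin(pet_dim, spec$pet_spacing)
    pc <- coord_arrays(pet_dim, spec$pet_spacing, pet_org)
    body_pet <- (pc$x / 44)^2 + (pc$y / 40)^2 <= 1
    hotspot <- function(center, peak, sigma) {
      r2 <- (pc$x - center[1])^2 + (pc$y - center[2])^2 +
        (pc$z - center[3])^2
      (peak - 1) * exp(-r2 / (2 * sigma^2))
    }
    sigma_pre <- tr / 2
    pre_pet_arr <- ifelse(body_pet, 1, 0.05) + hotspot(tc, 8, sigma_pre)
    post_center <- invert_field_point(tc, true_field)
    post_hot_center <- if (spec$scenario == "new-hotspot")
      tc + c(-18, -14, 12) else post_center
    post_pet_arr <- ifelse(body_pet, 1, 0.05) +
      hotspot(post_hot_center, 4, 0.8 * sigma_pre)
    pre_pet <- scalar_volume(pre_pet_arr + array(
      rnorm(prod(pet_dim), 0, spec$noise_pet), pet_dim),
      spec$pet_spacing, pet_org)
    post_pet <- scalar_volume(post_pet_arr + array(
      rnorm(prod(pet_dim), 0, spec$noise_pet), pet_dim),
      spec$pet_spacing, pet_org)

    ptv <- bounding_box(tc - (tr + 5), tc + (tr + 5))

    structure(list(pre_ct = pre_ct, post_ct = post_ct,
                   pre_pet = pre_pet, post_pet = post_pet,
                   true_field = true_field, landmarks = lm,
                   ptv_box = ptv, spec = spec),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> scenario '%s', seed %d\n",
              x$spec$scenario, x$spec$seed))
  cat(sprintf("  CT %s @ (%s) mm; %d landmarks (%d near tumour)\n",
              paste(dim(x$pre_ct$data), collapse = "x"),
              paste(x$pre_ct$spacing, collapse = ","),
              nrow(x$landmarks), sum(x$landmarks$near_tumor)))
  invisible(x)
}

#' Export a phantom case to disk
#'
#' Writes the four volumes and the true field as NIfTI, the landmark
#' tables as CSV (`name,x_mm,y_mm,z_mm,near_tumor`), the PTV box as JSON,
#' and a manifest recording the generating spec.
#'
#' @param case A `phantom_case`.
#' @param directory Output directory (created if needed).
#' @export
export_case <- function(case, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$pre_ct, file.path(directory, "pre_ct.nii.gz"))
  write_volume(case$post_ct, file.path(directory, "post_ct.nii.gz"))
  write_volume(case$pre_pet, file.path(directory, "pre_pet.nii.gz"))
  write_volume(case$post_pet, file.path(directory, "post_pet.nii.gz"))
  write_volume(case$true_field, file.path(directory, "true_field.nii.gz"))
  lm <- case$landmarks
  write_landmarks(tibble(name = lm$name, x_mm = lm$pre_x, y_mm = lm$pre_y,
                         z_mm = lm$pre_z, near_tumor = lm$near_tumor),
                  file.path(directory, "landmarks_pre.csv"))
  write_landmarks(tibble(name = lm$name, x_mm = lm$post_x, y_mm = lm$post_y,
                         z_mm = lm$post_z, near_tumor = lm$near_tumor),
                  file.path(directory, "landmarks_post.csv"))
  jsonlite::write_json(list(lower_mm = case$ptv_box$lower,
                            upper_mm = case$ptv_box$upper),
                       file.path(directory, "ptv_box.json"),
                       auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(unclass(case$spec),
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Load a case directory written by [export_case()]
#'
#' Also accepts equivalently named user data; `true_field.nii.gz` and
#' `manifest.json` are optional.
#'
#' @param directory Case directory.
#' @return A `phantom_case` (with `true_field`/`spec` possibly NULL).
#' @export
read_case <- function(directory) {
  need <- c("pre_ct.nii.gz", "post_ct.nii.gz", "pre_pet.nii.gz",
            "post_pet.nii.gz", "landmarks_pre.csv", "landmarks_post.csv",
            "ptv_box.json")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing) > 0L)
    abort(sprintf("case directory %s is missing: %s", directory,
                  paste(missing, collapse = ", ")),
          class = "thoraxreg_io_error")
  box <- jsonlite::read_json(file.path(directory, "ptv_box.json"),
                             simplifyVector = TRUE)
  tf_path <- file.path(directory, "true_field.nii.gz")
  mf_path <- file.path(directory, "manifest.json")
  structure(list(
    pre_ct = read_volume(file.path(directory, "pre_ct.nii.gz")),
    post_ct = read_volume(file.path(directory, "post_ct.nii.gz")),
    pre_pet = read_volume(file.path(directory, "pre_pet.nii.gz")),
    post_pet = read_volume(file.path(directory, "post_pet.nii.gz")),
    true_field = if (file.exists(tf_path)) read_field(tf_path) else NULL,
    landmarks = pair_landmarks(
      read_landmarks(file.path(directory, "landmarks_pre.csv")),
      read_landmarks(file.path(directory, "landmarks_post.csv"))),
    ptv_box = bounding_box(box$lower_mm, box$upper_mm),
    spec = if (file.exists(mf_path))
      jsonlite::read_json(mf_path, simplifyVector = TRUE) else NULL),
    class = "phantom_case")
}
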