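test_that("NIfTI round-trip preserves geometry exactly and data to float32", {
  vol <- scalar_volume(array(rnorm(10 * 12 * 8, sd = 100), c(10, 12, 8)),
                       spacing = c(1, 1, 5), origin = c(-100, -120, -50))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(dim(back$data), dim(vol$data))
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
  expect_lt(max(abs(back$data - vol$data)), 1e-3)  # float32 storage

  fld <- deformation_field(array(rnorm(10 * 12 * 8 * 3), c(10, 12, 8, 3)),
                           c(1, 1, 5), c(-100, -120, -50))
  write_volume(fld, path)
  fback <- read_field(path)
  expect_lt(max(abs(fback$vectors - fld$vectors)), 1e-5)
  expect_equal(fback$origin, fld$origin)
})

test_that("read_volume rejects non-3-D images and missing files", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(deformation_field(array(0, c(6, 6, 6, 3))), path)
  expect_error(read_volume(path), class = "thoraxreg_dim_error")
  expect_error(read_volume(file.path(tempdir(), "no_such.nii.gz")),
               class = "thoraxreg_io_error")
})

test_that("trilinear sampling reproduces affine intensity fields", {
  vol <- affine_volume()
  withr::local_seed(11)
  pts <- interior_points(vol, 200)
  expected <- 7 + pts %*% c(0.5, -1.2, 2)
  expect_equal(sample_trilinear(vol, pts), drop(expected), tolerance = 1e-6)
  # voxel-centre identity and axis midpoint linearity
  expect_equal(sample_trilinear(vol, vol$origin), vol$data[1, 1, 1])
  v <- scalar_volume(array(c(0, 10), c(2, 2, 2)))
  expect_equal(sample_trilinear(v, c(0.5, 0, 0)), 5)
})

test_that("out-of-bounds sampling follows the configured policy", {
  vol <- affine_volume()
  far <- matrix(c(1e3, 1e3, 1e3), ncol = 3)
  corner <- vol$origin + (dim(vol$data) - 1) * vol$spacing
  expect_equal(sample_trilinear(vol, far),
               sample_trilinear(vol, matrix(corner, ncol = 3)))
  expect_equal(sample_trilinear(vol, far, oob = "constant", fill = -1), -1)
})

test_that("warp with the zero field is the identity on a shared grid", {
  vol <- small_case()$pre_ct
  out <- warp(vol, zero_field(vol))
  expect_equal(out$data, vol$data, tolerance = 1e-12)
})

test_that("warp by a constant field shifts an affine volume analytically", {
  vol <- affine_volume(dm = c(16L, 16L, 12L), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0))
  fld <- zero_field(vol)
  fld$vectors[, , , 1] <- 5
  out <- warp(vol, fld)
  inner <- out$data[2:12, 2:15, 2:11]
  ref <- vol$data[2:12, 2:15, 2:11] + 5 * 0.5   # b_x = 0.5
  expect_equal(inner, ref, tolerance = 1e-6)
})

test_that("phantom follow-up equals pre-treatment warped by the truth, up to noise", {
  ph <- small_case()
  w <- warp(ph$pre_ct, ph$true_field)
  rms <- sqrt(mean((w$data - ph$post_ct$data)^2))
  expect_lt(rms, 2.5 * ph$spec$noise_ct)
})

test_that("gaussian smoothing preserves constants, mass, and sigma-0 inputs", {
  vol <- scalar_volume(array(3.5, c(10, 10, 10)), c(1, 1, 2))
  expect_equal(gaussian_smooth(vol, 0)$data, vol$data)
  expect_equal(gaussian_smooth(vol, c(2, 2, 4))$data, vol$data,
               tolerance = 1e-9)
  imp <- scalar_volume(array(0, c(21, 21, 21)), c(1, 1, 1))
  imp$data[11, 11, 11] <- 42
  sm <- gaussian_smooth(imp, 2)
  expect_equal(sum(sm$data), 42, tolerance = 1e-6)
  expect_error(gaussian_smooth(vol, -1), "non-negative")
})

test_that("downsampling halves the grid and doubles the spacing", {
  vol <- scalar_volume(array(rnorm(64^3), c(64, 64, 64)), c(1, 1, 1))
  expect_identical(downsample(vol, 1), vol)
  dn <- downsample(vol, 2)
  expect_identical(dim(dn$data), c(32L, 32L, 32L))
  expect_equal(dn$spacing, c(2, 2, 2))
  const <- scalar_volume(array(7, c(16, 16, 16)), c(1, 1, 3))
  expect_equal(downsample(const, 4)$data,
               array(7, c(4, 4, 4)), tolerance = 1e-9)
})

test_that("VOI cropping preserves world coordinates and honours the margin", {
  ph <- small_case()
  vol <- ph$pre_ct
  full <- bounding_box(vol$origin,
                       vol$origin + (dim(vol$data) - 1) * vol$spacing)
  expect_equal(crop_voi(vol, full, 0)$data, vol$data)

  crop <- crop_voi(vol, ph$ptv_box, 20)
  # a 40 mm PTV box + 20 mm margin spans >= 80 mm per axis (before clipping)
  span <- (dim(crop$data) - 1) * crop$spacing
  clip_lo <- pmax(ph$ptv_box$lower - 20, vol$origin)
  clip_hi <- pmin(ph$ptv_box$upper + 20,
                  vol$origin + (dim(vol$data) - 1) * vol$spacing)
  expect_true(all(span >= clip_hi - clip_lo - 2 * vol$spacing))
  # world coordinate of a retained voxel is unchanged
  off <- round((crop$origin - vol$origin) / vol$spacing)
  expect_equal(crop$data[3, 4, 2],
               vol$data[off[1] + 3, off[2] + 4, off[3] + 2])
  expect_error(crop_voi(vol, bounding_box(c(900, 900, 900),
                                          c(950, 950, 950)), 0),
               "intersect")
})

test_that("field resampling keeps displacement vectors in mm", {
  ph <- small_case()
  coarse <- downsample(ph$pre_ct, 2)
  res <- resample_field(ph$true_field, coarse)
  pts <- interior_points(coarse, 50, margin = 3)
  orig <- ph$true_field
  expect_equal(res$spacing, coarse$spacing)
  d_orig <- cbind(sample_trilinear(scalar_volume(orig$vectors[, , , 1],
                                                 orig$spacing, orig$origin),
                                   pts),
                  sample_trilinear(scalar_volume(orig$vectors[, , , 2],
                                                 orig$spacing, orig$origin),
                                   pts),
                  sample_trilinear(scalar_volume(orig$vectors[, , , 3],
                                                 orig$spacing, orig$origin),
                                   pts))
  d_res <- cbind(sample_trilinear(scalar_volume(res$vectors[, , , 1],
                                                res$spacing, res$origin),
                                  pts),
                 sample_trilinear(scalar_volume(res$vectors[, , , 2],
                                                res$spacing, res$origin),
                                  pts),
                 sample_trilinear(scalar_volume(res$vectors[, , , 3],
                                                res$spacing, res$origin),
                                  pts))
  expect_lt(max(abs(d_res - d_orig)), 0.5)   # smooth field, coarse grid
})

test_that("landmark CSV round-trips and pairs by name", {
  pre <- tibble::tibble(name = c("a", "b", "c"),
                        x_mm = c(1, 2, 3), y_mm = c(4, 5, 6),
                        z_mm = c(7, 8, 9), near_tumor = c(TRUE, FALSE, TRUE))
  post <- tibble::tibble(name = c("c", "a"),
                         x_mm = c(3.5, 1.5), y_mm = c(6.5, 4.5),
                         z_mm = c(9.5, 7.5))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(pre, f1)
  expect_equal(as.data.frame(read_landmarks(f1)), as.data.frame(pre))
  pairs <- pair_landmarks(pre, post)
  expect_equal(pairs$name, c("a", "c"))
  expect_equal(pairs$post_x, c(1.5, 3.5))
  expect_equal(pairs$near_tumor, c(TRUE, TRUE))
})
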