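ramp_volume <- function(n = 32L, slope = 10, spacing = c(1, 1, 1)) {
  x <- (seq_len(n) - 1) * spacing[1]
  scalar_volume(array(rep(slope * x, times = n * n), c(n, n, n)), spacing)
}

test_that("demons force is zero for identical images and flat mismatches", {
  vol <- small_case()$pre_ct
  u <- demons_update(vol, vol)
  expect_equal(max(abs(u$vectors)), 0)
  flat <- scalar_volume(array(100, c(8, 8, 8)))
  flat2 <- scalar_volume(array(150, c(8, 8, 8)))
  expect_equal(max(abs(demons_update(flat, flat2)$vectors)), 0)
})

test_that("demons force on a shifted linear ramp recovers the shift", {
  delta <- 0.2
  f <- ramp_volume()
  m <- f
  m$data <- m$data - delta * 10           # f(x - delta), slope 10
  u <- demons_update(f, m)
  interior <- u$vectors[5:28, 5:28, 5:28, 1]
  expect_equal(mean(interior), delta, tolerance = 0.05)
  expect_lt(max(abs(u$vectors[, , , 2:3])), 1e-9)
})

test_that("quadrature filters have zero DC response and span 3-space", {
  bank <- build_filter_bank()
  for (h in bank$kernels) {
    peak <- max(Mod(h))
    expect_lt(Mod(sum(h)), 1e-6 * peak)
  }
  o <- bank$orientations
  expect_gte(nrow(o), 6)
  expect_equal(qr(o)$rank, 3L)
  cross <- abs(o %*% t(o))
  expect_lt(max(cross[upper.tri(cross)]), 0.999)  # pairwise non-collinear
})

test_that("filter response peaks at the centre frequency along its orientation", {
  bank <- build_filter_bank()
  rho0 <- bank$center_frequency
  n <- 32L
  idx <- (seq_len(n) - 1)
  for (k in c(1L, 5L)) {
    nv <- bank$orientations[k, ]
    # octave-spaced probes around the nominal centre frequency
    mags <- vapply(c(0.5, 1, 2) * rho0, function(rho) {
      phase <- rho * (outer(outer(idx * nv[1], idx * nv[2], "+"),
                            idx * nv[3], "+"))
      vol <- scalar_volume(array(cos(phase), c(n, n, n)))
      q <- quadrature_responses(vol, bank)[[k]]
      mean(Mod(q[9:24, 9:24, 9:24]))
    }, numeric(1))
    expect_equal(which.max(mags), 2L)
  }
})

test_that("morphons update is zero for identical inputs yet certain where structured", {
  vol <- small_case()$pre_ct
  bank <- build_filter_bank(vol$spacing)
  res <- morphons_update(vol, vol, bank)
  expect_lt(max(abs(res$field$vectors)), 1e-8)
  expect_gt(max(res$certainty), 0)
  flat <- scalar_volume(array(5, c(16, 16, 16)))
  res0 <- morphons_update(flat, flat, bank)
  expect_equal(max(abs(res0$field$vectors)), 0)
})

test_that("morphons recovers a sub-quarter-wavelength texture shift", {
  # band-limited isotropic texture, shifted exactly in the Fourier domain
  withr::local_seed(31)
  n <- 32L
  rho0 <- pi / 3
  fr <- 2 * pi * c(0:(n / 2 - 1), -(n / 2):-1) / n
  ux <- array(rep(fr, times = n * n), rep(n, 3))
  uy <- array(rep(rep(fr, each = n), times = n), rep(n, 3))
  uz <- array(rep(fr, each = n * n), rep(n, 3))
  rho <- sqrt(ux^2 + uy^2 + uz^2)
  shell <- exp(-((rho - rho0) / (0.25 * rho0))^2)
  spec <- fft(array(rnorm(n^3), rep(n, 3))) * shell
  delta <- 1                               # voxels, < quarter wavelength (1.5)
  f <- Re(fft(spec, inverse = TRUE)) / n^3
  m <- Re(fft(spec * exp(-1i * ux * delta), inverse = TRUE)) / n^3
  bank <- build_filter_bank()
  res <- morphons_update(scalar_volume(f), scalar_volume(m), bank)
  core <- res$field$vectors[9:24, 9:24, 9:24, ]
  est <- colMeans(matrix(core, ncol = 3))
  expect_equal(est[1], delta, tolerance = 0.25 * delta)
  expect_lt(max(abs(est[2:3])), 0.1)
})

test_that("field accumulation honours both modes on constant fields", {
  grid <- scalar_volume(array(0, c(16, 16, 16)), c(1, 1, 2))
  a <- zero_field(grid); a$vectors[, , , 1] <- 2
  b <- zero_field(grid); b$vectors[, , , 2] <- 3
  ws <- accumulate_field(a, b, "weighted_sum", sigma = c(1.5, 1.5, 3))
  expect_equal(ws$vectors[, , , 1], array(2, c(16, 16, 16)), tolerance = 1e-9)
  expect_equal(ws$vectors[, , , 2], array(3, c(16, 16, 16)), tolerance = 1e-9)

  z <- zero_field(grid)
  ws0 <- accumulate_field(a, z, "weighted_sum", sigma = c(1.5, 1.5, 3))
  expect_equal(ws0$vectors, gaussian_smooth(a, c(1.5, 1.5, 3))$vectors)
  df0 <- accumulate_field(a, z, "diffeomorphic", sigma = c(1.5, 1.5, 3))
  expect_equal(df0$vectors, gaussian_smooth(a, c(1.5, 1.5, 3))$vectors)
})

test_that("diffeomorphic accumulation keeps the Jacobian positive", {
  ph <- small_case()
  upd <- ph$true_field
  fld <- zero_field(ph$pre_ct)
  for (i in 1:3)
    fld <- accumulate_field(fld, upd, "diffeomorphic",
                            sigma = 1.5 * ph$pre_ct$spacing)
  expect_gt(min(jacobian_determinant(fld)$data), 0)
})

test_that("jacobian determinant matches the closed form of a linear field", {
  grid <- scalar_volume(array(0, c(12, 12, 12)), c(2, 2, 2))
  fld <- zero_field(grid)
  cc <- thoraxreg:::grid_world(grid)
  # d(x) = (0.1 x, -0.05 y, 0.2 z): J = diag(1.1, 0.95, 1.2)
  fld$vectors <- array(cbind(0.1 * cc[, 1], -0.05 * cc[, 2], 0.2 * cc[, 3]),
                       c(12, 12, 12, 3))
  jd <- jacobian_determinant(fld)
  expect_equal(jd$data[4, 5, 6], 1.1 * 0.95 * 1.2, tolerance = 1e-9)
})

test_that("self-registration yields a sub-quarter-voxel field (default pair)", {
  ph <- small_case()
  fixed <- crop_voi(ph$post_ct, ph$ptv_box, 20)
  for (cfg in default_configs()) {
    fld <- register_deformable(fixed, fixed, cfg)
    mag <- sqrt(rowSums(matrix(fld$vectors, ncol = 3)^2))
    expect_lt(mean(mag), 0.25 * min(fixed$spacing))
  }
})

test_that("a known constant translation is recovered by both algorithms", {
  ph <- small_case()
  fixed <- crop_voi(ph$post_ct, ph$ptv_box, 20)
  moving <- fixed
  moving$origin <- fixed$origin + c(6, 0, 0)    # content shifted +6 mm
  dm <- dim(fixed$data)
  for (alg in c("demons", "morphons")) {
    fld <- register_deformable(fixed, moving, registration_config(alg, 10))
    core <- fld$vectors[5:(dm[1] - 4), 5:(dm[2] - 4), 3:(dm[3] - 2), ]
    est <- colMeans(matrix(core, ncol = 3))
    expect_true(all(abs(est - c(6, 0, 0)) <= fixed$spacing),
                label = sprintf("%s translation estimate", alg))
  }
})

test_that("degenerate registration inputs are rejected", {
  flat <- scalar_volume(array(1, c(16, 16, 16)))
  expect_error(register_deformable(flat, flat), "constant")
  a <- small_case()$pre_ct
  b <- a
  b$origin <- a$origin + c(1e4, 0, 0)
  expect_error(register_deformable(a, b), "overlap")
})
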