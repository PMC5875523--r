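gaussian_pet <- function(n = 24L, spacing = c(5, 5, 5), peak = 10,
                         sigma = 12) {
  org <- -(n - 1) * spacing / 2
  g <- thoraxreg:::coord_arrays(rep(n, 3), spacing, org)
  scalar_volume(peak * exp(-(g$x^2 + g$y^2 + g$z^2) / (2 * sigma^2)),
                spacing, org)
}

test_that("threshold scheme validates its fractions", {
  sch <- threshold_scheme()
  expect_equal(sch$pre_fractions, c(0.34, 0.40, 0.50, 0.60, 0.70))
  expect_equal(sch$post_fractions, c(0.70, 0.80, 0.90))
  expect_error(threshold_scheme(pre_fractions = c(0.5, 0.4)), "increasing")
  expect_error(threshold_scheme(post_fractions = c(0, 0.5)), "increasing")
})

test_that("fractional-SUVmax region matches the analytic level set", {
  pet <- gaussian_pet()
  m <- threshold_region(pet, 0.60)
  # analytic radius of the 60% level set of a Gaussian hotspot
  r_true <- 12 * sqrt(2 * log(1 / 0.6))
  vol_true <- 4 / 3 * pi * r_true^3
  vol_mask <- sum(m$data) * prod(pet$spacing)
  expect_lt(abs(vol_mask - vol_true) / vol_true, 0.2)   # coarse PET voxels
  # fraction 1.0 keeps only the peak component
  top <- threshold_region(pet, 1.0)
  expect_gte(sum(top$data), 1)
  expect_lte(sum(top$data), 8)
})

test_that("threshold regions nest and keep only the hotspot component", {
  pet <- gaussian_pet()
  # secondary disconnected uptake, brighter than parts of the main tail
  pet$data[2:3, 2:3, 2:3] <- 6
  prev <- NULL
  for (fr in c(0.34, 0.40, 0.50, 0.60, 0.70)) {
    m <- threshold_region(pet, fr)
    if (!is.null(prev)) expect_true(all(prev$data >= m$data))
    prev <- m
  }
  m50 <- threshold_region(pet, 0.50)
  expect_false(any(m50$data[2:3, 2:3, 2:3]))
  expect_error(threshold_region(scalar_volume(array(-1, c(4, 4, 4))), 0.5),
               "positive")
})

test_that("mask deformation shifts the centroid and preserves volume", {
  pet <- gaussian_pet()
  m <- threshold_region(pet, 0.5)
  expect_equal(deform_mask(m, zero_field(pet))$data, m$data)

  fld <- zero_field(pet)
  fld$vectors[, , , 1] <- -5   # backward field: contour appears at +5 mm
  moved <- deform_mask(m, fld, pet)
  centroid <- function(mask) {
    w <- which(mask$data, arr.ind = TRUE)
    colMeans(sweep(sweep(w - 1, 2, mask$spacing, "*"), 2, mask$origin, "+"))
  }
  shift <- centroid(moved) - centroid(m)
  expect_true(all(abs(shift - c(5, 0, 0)) <= pet$spacing / 2))
  expect_lt(abs(sum(moved$data) - sum(m$data)) / sum(m$data), 0.1)
})

test_that("Dice ratio follows its defining identity", {
  sp <- c(2, 2, 2)
  base <- array(FALSE, c(10, 10, 10))
  a <- base; a[1:5, 1:5, 1:4] <- TRUE            # 100 voxels
  b <- base; b[4:5, 1:5, 1:6] <- TRUE            # 60 voxels, overlap 40
  ra <- region_mask(a, sp); rb <- region_mask(b, sp)
  res <- dice_ratio(ra, rb)
  expect_equal(res$DR, 2 * 40 / (100 + 60))
  expect_equal(res$Vint_mm3, 40 * 8)
  expect_true(res$Vint_mm3 <= min(res$VA_mm3, res$VB_mm3))

  expect_equal(dice_ratio(ra, ra)$DR, 1)
  disjoint <- region_mask(base, sp); disjoint[["data"]][9:10, 9:10, 9:10] <- TRUE
  expect_equal(dice_ratio(ra, disjoint)$DR, 0)
  empty <- region_mask(base, sp)
  res0 <- dice_ratio(empty, empty)
  expect_equal(res0$DR, 0)
  expect_true(res0$empty_input)
  expect_error(dice_ratio(ra, region_mask(base, c(1, 1, 1))),
               class = "thoraxreg_geometry_error")
})

test_that("overlap table covers all threshold combinations symmetrically", {
  pet <- gaussian_pet()
  tbl <- overlap_table(pet, pet, field = zero_field(pet))
  expect_equal(nrow(tbl), 5 * 3 * 2)
  diag <- tbl[tbl$pre_fraction == 0.70 & tbl$post_fraction == 0.70, ]
  expect_equal(diag$DR, c(1, 1))
})

test_that("wilcoxon signed-rank p matches exhaustive sign enumeration", {
  # n = 6, all differences the same sign. Oracle: enumerate all 2^6 sign
  # assignments of ranks 1..6 and count W+ at least as extreme.
  ranks <- 1:6
  wplus <- vapply(0:63, function(mask) {
    signs <- bitwAnd(mask, 2^(0:5)) > 0
    sum(ranks[signs])
  }, numeric(1))
  observed <- 0   # all differences positive in the "after" direction
  p_oracle <- 2 * mean(wplus <= observed)
  expect_equal(p_oracle, 0.03125)

  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6) + 0.5,
                              c(1, 2, 3, 4, 5, 6) + c(1, 2, 3, 4, 5, 7))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
})

test_that("the signed-rank test has power for a median shift at n = 7", {
  withr::local_seed(99)
  hits <- 0L
  for (i in 1:1000) {
    before <- runif(7, 0.1, 0.4)
    after <- before + 0.1 + rnorm(7, 0, 0.05)
    if (wilcoxon_signed_rank(before, after)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits, 500L)
})
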