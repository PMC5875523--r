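const_field <- function(shift, reference) {
  f <- zero_field(reference)
  for (i in 1:3) f$vectors[, , , i] <- shift[i]
  f
}

test_that("landmark tracking follows the backward field", {
  grid <- scalar_volume(array(0, c(10, 10, 10)), c(2, 2, 2), c(-9, -9, -9))
  expect_equal(track_landmark(zero_field(grid), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(track_landmark(const_field(c(5, 0, 0), grid), c(1, 2, 3)),
               c(6, 2, 3))
  expect_error(track_landmark(zero_field(grid), c(100, 0, 0)),
               class = "thoraxreg_extent_error")
})

test_that("tracking through the ground-truth field reproduces the stored pairs", {
  ph <- exact_case()
  lm <- ph$landmarks
  post <- as.matrix(lm[, c("post_x", "post_y", "post_z")])
  mapped <- track_landmark(ph$true_field, post)
  err <- sqrt(rowSums((mapped -
                         as.matrix(lm[, c("pre_x", "pre_y", "pre_z")]))^2))
  expect_lt(max(err), 1e-3)
})

test_that("distance reports aggregate correctly, including the n = 1 case", {
  pairs <- tibble::tibble(name = c("a", "b"),
                          pre_x = c(0, 0), pre_y = c(0, 0), pre_z = c(0, 0),
                          post_x = c(0, 3), post_y = c(0, 0),
                          post_z = c(0, 0), near_tumor = c(FALSE, TRUE))
  rep0 <- landmark_distances(pairs)
  expect_equal(rep0$distance_mm, c(0, 3))
  expect_equal(attr(rep0, "mean_mm"), 1.5)
  expect_equal(attr(rep0, "sd_mm"), stats::sd(c(0, 3)))

  one <- landmark_distances(pairs, subset = "tumor")
  expect_equal(attr(one, "mean_mm"), 3)
  expect_equal(attr(one, "sd_mm"), 0)
  expect_true(attr(one, "insufficient_n"))
  expect_error(landmark_distances(pairs[pairs$name == "none", ]),
               "no landmarks")
  g <- glance(rep0)
  expect_equal(g$mean_mm, 1.5)
  expect_equal(g$n, 2L)
})

test_that("the three-group classifier reproduces the published group means", {
  expect_equal(classify_group(9.5, 3.8)$group, 1L)
  expect_equal(classify_group(5.6, 4.5)$group, 2L)
  expect_equal(classify_group(13.6, 8.0)$group, 3L)
})

test_that("the classifier is total and flags fallback assignments", {
  withr::local_seed(42)
  for (i in 1:200) {
    r <- runif(1, 0, 25); d <- runif(1, 0, 25)
    g <- classify_group(r, d)
    expect_true(g$group %in% 1:3)
    if (g$group == 1L) expect_true(d < r / 2 && d < 6)
    if (g$group == 3L) expect_true(!(d < r / 2 && d < 6) && r > 7.5 && d > 6)
  }
  # the published criteria miss e.g. (10, 5.5): rigid > 7.5 but deformable < 6
  gap <- classify_group(10, 5.5)
  expect_equal(gap$group, 2L)
  expect_true(gap$fallback)
  expect_false(classify_group(5.6, 4.5)$fallback)
  expect_error(classify_group(-1, 2), "non-negative")
})

test_that("distances are invariant to a global rigid motion of the frame", {
  ph <- small_case()
  lm <- ph$landmarks
  base <- attr(landmark_distances(lm), "mean_mm")
  shift <- c(12, -7, 9)
  lm2 <- lm
  for (ax in c("x", "y", "z")) {
    i <- match(ax, c("x", "y", "z"))
    lm2[[paste0("pre_", ax)]] <- lm2[[paste0("pre_", ax)]] + shift[i]
    lm2[[paste0("post_", ax)]] <- lm2[[paste0("post_", ax)]] + shift[i]
  }
  expect_equal(attr(landmark_distances(lm2), "mean_mm"), base,
               tolerance = 1e-12)
})

test_that("paired t-test matches the closed form and its error contracts", {
  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)) = 2 sqrt(3), df = 2
  res <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * (1 - stats::pt(2 * sqrt(3), 2)),
               tolerance = 1e-9)
  expect_error(paired_t_test(c(1, 2), c(2, 3)), "zero variance")
  expect_error(paired_t_test(1, 2), "n >= 2")
})

test_that("the paired t-test detects a true 5 mm reduction at n = 7", {
  withr::local_seed(123)
  hits <- 0L
  for (i in 1:1000) {
    before <- rnorm(7, 10, 1.5)
    after <- before - 5 + rnorm(7, 0, 1.5)
    if (paired_t_test(before, after)$p_value < 0.001) hits <- hits + 1L
  }
  # analytic power of the noncentral t: ncp = (5/1.5) sqrt(7) = 8.82,
  # two-sided alpha 0.001, df 6 -> 0.938; assert above its 3-sigma
  # binomial lower bound over 1000 draws
  ncp <- 5 / 1.5 * sqrt(7)
  crit <- stats::qt(1 - 0.001 / 2, 6)
  power <- 1 - stats::pt(crit, 6, ncp) + stats::pt(-crit, 6, ncp)
  expect_gte(hits, floor(1000 * (power - 3 * sqrt(power * (1 - power) / 1000))))
})

test_that("numerical field inversion undoes the ground-truth map", {
  ph <- small_case()
  inv <- invert_field(ph$true_field, tol = 0.01)
  lm <- ph$landmarks
  pre <- as.matrix(lm[, c("pre_x", "pre_y", "pre_z")])
  post <- as.matrix(lm[, c("post_x", "post_y", "post_z")])
  # forward use of the inverse: pre-positions map back to post-positions
  mapped <- pre + thoraxreg:::sample_field(inv, pre)
  err <- sqrt(rowSums((mapped - post)^2))
  # annotation jitter aside, the inverse should land within ~3 mm
  expect_lt(mean(err), 3 * sqrt(6) * ph$spec$landmark_noise_mm + 0.5)
})
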