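#' Fractional-SUVmax threshold scheme
#'
#' The uptake-contour fractions applied to the pre- and post-treatment PET
#' scans. Post-treatment residual uptake is generally lower, hence the
#' higher fractions there.
#'
#' @param pre_fractions Strictly increasing fractions of SUVmax in (0, 1]
#'   for the pre-treatment scan (default 0.34, 0.40, 0.50, 0.60, 0.70).
#' @param post_fractions Likewise for the post-treatment scan (default
#'   0.70, 0.80, 0.90).
#' @return An object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(pre_fractions = c(0.34, 0.40, 0.50, 0.60, 0.70),
                             post_fractions = c(0.70, 0.80, 0.90)) {
  chk <- function(x, nm) {
    if (any(x <= 0) || any(x > 1) || is.unsorted(x, strictly = TRUE))
      abort(sprintf("`%s` must be strictly increasing within (0, 1].", nm))
  }
  chk(pre_fractions, "pre_fractions")
  chk(post_fractions, "post_fractions")
  structure(list(pre_fractions = pre_fractions,
                 post_fractions = post_fractions),
            class = "threshold_scheme")
}

#' Fractional-SUVmax region extraction
#'
#' Thresholds the PET volume at `fraction * SUVmax` and keeps only the
#' 26-connected component containing the SUVmax voxel, so disconnected
#' physiological uptake elsewhere does not join the tumour contour.
#' SUVmax is taken within `search_mask` when given, otherwise over the
#' whole volume.
#'
#' @param pet A [scalar_volume()] in SUV.
#' @param fraction Fraction of SUVmax in (0, 1].
#' @param search_mask Optional [region_mask()] on the same grid restricting
#'   the SUVmax search.
#' @return A [region_mask()] on the PET grid.
#' @export
threshold_region <- function(pet, fraction, search_mask = NULL) {
  if (fraction <= 0 || fraction > 1)
    abort("`fraction` must be in (0, 1].")
  dat <- pet$data
  search <- if (is.null(search_mask)) array(TRUE, dim(dat)) else {
    if (!same_geometry(pet, search_mask))
      abort("search mask and PET must share a grid.",
            class = "thoraxreg_geometry_error")
    search_mask$data
  }
  vmax <- max(dat[search])
  if (!is.finite(vmax) || vmax <= 0)
    abort("PET maximum within the search region must be positive.")
  mask <- dat >= fraction * vmax
  seed <- which(search & (dat == vmax))[1]
  d <- dim(dat)
  seed_ijk <- c((seed - 1) %% d[1],
                ((seed - 1) %/% d[1]) %% d[2],
                (seed - 1) %/% (d[1] * d[2]))
  comp <- cpp_flood26(as.logical(mask), d, as.integer(seed_ijk))
  region_mask(array(comp, d), pet$spacing, pet$origin)
}

#' Deform a region mask through a deformation field
#'
#' Warps the 0/1 indicator of the mask onto the target grid by trilinear
#' interpolation and re-binarizes at 0.5. This implements "deform the
#' contour, not the image": voxel values of the PET are never resampled.
#' The field may live on a different (e.g., CT) grid; it is sampled in
#' world mm at the target voxel centres.
#'
#' @param mask A [region_mask()].
#' @param field A [deformation_field()], or NULL for pure resampling.
#' @param target Object supplying the output grid geometry (defaults to
#'   the mask's own grid).
#' @return A [region_mask()] on the target grid.
#' @export
deform_mask <- function(mask, field = NULL, target = mask) {
  pts <- grid_world(target)
  if (!is.null(field)) pts <- pts + sample_field(field, pts)
  ind <- scalar_volume(array(as.numeric(mask$data), grid_dim(mask)),
                       mask$spacing, mask$origin)
  vals <- sample_trilinear(ind, pts, oob = "constant", fill = 0)
  region_mask(array(vals >= 0.5, grid_dim(target)),
              target$spacing, target$origin)
}

#' Dice overlap ratio of two region masks
#'
#' `DR = 2 V_AB / (V_A + V_B)` with volumes in mm^3 (voxel counts times
#' voxel volume). Two empty masks give DR = 0 with an `empty_input` flag.
#'
#' @param a,b [region_mask()] objects on the same grid.
#' @return A one-row tibble: `VA_mm3`, `VB_mm3`, `Vint_mm3`, `DR`,
#'   `empty_input`.
#' @export
dice_ratio <- function(a, b) {
  if (!same_geometry(a, b))
    abort("masks must share a grid.", class = "thoraxreg_geometry_error")
  vv <- prod(a$spacing)
  va <- sum(a$data) * vv
  vb <- sum(b$data) * vv
  vi <- sum(a$data & b$data) * vv
  empty <- (va + vb) == 0
  tibble(VA_mm3 = va, VB_mm3 = vb, Vint_mm3 = vi,
         DR = if (empty) 0 else 2 * vi / (va + vb),
         empty_input = empty)
}

#' Dice overlap table over all threshold combinations
#'
#' For every pre-fraction x post-fraction pair, extracts the uptake
#' contours, maps the pre-treatment contour into the post-treatment frame
#' (rigidly, i.e. plain resampling, and additionally through the
#' deformation field when one is given), and tabulates the Dice ratios.
#'
#' @param pre_pet,post_pet PET [scalar_volume()]s, rigidly aligned to the
#'   frame the field lives in.
#' @param field Optional [deformation_field()] from the CT registration.
#' @param scheme A [threshold_scheme()].
#' @param pre_search,post_search Optional search masks for SUVmax.
#' @return Tibble with columns `pre_fraction`, `post_fraction`,
#'   `registration` ("rigid"/"deformable"), `VA_mm3`, `VB_mm3`,
#'   `Vint_mm3`, `DR`, `empty_input`.
#' @export
overlap_table <- function(pre_pet, post_pet, field = NULL,
                          scheme = threshold_scheme(),
                          pre_search = NULL, post_search = NULL) {
  post_masks <- lapply(scheme$post_fractions, function(fr)
    threshold_region(post_pet, fr, post_search))
  rows <- list()
  for (pf in scheme$pre_fractions) {
    pre_mask <- threshold_region(pre_pet, pf, pre_search)
    variants <- list(rigid = deform_mask(pre_mask, NULL, post_pet))
    if (!is.null(field))
      variants$deformable <- deform_mask(pre_mask, field, post_pet)
    for (reg in names(variants)) {
      for (bi in seq_along(post_masks)) {
        dr <- dice_ratio(variants[[reg]], post_masks[[bi]])
        rows[[length(rows) + 1L]] <-
          dplyr::bind_cols(tibble(pre_fraction = pf,
                                  post_fraction = scheme$post_fractions[bi],
                                  registration = reg), dr)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Wilcoxon signed-rank test on paired Dice ratios
#'
#' Two-sided signed-rank test on paired values (e.g., Dice ratios before
#' and after deformable registration). Zero differences are dropped per
#' the Wilcoxon convention; the exact null distribution is used for small
#' samples without ties, otherwise the normal approximation with
#' correction.
#'
#' @param before,after Equal-length numeric vectors.
#' @return A one-row tibble with `statistic`, `p_value`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(before, after) {
  if (length(before) != length(after))
    abort("`before` and `after` must have equal length.")
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0L)
    abort("all differences are zero; the signed-rank test is undefined.")
  ht <- suppressWarnings(wilcox.test(after, before, paired = TRUE,
                                     exact = length(d) <= 25 &&
                                       !any(duplicated(abs(d)))))
  tibble(statistic = unname(ht$statistic),
         p_value = ht$p.value,
         n_effective = length(d))
}
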