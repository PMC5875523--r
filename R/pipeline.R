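#' Default registration variant pair
#'
#' The fastest Demons variant and the fastest Morphons variant (10
#' iterations per scale, weighted-sum accumulation), the pair carried
#' forward to the full patient analysis in the study design this package
#' reproduces.
#' @return Named list of two [registration_config()]s.
#' @export
default_configs <- function() {
  list(demons = registration_config("demons", 10L, 8L, "weighted_sum"),
       morphons = registration_config("morphons", 10L, 8L, "weighted_sum"))
}

#' Run the full per-case analysis chain
#'
#' Rigid baseline, VOI crop (PTV box + margin), deformable registration
#' with each configured variant, landmark validation, best-field selection
#' by all-landmark mean distance, three-group classification, and - unless
#' the case lands in Group 3 - the fractional-SUVmax Dice overlap table
#' with the Wilcoxon comparison of rigid versus deformable ratios.
#'
#' @param case A `phantom_case` or a case directory path as written by
#'   [export_case()].
#' @param configs Named list of [registration_config()]s (default
#'   [default_configs()]).
#' @param voi_margin VOI expansion around the PTV box in mm (default 20).
#' @param rigid `"identity"` (scans already aligned, the phantom default)
#'   or `"auto"` for automatic rigid pre-alignment of the pre-treatment
#'   scan onto the follow-up grid before cropping.
#' @param scheme [threshold_scheme()] for the PET analysis.
#' @param dice_group3 Compute the Dice table even for Group 3 cases
#'   (excluded by default).
#' @param keep_fields Keep the computed deformation fields in the report.
#' @param verbose Progress messages.
#' @return A `case_report` list; see [glance.case_report()].
#' @export
run_case <- function(case, configs = default_configs(), voi_margin = 20,
                     rigid = c("identity", "auto"),
                     scheme = threshold_scheme(), dice_group3 = FALSE,
                     keep_fields = FALSE, verbose = FALSE) {
  rigid <- match.arg(rigid)
  if (is.character(case)) case <- read_case(case)
  pre_ct <- case$pre_ct

  rigid_tr <- rigid_transform(pivot = volume_center(case$post_ct))
  if (rigid == "auto") {
    rigid_tr <- register_rigid(case$post_ct, case$pre_ct, dof = 6)
    pre_ct <- apply_rigid(rigid_tr, case$pre_ct, case$post_ct)
  }

  fixed <- crop_voi(case$post_ct, case$ptv_box, voi_margin)
  moving <- crop_voi(pre_ct, case$ptv_box, voi_margin + 15)

  lm <- case$landmarks
  lo <- fixed$origin
  hi <- fixed$origin + (grid_dim(fixed) - 1) * fixed$spacing
  post <- as.matrix(lm[, c("post_x", "post_y", "post_z")])
  inside <- rowSums(sweep(post, 2L, lo, ">=") &
                      sweep(post, 2L, hi, "<=")) == 3L
  n_excluded <- sum(!inside)
  lm <- lm[inside, ]
  if (nrow(lm) == 0L) abort("no landmarks inside the registration VOI.")

  fields <- list()
  reports <- list(rigid = landmark_distances(lm, NULL, "all"))
  tumor_reports <- list(
    rigid = if (any(lm$near_tumor)) landmark_distances(lm, NULL, "tumor"))
  for (nm in names(configs)) {
    if (verbose) message(sprintf("registering variant '%s' ...", nm))
    fields[[nm]] <- register_deformable(fixed, moving, configs[[nm]],
                                        verbose = verbose)
    reports[[nm]] <- landmark_distances(lm, fields[[nm]], "all")
    tumor_reports[[nm]] <- if (any(lm$near_tumor))
      landmark_distances(lm, fields[[nm]], "tumor")
  }

  means <- vapply(reports[names(configs)], attr, numeric(1), "mean_mm")
  best_name <- names(configs)[which.min(means)]
  best_field <- fields[[best_name]]
  group <- classify_group(attr(reports$rigid, "mean_mm"),
                          min(means))
  ttest <- tryCatch(
    paired_t_test(reports$rigid$distance_mm,
                  reports[[best_name]]$distance_mm),
    error = function(e) tibble(statistic = NA_real_, p_value = NA_real_,
                               df = NA_real_, mean_difference = NA_real_))

  dice <- NULL; wilcoxon <- NULL
  if (group$group != 3L || dice_group3) {
    dice <- overlap_table(case$pre_pet, case$post_pet, best_field, scheme)
    wide <- tidyr::pivot_wider(
      dice[, c("pre_fraction", "post_fraction", "registration", "DR")],
      names_from = "registration", values_from = "DR")
    wilcoxon <- tryCatch(
      wilcoxon_signed_rank(wide$rigid, wide$deformable),
      error = function(e) tibble(statistic = NA_real_, p_value = NA_real_,
                                 n_effective = 0L))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("thoraxreg")),
    input_hash = hash(list(case$pre_ct$data, case$post_ct$data,
                           case$pre_pet$data, case$post_pet$data,
                           case$landmarks)),
    config_hash = hash(configs),
    configs = configs,
    rigid_transform = rigid_tr,
    voi_margin = voi_margin,
    seed = if (!is.null(case$spec)) case$spec$seed,
    scenario = if (!is.null(case$spec)) case$spec$scenario)

  structure(list(distance_reports = reports,
                 tumor_reports = tumor_reports,
                 best = best_name,
                 group = group,
                 t_test = ttest,
                 dice = dice,
                 wilcoxon = wilcoxon,
                 n_landmarks = nrow(lm),
                 n_landmarks_excluded = n_excluded,
                 fields = if (keep_fields) fields,
                 provenance = provenance),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> Group %d; best variant '%s'\n",
              x$group$group, x$best))
  for (nm in names(x$distance_reports))
    cat(sprintf("  %-10s %.2f +/- %.2f mm\n", nm,
                attr(x$distance_reports[[nm]], "mean_mm"),
                attr(x$distance_reports[[nm]], "sd_mm")))
  if (!is.null(x$dice))
    cat(sprintf("  Dice table: %d rows; Wilcoxon p = %.4g\n",
                nrow(x$dice), x$wilcoxon$p_value))
  else cat("  Dice analysis skipped (Group 3)\n")
  invisible(x)
}

#' Tidy per-landmark distances of a case report
#' @param x A `case_report`.
#' @param ... Unused.
#' @return Long tibble: `registration`, `name`, `near_tumor`,
#'   `distance_mm`.
#' @method tidy case_report
#' @export
tidy.case_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$distance_reports), function(nm)
    dplyr::mutate(as_tibble(x$distance_reports[[nm]]),
                  registration = nm, .before = 1L)))
}

#' One-row summary of a case report
#' @param x A `case_report`.
#' @param ... Unused.
#' @return Tibble with group, per-variant means, best variant, and test
#'   p-values.
#' @method glance case_report
#' @export
glance.case_report <- function(x, ...) {
  out <- tibble(group = x$group$group,
                fallback_group = x$group$fallback,
                best = x$best,
                n_landmarks = x$n_landmarks,
                t_p_value = x$t_test$p_value,
                wilcoxon_p_value = if (is.null(x$wilcoxon)) NA_real_
                                   else x$wilcoxon$p_value)
  for (nm in names(x$distance_reports)) {
    out[[paste0(nm, "_mean_mm")]] <- attr(x$distance_reports[[nm]], "mean_mm")
    out[[paste0(nm, "_sd_mm")]] <- attr(x$distance_reports[[nm]], "sd_mm")
  }
  out
}

#' Aggregate a set of cases into a study summary
#'
#' Runs (or accepts) per-case reports, groups them by the three-group
#' classifier, and aggregates: mean +/- SD of the per-case mean landmark
#' distances per group with a paired t-test of rigid versus best
#' deformable, and Wilcoxon signed-rank comparisons of Dice ratios per
#' threshold pair across the cases of Groups 1 and 2 separately.
#'
#' @param cases List of `phantom_case` objects, case directories, or
#'   ready-made `case_report`s.
#' @param ... Passed on to [run_case()] for unprocessed cases.
#' @return A `study_summary` list with tibbles `cases`, `groups`,
#'   `dice_tests`.
#' @export
run_study <- function(cases, ...) {
  if (length(cases) == 0L) abort("at least one case is required.")
  reports <- lapply(cases, function(cs)
    if (inherits(cs, "case_report")) cs else run_case(cs, ...))
  case_tbl <- dplyr::bind_rows(lapply(reports, glance.case_report))
  case_tbl$case <- seq_len(nrow(case_tbl))

  variant_names <- setdiff(names(reports[[1]]$distance_reports), "rigid")
  groups <- lapply(sort(unique(case_tbl$group)), function(g) {
    sub <- case_tbl[case_tbl$group == g, ]
    best_means <- vapply(seq_len(nrow(sub)), function(i)
      sub[[paste0(sub$best[i], "_mean_mm")]][i], numeric(1))
    tt <- if (nrow(sub) >= 2L && sd(sub$rigid_mean_mm - best_means) > 0)
      paired_t_test(sub$rigid_mean_mm, best_means)
    row <- tibble(group = g, n = nrow(sub),
                  rigid_mean_mm = mean(sub$rigid_mean_mm),
                  rigid_sd_mm = if (nrow(sub) > 1) sd(sub$rigid_mean_mm) else 0,
                  best_mean_mm = mean(best_means),
                  best_sd_mm = if (nrow(sub) > 1) sd(best_means) else 0,
                  p_rigid_vs_best = if (is.null(tt)) NA_real_ else tt$p_value,
                  stats_computed = !is.null(tt))
    for (v in variant_names) {
      row[[paste0(v, "_mean_mm")]] <- mean(sub[[paste0(v, "_mean_mm")]])
      row[[paste0(v, "_sd_mm")]] <- if (nrow(sub) > 1)
        sd(sub[[paste0(v, "_mean_mm")]]) else 0
    }
    row
  })
  groups <- dplyr::bind_rows(groups)

  dice_tests <- list()
  for (g in c(1L, 2L)) {
    idx <- which(case_tbl$group == g)
    dices <- lapply(reports[idx], function(r) r$dice)
    dices <- dices[!vapply(dices, is.null, TRUE)]
    if (length(dices) < 2L) next
    all_d <- dplyr::bind_rows(lapply(seq_along(dices), function(i)
      dplyr::mutate(dices[[i]], case = i)))
    pairs <- dplyr::distinct(all_d[, c("pre_fraction", "post_fraction")])
    for (i in seq_len(nrow(pairs))) {
      sub <- all_d[all_d$pre_fraction == pairs$pre_fraction[i] &
                     all_d$post_fraction == pairs$post_fraction[i], ]
      wide <- tidyr::pivot_wider(sub[, c("case", "registration", "DR")],
                                 names_from = "registration",
                                 values_from = "DR")
      wt <- tryCatch(wilcoxon_signed_rank(wide$rigid, wide$deformable),
                     error = function(e) tibble(statistic = NA_real_,
                                                p_value = NA_real_,
                                                n_effective = 0L))
      dice_tests[[length(dice_tests) + 1L]] <-
        dplyr::bind_cols(tibble(group = g,
                                pre_fraction = pairs$pre_fraction[i],
                                post_fraction = pairs$post_fraction[i],
                                n_cases = nrow(wide)), wt)
    }
  }
  structure(list(cases = case_tbl,
                 groups = groups,
                 dice_tests = dplyr::bind_rows(dice_tests),
                 reports = reports),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %d cases\n", nrow(x$cases)))
  print(x$groups)
  invisible(x)
}
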