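#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Paired Dice-ratio plot
#'
#' For each case, the rigid and deformable Dice ratios of every threshold
#' pair are drawn as paired points connected by a segment - improvement
#' shows as upward-sloping pairs.
#'
#' @param x A `study_summary`, a `case_report`, or a Dice tibble from
#'   [overlap_table()] (optionally with a `case` column).
#' @return A ggplot object.
#' @export
plot_dice_pairs <- function(x) {
  dice <- if (inherits(x, "study_summary")) {
    dplyr::bind_rows(lapply(seq_along(x$reports), function(i)
      if (!is.null(x$reports[[i]]$dice))
        dplyr::mutate(x$reports[[i]]$dice, case = factor(i))))
  } else if (inherits(x, "case_report")) {
    if (is.null(x$dice)) abort("this case has no Dice table (Group 3).")
    dplyr::mutate(x$dice, case = factor(1))
  } else dplyr::mutate(as_tibble(x),
                       case = factor(if (is.null(x$case)) 1 else x$case))
  dice$pair <- sprintf("%.0f%%/%.0f%%", 100 * dice$pre_fraction,
                       100 * dice$post_fraction)
  dice$registration <- factor(dice$registration,
                              levels = c("rigid", "deformable"))
  ggplot2::ggplot(dice, ggplot2::aes(x = .data$registration, y = .data$DR,
                                     group = interaction(.data$case,
                                                         .data$pair),
                                     colour = .data$case)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(shape = 4, size = 2) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Dice overlap ratio",
                  colour = "case",
                  title = "Uptake-contour overlap, rigid vs deformable") +
    ggplot2::theme_minimal()
}

#' Per-landmark distance plot for a case
#'
#' Distances before (rigid) and after each deformable variant, one line
#' per landmark; tumour-adjacent landmarks are highlighted.
#'
#' @param report A `case_report`.
#' @return A ggplot object.
#' @export
plot_landmark_distances <- function(report) {
  d <- tidy.case_report(report)
  d$registration <- factor(d$registration,
                           levels = names(report$distance_reports))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$registration,
                                  y = .data$distance_mm,
                                  group = .data$name,
                                  colour = .data$near_tumor)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2,
                          colour = "black") +
    ggplot2::labs(x = NULL, y = "landmark distance [mm]",
                  colour = "near tumour",
                  title = "Landmark distances by registration") +
    ggplot2::theme_minimal()
}
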