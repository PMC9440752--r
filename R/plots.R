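#' Plot methods for assay results
#'
#' `autoplot()` methods render the package's result types as ggplot2
#' figures: step survival curves for [km_estimate()], smoothed hazard
#' curves for [hazard_estimate()], and `plot_crossings()` draws the
#' per-treatment crossing-count boxplot (box width proportional to sample
#' size).
#'
#' @param object A `km_curve` or `hazard_curve`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @name assay-plots
NULL

#' @rdname assay-plots
#' @export
autoplot.km_curve <- function(object, ...) {
  has_group <- "group" %in% names(object)
  p <- ggplot2::ggplot(
    object,
    if (has_group) {
      ggplot2::aes(.data$time, .data$survival, colour = .data$group)
    } else {
      ggplot2::aes(.data$time, .data$survival)
    }
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Return duration (s)", y = "Proportion not yet returned",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' @rdname assay-plots
#' @export
autoplot.hazard_curve <- function(object, ...) {
  has_group <- "group" %in% names(object)
  ggplot2::ggplot(
    object,
    if (has_group) {
      ggplot2::aes(.data$time, .data$hazard, colour = .data$group)
    } else {
      ggplot2::aes(.data$time, .data$hazard)
    }
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Return duration (s)", y = "Smoothed hazard (1/s)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname assay-plots
#' @param outcomes A data frame with `treatment` and `crossings` columns
#'   (e.g. the `outcomes` of [generate_cohort()]).
#' @export
plot_crossings <- function(outcomes) {
  d <- filter(outcomes, !is.na(.data$crossings))
  ggplot2::ggplot(
    d, ggplot2::aes(.data$treatment, .data$crossings)
  ) +
    ggplot2::geom_boxplot(varwidth = TRUE) +
    ggplot2::labs(
      x = NULL, y = "Crossings of the leader's outward path"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname assay-plots
#' @param traj A trajectory tibble; `leader` an optional leader path;
#'   `arena` an [arena_spec()] drawn as backdrop.
#' @param leader,arena See above.
#' @export
plot_trajectory <- function(traj, leader = NULL, arena = NULL) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(leader)) {
    p <- p + ggplot2::geom_path(
      data = leader, colour = "firebrick", linetype = 2
    )
  }
  if (!is.null(arena)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = arena$xlim[1], xmax = arena$xlim[2],
      ymin = arena$ylim[1], ymax = arena$ylim[2],
      fill = NA, colour = "grey40"
    )
  }
  p
}
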