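#' Plot a sampling-error curve
#'
#' Predicted relative error of the mean bark thickness against the number of
#' gauge readings, for the CV the table was built from.
#'
#' @param object A `bark_error_table` (from [error_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bark_error_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$error_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Number of gauge readings per tree",
      y = "Relative error of mean bark thickness (%)",
      title = sprintf(
        "Sampling error for CV = %.1f%% (confidence %.0f%%)",
        attr(object, "cv"), 100 * attr(object, "confidence")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic bark cross-section
#'
#' Draws the wood circle and the fissured outer bark surface of a simulated
#' section in planar cm coordinates, with the bark ring filled.
#'
#' @param object A `bark_section` (from [make_section()]).
#' @param vertices_per_degree Outline sampling density.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bark_section <- function(object, vertices_per_degree = 4, ...) {
  profile <- to_profile(object, vertices_per_degree)
  outer <- profile[profile$contour == "outer", ]
  wood <- profile[profile$contour == "wood", ]
  ring <- rbind(outer, wood[rev(seq_len(nrow(wood))), ])
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = ring, ggplot2::aes(.data$x, .data$y),
      fill = "tan4", alpha = 0.6
    ) +
    ggplot2::geom_path(
      data = rbind(wood, wood[1, ]), ggplot2::aes(.data$x, .data$y),
      colour = "firebrick"
    ) +
    ggplot2::geom_path(
      data = rbind(outer, outer[1, ]), ggplot2::aes(.data$x, .data$y),
      colour = "navy", linewidth = 0.3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (cm)", y = "y (cm)",
      title = sprintf(
        "Synthetic section: BFI(area) = %.3f, BFI(thickness) = %.3f",
        object$true_bfi_area, object$true_bfi_thickness
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Monte Carlo validation of the gauge estimator
#'
#' Empirical 95th-percentile relative error of the thickness-ratio BFI against
#' sample size, next to the t-formula prediction.
#'
#' @param object A `bgm_validation` (from [validate_bgm()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bgm_validation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("rel_error_pct", "predicted_error_pct"),
    names_to = "kind", values_to = "error_pct"
  )
  long$kind <- ifelse(
    long$kind == "rel_error_pct", "empirical (95th pct.)", "t-formula prediction"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$n, .data$error_pct, colour = .data$kind, linetype = .data$kind)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Number of gauge readings",
      y = "Relative error of BFI (%)",
      colour = NULL, linetype = NULL,
      title = sprintf(
        "Gauge-method validation (%d replicates, true BFI %.3f)",
        attr(object, "replicates"), attr(object, "true_bfi_thickness")
      )
    ) +
    ggplot2::theme_minimal()
}
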