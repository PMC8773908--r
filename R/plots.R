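# ggplot2 views of the main result types. Class colours follow the
# conventional merged-image palette: linear = yellow (both channels),
# circular = green (PC only), fragment = red (PL only).

circfish_class_colors <- c(linear = "#E6C229", circular = "#2E9E46",
                           fragment = "#C0392B")

#' Plot classified spots in the image plane
#'
#' @param object A `classified_spots` tibble.
#' @param ... Unused.
#' @return A ggplot: x/y positions (um) coloured by RNA class.
#' @method autoplot classified_spots
#' @export
autoplot.classified_spots <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$x_nm / 1000, y = .data$y_nm / 1000,
                 colour = .data$class)
  ) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = circfish_class_colors) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot per-condition means with 95% CIs
#'
#' @param object A `circfish_summary`.
#' @param ... Unused.
#' @return A ggplot: mean molecules per cell by condition, faceted by
#'   class, with 95% CI error bars.
#' @method autoplot circfish_summary
#' @export
autoplot.circfish_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$stats,
    ggplot2::aes(x = .data$condition, y = .data$mean_per_cell,
                 fill = .data$class)
  ) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_per_cell - .data$ci95_halfwidth,
                   ymax = .data$mean_per_cell + .data$ci95_halfwidth),
      width = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::scale_fill_manual(values = circfish_class_colors, guide = "none") +
    ggplot2::labs(x = NULL, y = "molecules per cell (mean ± 95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot a max-projection of one stack channel
#'
#' @param stack An `image_stack`.
#' @param channel Channel name.
#' @return A ggplot raster of the z max-projection.
#' @export
plot_projection <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"), channel %in% names(stack$channels))
  proj <- apply(stack$channels[[channel]], c(2, 3), max)
  df <- tidyr::expand_grid(y = seq_len(nrow(proj)), x = seq_len(ncol(proj)))
  df$intensity <- proj[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(title = channel, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot nuclear/cytoplasmic localisation fractions
#'
#' @param fractions Output of [localization_fractions()].
#' @return A ggplot: stacked nuclear vs cytoplasmic fractions per class
#'   (and condition when present), nuclear fraction with its 95% CI.
#' @export
plot_localization <- function(fractions) {
  long <- fractions |>
    tidyr::pivot_longer(
      c("nuclear_fraction", "cytoplasmic_fraction"),
      names_to = "compartment", values_to = "fraction"
    ) |>
    mutate(compartment = sub("_fraction", "", .data$compartment))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$fraction,
                                          fill = .data$compartment)) +
    ggplot2::geom_col(position = "stack", width = 0.7) +
    ggplot2::geom_errorbar(
      data = fractions,
      ggplot2::aes(x = .data$class,
                   ymin = .data$nuclear_fraction - .data$ci95_halfwidth,
                   ymax = .data$nuclear_fraction + .data$ci95_halfwidth),
      inherit.aes = FALSE, width = 0.2
    ) +
    ggplot2::scale_fill_manual(values = c(nuclear = "#4461A8",
                                          cytoplasmic = "#A8C3E8")) +
    ggplot2::labs(x = NULL, y = "fraction of molecules") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(fractions)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}
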