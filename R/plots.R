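# ggplot2 views of the main result types.

#' Morphospace scatter plot
#'
#' Molecules in the (P, Q) plane, point size by mean stem length S,
#' facetted by region when per-region rows are present.
#'
#' @param stats tibble from [morphospace_stats()].
#' @return A ggplot.
#' @export
plot_morphospace <- function(stats) {
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data$P, y = .data$Q,
                                           size = .data$S)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "base-pairing propensity P",
                  y = "ensemble entropy Q (bits/nt)",
                  size = "mean stem length S") +
    ggplot2::theme_minimal()
  if (length(unique(stats$region)) > 1) {
    p <- p + ggplot2::facet_wrap(~region)
  }
  p
}

#' @export
autoplot.bpp_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(object$n), j = seq_len(object$n))
  df$p <- as.vector(object$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "p(i,j)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.clock_model <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$age_gy)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(x = "relative age (1 - nd/nd_max)", y = "age (Gy)",
                  title = sprintf("molecular clock, R^2 = %.3f",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.parsimony_result <- function(object, ...) {
  nd <- node_distances(object$trees[[1]])
  nd$taxon <- factor(nd$taxon, levels = nd$taxon[order(nd$relative_age)])
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$relative_age, y = .data$taxon)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = "relative age (1 - nd/nd_max)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Timeline plot
#'
#' Ages of timeline entries as lollipops on the Gy axis, coloured by
#' provenance (clock vs interaction anchor).
#'
#' @param timeline a timeline tibble.
#' @return A ggplot.
#' @export
plot_timeline <- function(timeline) {
  tl <- dplyr::arrange(timeline, .data$age_gy)
  tl$unit <- factor(tl$unit, levels = unique(tl$unit))
  ggplot2::ggplot(tl, ggplot2::aes(x = .data$age_gy, y = .data$unit,
                                   colour = .data$provenance)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$age_gy,
                                       yend = .data$unit), alpha = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Gy before present)", y = NULL) +
    ggplot2::theme_minimal()
}
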