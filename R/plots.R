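# ggplot2 views of the result types.

#' Plot an iron speciation result
#' @method autoplot fe_speciation
#' @param object An `fe_speciation` result.
#' @param ... Unused.
#' @export
autoplot.fe_speciation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pool, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of total Fe",
                  title = sprintf("Fe partition at total Fe = %.3g mol/L",
                                  object$total_fe)) +
    ggplot2::theme_minimal()
}

#' Plot transect residuals by class
#' @method autoplot fe_transect
#' @param object An `fe_transect` result.
#' @param ... Unused.
#' @export
autoplot.fe_transect <- function(object, ...) {
  s <- object$samples
  ggplot2::ggplot(s, ggplot2::aes(x = .data$residual_dfe,
                                  y = .data$residual_lpfe,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$inlier_band, linetype = 3) +
    ggplot2::labs(x = "DFe residual (pred - obs, nmol/L)",
                  y = "LPFe residual (pred - obs, nmol/L)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Section plot of a transect field
#'
#' Depth-longitude scatter section of any sample-table column, colour-coded
#' by value, depth increasing downwards.
#'
#' @param data Sample table with `lon`, `depth` and the field.
#' @param field Column name to plot.
#' @return A ggplot object.
#' @export
plot_section <- function(data, field) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$lon, y = .data$depth,
                                     colour = .data[[field]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "longitude (deg E)", y = "depth (m)", colour = field) +
    ggplot2::theme_minimal()
}
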