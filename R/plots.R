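#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_col geom_raster labs facet_wrap theme_minimal scale_fill_viridis_c
#' @export
ggplot2::autoplot

#' Plot a weight scan
#'
#' Strain energy and average RSCC against the map weight, with the selected
#' weight marked.
#'
#' @param object A `qr_weight_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qr_weight_scan <- function(object, ...) {
  tb <- tidy(object)
  long <- tidyr::pivot_longer(tb, c("avg_rscc", "delta_e_str"),
                              names_to = "metric", values_to = "value")
  long$metric <- ifelse(long$metric == "avg_rscc", "average RSCC",
                        "strain energy (kJ/mol)")
  ggplot(long, aes(x = .data$w_x, y = .data$value)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = selected_weight(object), linetype = "dashed") +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "map weight w_x", y = NULL,
         title = sprintf("Weight scan (selected w_x = %g)", selected_weight(object))) +
    theme_minimal()
}

#' Plot a site report
#'
#' Strain energy versus average RSCC per interpretation variant; good
#' interpretations sit low (strain) and right (RSCC).
#'
#' @param object A `qr_site_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qr_site_report <- function(object, ...) {
  tb <- tidy(object)
  ggplot(tb, aes(x = .data$avg_rscc, y = .data$delta_e_str,
                 label = .data$variant)) +
    geom_point(size = 3) +
    ggplot2::geom_text(vjust = -0.8) +
    labs(x = "average RSCC", y = "strain energy (kJ/mol)",
         title = sprintf("Site %s: interpretation comparison", object$site_name)) +
    theme_minimal()
}

#' Plot one section of a map
#'
#' @param m A `qr_map`.
#' @param z Section index along the third (world z) axis; default the middle.
#' @return A ggplot raster of the section.
#' @export
plot_map_section <- function(m, z = NULL) {
  d <- dim(m$values)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- expand.grid(ix = seq_len(d[1]), iy = seq_len(d[2]))
  df$x <- m$origin[1] + (df$ix - 1) * m$voxel_size[1]
  df$y <- m$origin[2] + (df$iy - 1) * m$voxel_size[2]
  df$value <- as.numeric(m$values[, , z])
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "x (A)", y = "y (A)",
         title = sprintf("map section z index %d", z)) +
    theme_minimal()
}
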