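# ggplot2 displays for the pipeline's result types.

#' Plot a pacing-band activity map
#'
#' @param activity An `"activity_map"` matrix from [pixel_activity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_activity_map <- function(activity, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(activity)),
                           col = seq_len(ncol(activity)))
  df$score <- activity[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  fill = "pacing-band\nscore")
}

#' @exportS3Method ggplot2::autoplot
autoplot.shift_map <- function(object, ...) {
  df <- mutate(object,
               cell = ifelse(is.na(.data$shift) & !.data$excitable,
                             "non-excitable", "value"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$dose), factor(.data$tissue))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$shift)) +
    ggplot2::geom_tile(data = filter(df, .data$cell == "non-excitable"),
                       fill = "black") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey90") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "dose", y = "microtissue",
                  fill = expression(shift ~ (sigma[CTR])))
}

#' @exportS3Method ggplot2::autoplot
autoplot.signature_map <- function(object, ...) {
  df <- mutate(object,
               shown = ifelse(.data$significant %in% TRUE, .data$effect_sigma, 0))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$dose), .data$metric,
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "dose", y = NULL,
                  fill = expression(Delta / sigma[CTR]))
}

#' @exportS3Method ggplot2::autoplot
autoplot.restitution_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cycle_length_ms,
                                       .data$mean_apd_ms)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_apd_ms - .data$sd_apd_ms,
      ymax = .data$mean_apd_ms + .data$sd_apd_ms)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pacing cycle length (ms)", y = "APD (ms)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.tri_mxr_slopes <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$dose), .data$slope)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$slope - .data$se,
                                        ymax = .data$slope + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "dose",
                  y = expression(slope ~ of ~ APD[tri] ~ vs ~ APD[MxR]))
}
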