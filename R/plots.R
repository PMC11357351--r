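# Small ggplot2 helpers for visual inspection of fields and fits.

#' Display one channel of a field
#'
#' @param field A field.
#' @param role Channel role to show.
#' @return A ggplot raster of the channel.
#' @export
plot_field <- function(field, role) {
  m <- field_channel(field, role)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- as.numeric(m[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = role, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a growth curve with its log-linear fit
#'
#' @param data Tibble with `time_hr` and `count`.
#' @return A ggplot of log2(normalized count) vs time with the fitted line
#'   and the estimated doubling time in the subtitle.
#' @export
plot_growth_curve <- function(data) {
  fit <- doubling_time(data)
  df <- tibble(time_hr = data$time_hr,
               log2_norm = log2(data$count / data$count[1L]))
  subtitle <- if (fit$non_growing) "non-growing" else
    sprintf("doubling time %.2f h", fit$doubling_time_hr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hr, y = .data$log2_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = expression(log[2] ~ "normalized count"),
                  subtitle = subtitle) +
    ggplot2::theme_minimal()
}
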