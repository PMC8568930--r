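#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a flood hydrograph
#'
#' @param object An `fp_hydrograph`.
#' @param dt Sampling interval, s.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fp_hydrograph <- function(object, dt = 600, ...) {
  df <- hydrograph_series(object, dt)
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 3600, .data$Q)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(x = "time (h)", y = expression(discharge ~ (m^3 / s))) +
    ggplot2::theme_minimal()
}

#' Plot a difference series
#'
#' Case-minus-reference plume-mean differences against time, one panel per
#' variable (salinity, nutrient, phytoplankton), coloured by nutrient
#' multiplier.
#'
#' @param object An `fp_plume_series` from [difference_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fp_plume_series <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$time / 3600, .data$difference,
                               colour = factor(.data$nutrient_mult))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "time (h)", y = "difference from reference",
                  colour = "nutrient x") +
    ggplot2::theme_minimal()
}

#' Plot a regime map
#'
#' Heat map of the extremal plume-mean salinity difference over the SSM
#' multiplier x particle diameter sweep; blue cells are intensified
#' hypopycnal plumes, brown/red cells hyperpycnal ones.
#'
#' @param object An `fp_regime_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fp_regime_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$ssm_mult),
                                   factor(.data$diameter * 1e3),
                                   fill = .data$dS)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$dS)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#8c510a", midpoint = 0) +
    ggplot2::labs(x = "SSM input (x standard)", y = "diameter (mm)",
                  fill = expression(Delta * S ~ (psu))) +
    ggplot2::theme_minimal()
}

#' Plot a vertical section of a model field
#'
#' Quick z-x section of one tracer of a state, for solver QC.
#'
#' @param state An `fp_state`.
#' @param grid An [fp_grid()].
#' @param field Field name (`"S"`, `"T"`, `"C"`, `"N"`, `"P"`, `"Z"`, `"Dt"`).
#' @return A ggplot.
#' @export
plot_section <- function(state, grid, field = "S") {
  f <- state[[field]]
  df <- tidyr::expand_grid(i = seq_len(grid$nx), k = seq_len(grid$nz))
  df$x <- (df$i - 0.5) * grid$dx / 1000
  df$z <- -grid$zc[df$k]
  df$value <- f[cbind(df$i, df$k)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "offshore distance (km)", y = "depth (m)", fill = field) +
    ggplot2::theme_minimal()
}
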