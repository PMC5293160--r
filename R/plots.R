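#' Quiver plot of an empirical vector field
#'
#' Arrows rooted at bin centers, with length equal to half the mean
#' velocity (a display convention that keeps arrows from overlapping; the
#' stored velocities are unscaled) and grey shade encoding the circular
#' variance (black = consistent directions, light = dispersed).
#'
#' @param vf A [estimate_field()] result.
#' @param min_n Hide bins with fewer members.
#' @param arrow_scale Minutes of travel an arrow represents before the
#'   1/2 display scaling (default one frame interval, 20 min).
#' @return A ggplot object.
#' @export
plot_vector_field <- function(vf, min_n = 5, arrow_scale = 20) {
  stopifnot(inherits(vf, "vector_field"))
  f <- vf$field[vf$field$n >= min_n, ]
  f$cx <- f$lo3 + vf$width / 2
  f$cy <- f$lo1 + vf$width / 2
  half <- arrow_scale / 2
  ggplot2::ggplot(f) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$cx, y = .data$cy,
                   xend = .data$cx + .data$v3 * half,
                   yend = .data$cy + .data$v1 * half,
                   colour = .data$circ_var),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))) +
    ggplot2::scale_colour_gradient(low = "black", high = "grey85",
                                   limits = c(0, 1),
                                   name = "circular\nvariance") +
    ggplot2::labs(x = "Gal3p (% of plateau)", y = "Gal1p (% of plateau)") +
    ggplot2::theme_minimal()
}

#' Lag ECDF curves with bootstrap confidence bands
#'
#' @param bands Named list of [ecdf_with_ci()] results (name = condition).
#' @return A ggplot object.
#' @export
plot_ecdf_bands <- function(bands) {
  d <- dplyr::bind_rows(lapply(names(bands), function(nm) {
    b <- bands[[nm]]$band
    b$condition <- nm
    b
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t / 60)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$condition),
                         alpha = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ecdf,
                                    colour = .data$condition)) +
    ggplot2::labs(x = "Induction lag (h)",
                  y = "Fraction of inducing cells") +
    ggplot2::theme_minimal()
}

#' Viability and movement panels
#'
#' @param curves Named list of [viability_curve()] (or
#'   [movement_median()]) tibbles.
#' @param y Column to draw (`"prop"` or `"median_um_min"`).
#' @return A ggplot object.
#' @export
plot_population_curves <- function(curves, y = "prop") {
  d <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    v <- curves[[nm]]
    v$condition <- nm
    v
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min / 60)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$condition),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[y]],
                                    colour = .data$condition)) +
    ggplot2::labs(x = "Time after switch to galactose (h)", y = y) +
    ggplot2::theme_minimal()
}
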