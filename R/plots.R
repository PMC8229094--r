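# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_col labs scale_fill_viridis_c facet_wrap geom_smooth
NULL

#' Plot a field map
#'
#' @param map tibble from [field_map()].
#' @param quantity column to show (`"B"` or `"gradB"`).
#' @return A ggplot.
#' @export
plot_field_map <- function(map, quantity = c("B", "gradB")) {
  quantity <- match.arg(quantity)
  if (quantity == "gradB" && !"gradB" %in% names(map)) {
    abort("map has no gradB column; rerun field_map(gradient = TRUE)")
  }
  lab <- if (quantity == "B") "|B| (T)" else "|grad|B|| (T/m)"
  ggplot(map, aes(x = .data$x * 1e3, y = .data$z * 1e3,
                  fill = .data[[quantity]])) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "x (mm)", y = "z (mm)", fill = lab)
}

#' @export
autoplot.moment_curve <- function(object, ...) {
  ggplot(object, aes(.data$moment_fAm2, 100 * .data$recovery)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = expression(paste("magnetic moment (fA", m^2, ")")),
         y = "recovery (%)")
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  par <- attr(object, "parameter")
  ggplot(object, aes(.data[[par]] * 1e3, 100 * .data$recovery)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = paste0("element ", par, " (mm)"), y = "recovery (%)")
}

#' @export
autoplot.array_comparison <- function(object, ...) {
  ggplot(object$curves,
         aes(.data$moment_fAm2, 100 * .data$recovery, colour = .data$array)) +
    geom_line() +
    labs(x = expression(paste("magnetic moment (fA", m^2, ")")),
         y = "recovery (%)", colour = NULL)
}

#' @export
autoplot.width_height_fit <- function(object, ...) {
  ggplot(object$data,
         aes(.data$channel_height * 1e3, .data$optimal_width * 1e3)) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "grey60") +
    geom_point() +
    labs(x = "channel height (mm)", y = "optimal magnet width (mm)")
}

#' @export
autoplot.fluorescence_histogram <- function(object, ...) {
  ggplot(object, aes(.data$intensity, .data$weight)) +
    geom_col(width = diff(object$intensity[1:2]) * 0.95) +
    labs(x = "fluorescence intensity (a.u.)", y = "fraction of cells")
}
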