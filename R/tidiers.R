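# broom-style accessors for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname fit_scaling
#' @param x a `scaling_fit`.
#' @param ... unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "scale", population = NA_character_, estimate = x$scale,
           unit = "intensity/fAm2"),
    tibble(term = "offset", population = names(x$offsets),
           estimate = unname(x$offsets), unit = "fAm2")
  )
}

#' @rdname fit_scaling
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(residual_sse = x$residual, n_obs = nrow(x$fitted),
         n_populations = length(x$offsets),
         unidentifiable = x$unidentifiable)
}

#' @rdname optimal_width_vs_channel_height
#' @param x a `width_height_fit`.
#' @param ... unused.
#' @export
tidy.width_height_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  tibble(term = c("intercept", "slope"), estimate = unname(co),
         unit = c("m", "m per m of channel height"))
}

#' @rdname optimal_width_vs_channel_height
#' @export
glance.width_height_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_heights = nrow(x$data))
}
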