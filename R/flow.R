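#' Flow channel
#'
#' Shallow rectangular flow cell placed with its thin wall directly against
#' the magnet array. In the model coordinates the array top surface is
#' z = 0, so the channel interior occupies z in \[wall, wall + height\].
#'
#' @param height channel height (m); default 800 um.
#' @param width channel width (m); default 5 mm.
#' @param length channel length (m); default 50 mm.
#' @param wall wall thickness between magnets and fluid (m); default 200 um.
#' @param flow_rate volumetric flow rate (m^3/s); default 1 mL/min.
#' @return An object of class `flow_channel`.
#' @export
#' @examples
#' ch <- flow_channel()
#' ch$v_mean * 1e3  # mean velocity, mm/s
flow_channel <- function(height = 800e-6, width = 5e-3, length = 50e-3,
                         wall = 200e-6, flow_rate = 1e-6 / 60) {
  stopifnot(height > 0, width > 0, length > 0, wall > 0, flow_rate > 0)
  structure(list(height = height, width = width, length = length,
                 wall = wall, flow_rate = flow_rate,
                 area = height * width,
                 v_mean = flow_rate / (height * width)),
            class = "flow_channel")
}

#' @export
print.flow_channel <- function(x, ...) {
  cat(sprintf(
    "<flow_channel: %g x %g x %g mm, wall %g um, Q = %.3g mL/min>\n",
    x$height * 1e3, x$width * 1e3, x$length * 1e3, x$wall * 1e6,
    x$flow_rate * 6e7))
  invisible(x)
}

#' Commercial channel-slide preset
#'
#' Presets for the 50 x 5 mm channel slides with heights of 0.2, 0.4, 0.6 or
#' 0.8 mm and a 200-um bottom wall (Ibidi mu-Slide family).
#'
#' @param height_mm one of 0.2, 0.4, 0.6, 0.8.
#' @param flow_rate volumetric flow rate (m^3/s).
#' @return A [flow_channel()].
#' @export
ibidi_channel <- function(height_mm = 0.8, flow_rate = 1e-6 / 60) {
  if (!height_mm %in% c(0.2, 0.4, 0.6, 0.8)) {
    abort("preset heights are 0.2, 0.4, 0.6 or 0.8 mm")
  }
  flow_channel(height = height_mm * 1e-3, flow_rate = flow_rate)
}

#' Laminar velocity profile
#'
#' Plane-Poiseuille parabola between the two channel walls:
#' `v(z) = 6 v_mean (z/h) (1 - z/h)` with `v_mean = Q / (height * width)`.
#' The side walls are ignored (width/height > 6 for the default channel).
#'
#' @param channel a [flow_channel()].
#' @param z_local height above the inner array-side wall (m), in \[0, height\].
#' @return Streamwise velocity (m/s), same length as `z_local`.
#' @export
velocity_profile <- function(channel, z_local) {
  stopifnot(inherits(channel, "flow_channel"))
  if (any(z_local < 0 | z_local > channel$height)) {
    abort("`z_local` must lie inside the channel, [0, height]")
  }
  s <- z_local / channel$height
  6 * channel$v_mean * s * (1 - s)
}

#' Reynolds number of the channel flow
#'
#' `Re = rho * (Q/A) * D / eta` with the hydraulic diameter of a rectangular
#' duct, `D = 2 h w / (h + w)`. Values below 2000 indicate laminar flow.
#'
#' @param channel a [flow_channel()].
#' @param fluid a [fluid_medium()].
#' @return Reynolds number with attribute `laminar` (logical).
#' @export
#' @examples
#' reynolds_number(flow_channel(), fluid_medium())  # about 6.5
reynolds_number <- function(channel, fluid) {
  stopifnot(inherits(channel, "flow_channel"), inherits(fluid, "fluid_medium"))
  D <- 2 * channel$height * channel$width / (channel$height + channel$width)
  re <- fluid$density * (channel$flow_rate / channel$area) * D / fluid$viscosity
  attr(re, "laminar") <- re < 2000
  re
}
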