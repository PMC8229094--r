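#' Effective magnetization law of a labelled cell
#'
#' The cell plus its bound superparamagnetic particles is treated as a single
#' point-like magnetic entity whose total moment depends on the local field
#' magnitude. Three laws are supported:
#'
#' * `"arctan"` — `m(B) = (2/pi) * m_s * atan(B / Bs)`, an arctangent fit to
#'   the measured magnetization curve of the ferrofluid (`Bs` = 22 mT).
#' * `"saturated"` — `m(B) = m_s` for all `B > 0` (high-field limit).
#' * `"linear"` — `m(B) = (2/pi) * (m_s / Bs) * B`, the low-field tangent of
#'   the arctan curve, uncapped (the constant-susceptibility assumption).
#'
#' @param variant one of `"arctan"`, `"saturated"`, `"linear"`.
#' @param m_s total saturation moment of the cell (Am^2); use [fAm2()] for
#'   the conventional fAm^2 unit.
#' @param Bs shape parameter of the arctangent curve (T), default 0.022.
#' @return An object of class `magnetization_model`.
#' @export
#' @examples
#' mm <- magnetization_model("arctan", m_s = fAm2(10))
#' cell_moment(mm, 0.022) / fAm2(1)  # half the saturation moment
magnetization_model <- function(variant = c("arctan", "saturated", "linear"),
                                m_s = fAm2(10), Bs = 0.022) {
  variant <- match.arg(variant)
  stopifnot(m_s >= 0, Bs > 0)
  structure(list(variant = variant, m_s = m_s, Bs = Bs),
            class = "magnetization_model")
}

#' @export
print.magnetization_model <- function(x, ...) {
  cat(sprintf("<magnetization_model: %s, m_s = %.3g fAm^2, Bs = %.3g mT>\n",
              x$variant, x$m_s * 1e15, x$Bs * 1e3))
  invisible(x)
}

variant_code <- function(variant) {
  match(variant, c("arctan", "saturated", "linear")) - 1L
}

#' Cell moment at a given field magnitude
#'
#' @param model a [magnetization_model()].
#' @param B field magnitude(s), Tesla, non-negative.
#' @return Moment(s) in Am^2.
#' @export
cell_moment <- function(model, B) {
  stopifnot(inherits(model, "magnetization_model"))
  if (any(B < 0)) abort("`B` must be non-negative")
  switch(model$variant,
    arctan = (2 / pi) * model$m_s * atan(B / model$Bs),
    saturated = rep_len(model$m_s, length(B)),
    linear = (2 / pi) * (model$m_s / model$Bs) * B
  )
}

#' Magnetization curve table
#'
#' Convenience export of `m(B)` on a field grid, for plots in the style of a
#' measured ferrofluid magnetization curve and its approximations.
#'
#' @param model a [magnetization_model()].
#' @param B field grid (T).
#' @return Tibble with `B_T` and `moment_fAm2`.
#' @export
magnetization_curve <- function(model, B = seq(0, 0.5, length.out = 201)) {
  tibble(B_T = B, moment_fAm2 = cell_moment(model, B) * 1e15)
}

#' Cell model
#'
#' @param radius cell radius (m); default 5 um (10 um diameter spheres).
#' @param density cell density (kg/m^3); default 1077.
#' @param magnetization a [magnetization_model()].
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(radius = 5e-6, density = 1077,
                       magnetization = magnetization_model()) {
  stopifnot(radius > 0, density > 0,
            inherits(magnetization, "magnetization_model"))
  structure(list(radius = radius, density = density,
                 magnetization = magnetization,
                 volume = 4 / 3 * pi * radius^3),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model: r = %.3g um, rho = %.0f kg/m^3, %s m_s = %.3g fAm^2>\n",
              x$radius * 1e6, x$density, x$magnetization$variant,
              x$magnetization$m_s * 1e15))
  invisible(x)
}

#' Fluid medium
#'
#' @param viscosity dynamic viscosity (Pa s); default 0.89 mPa s (water-like
#'   buffer at room temperature).
#' @param density fluid density (kg/m^3); default 1000.
#' @return An object of class `fluid_medium`.
#' @export
fluid_medium <- function(viscosity = 8.9e-4, density = 1000) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_medium")
}

#' Magnetic force on a cell
#'
#' With the cell moment parallel to the local field, the force is
#' `F = m(|B|) * grad|B|`, evaluated with the field-magnitude gradient of
#' [grad_bmag_at()].
#'
#' @inheritParams field_at
#' @param cell a [cell_model()].
#' @return Tibble with force components `Fx`, `Fz` (N) and the local `B`.
#' @export
magnetic_force <- function(points, array, cell) {
  stopifnot(inherits(cell, "cell_model"))
  pts <- as_points(points)
  f <- field_at(pts, array)
  g <- grad_bmag_at(pts, array)
  m <- cell_moment(cell$magnetization, f$B)
  as_tibble(pts) |>
    mutate(B = f$B, Fx = m * g$dBdx, Fz = m * g$dBdz)
}

#' Gravitational (minus buoyancy) force on a cell
#'
#' `|Fg| = g * Vp * (rho_c - rho_f)`. The sign convention is that of the
#' channel geometry: gravity points toward the magnet array (negative z), so
#' a cell denser than the fluid gets a negative value.
#'
#' @param cell a [cell_model()].
#' @param fluid a [fluid_medium()].
#' @return Signed force (N) on the z axis.
#' @export
gravitational_force <- function(cell, fluid) {
  stopifnot(inherits(cell, "cell_model"), inherits(fluid, "fluid_medium"))
  -GRAV * cell$volume * (cell$density - fluid$density)
}

#' Quasi-static (Stokes) velocity from a force
#'
#' The overdamped balance of Stokes drag `Fd = 6 pi eta r (vp - vf)` against
#' an applied force gives the relative velocity `v = F / (6 pi eta r)`.
#'
#' @param force data frame with `Fx`, `Fz` (N), or a length-2 numeric.
#' @param cell a [cell_model()].
#' @param fluid a [fluid_medium()].
#' @return Tibble with `vx`, `vz` (m/s).
#' @export
stokes_velocity <- function(force, cell, fluid) {
  stopifnot(inherits(cell, "cell_model"), inherits(fluid, "fluid_medium"))
  if (is.numeric(force) && length(force) == 2) {
    force <- tibble(Fx = force[1], Fz = force[2])
  }
  drag <- 6 * pi * fluid$viscosity * cell$radius
  as_tibble(force) |>
    mutate(vx = .data$Fx / drag, vz = .data$Fz / drag)
}
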