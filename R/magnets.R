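#' Rectangular permanent magnet (2D cross-section)
#'
#' Describes one uniformly magnetized rectangular magnet in the 2D model
#' plane. The magnet is treated as infinitely long across the channel width.
#' The magnetization magnitude follows from the remanence, `|M| = Br / mu0`.
#'
#' @param x_min,x_max extent along the flow axis (m).
#' @param z_min,z_max extent normal to the channel (m); the channel side is
#'   at larger z, and arrays are built with top faces at z = 0.
#' @param Mx,Mz magnetization components (A/m). Exactly one of the two is
#'   nonzero for the axis-aligned arrays modelled here.
#' @return A one-row tibble of class `magnet_rect`.
#' @export
#' @examples
#' magnet_rect(0, 1e-3, -1.5e-3, 0, Mz = 1.35 / (4e-7 * pi))
magnet_rect <- function(x_min, x_max, z_min, z_max, Mx = 0, Mz = 0) {
  stopifnot(x_max > x_min, z_max > z_min)
  if ((Mx != 0) == (Mz != 0)) {
    abort("exactly one of `Mx`, `Mz` must be nonzero (axis-aligned magnetization)")
  }
  out <- tibble(x_min = x_min, x_max = x_max, z_min = z_min, z_max = z_max,
                Mx = Mx, Mz = Mz)
  class(out) <- c("magnet_rect", class(out))
  out
}

# remanence (T) of common sintered NdFeB grades; datasheet mid-values
GRADE_BR <- c(N52 = 1.45, N45 = 1.35)

#' Remanence of an NdFeB magnet grade
#'
#' @param grade character, e.g. `"N52"` or `"N45"`.
#' @return Remanence Br in Tesla.
#' @export
grade_remanence <- function(grade) {
  if (!grade %in% names(GRADE_BR)) {
    abort(paste0("unknown magnet grade '", grade, "'; known: ",
                 paste(names(GRADE_BR), collapse = ", ")))
  }
  unname(GRADE_BR[[grade]])
}

new_magnet_array <- function(elements, pattern, element_width, heights, Br,
                             span, phase) {
  structure(
    list(elements = elements, pattern = pattern,
         element_width = element_width, heights = heights, Br = Br,
         span = span, phase = phase),
    class = "magnet_array"
  )
}

#' @export
print.magnet_array <- function(x, ...) {
  cat(sprintf("<magnet_array: %s>\n", x$pattern))
  cat(sprintf("  %d elements, width %.3g mm, span [%.1f, %.1f] mm\n",
              nrow(x$elements), x$element_width * 1e3,
              x$span[1] * 1e3, x$span[2] * 1e3))
  cat(sprintf("  heights %s mm, Br = %.2f T, phase %d\n",
              paste(format(x$heights * 1e3, digits = 3), collapse = "/"),
              x$Br, x$phase))
  invisible(x)
}

# tile [span] with n = ceiling elements of width w, centered on the span
tile_span <- function(span, w) {
  len <- span[2] - span[1]
  if (len < 4 * w - 1e-12) {
    abort("span must cover at least one period (4 elements) of the array")
  }
  n <- as.integer(ceiling(len / w - 1e-9))
  mid <- (span[1] + span[2]) / 2
  x_start <- mid - n * w / 2
  list(n = n, x_left = x_start + (seq_len(n) - 1) * w, mid = mid)
}

halbach_elements <- function(tl, w, h_vert, h_horz, M, sense, phase) {
  # direction index d: 0 -> Mz = +M, 1 -> Mx = sense*M, 2 -> Mz = -M,
  # 3 -> Mx = -sense*M; the element containing the span midpoint has d = 0
  # at phase 0 (vertical, strong-side-up).
  i_center <- findInterval(tl$mid, c(tl$x_left, tl$x_left[tl$n] + w),
                           rightmost.closed = TRUE)
  d <- (seq_len(tl$n) - i_center + phase) %% 4
  vert <- d %% 2 == 0
  h <- ifelse(vert, h_vert, h_horz)
  tibble(
    x_min = tl$x_left, x_max = tl$x_left + w, z_min = -h, z_max = 0,
    Mx = ifelse(vert, 0, ifelse(d == 1, sense * M, -sense * M)),
    Mz = ifelse(vert, ifelse(d == 0, M, -M), 0)
  )
}

# mean |B| along one period at 0.5 mm above the top faces and 0.5 mm below
# the deepest bottom face (used to orient the strong side)
side_means <- function(elements, mid, w, pattern) {
  period <- if (pattern == "halbach") 4 * w else 2 * w
  xs <- seq(mid - period / 2, mid + period / 2, length.out = 33)
  segs <- segments_matrix_elements(elements)
  z_above <- 5e-4
  z_below <- min(elements$z_min) - 5e-4
  above <- cpp_field(segs, xs, rep(z_above, length(xs)))
  below <- cpp_field(segs, xs, rep(z_below, length(xs)))
  c(above = mean(sqrt(rowSums(above^2))), below = mean(sqrt(rowSums(below^2))))
}

#' Build a 4-phase Halbach array
#'
#' Elements of width `element_width` tile the span; the magnetization angle
#' steps by 90 degrees per element. The rotation sense is chosen
#' automatically so that the strong side faces the channel (z > 0): the mean
#' field 0.5 mm above the array exceeds the mean field 0.5 mm below it.
#' Vertically and horizontally magnetized elements may have different
#' heights; all top faces are flush at z = 0, against the channel wall.
#'
#' @param element_width magnet width along the flow axis (m).
#' @param h_vert,h_horz heights (m) of the vertically / horizontally
#'   magnetized elements.
#' @param Br remanence (T); see [grade_remanence()].
#' @param span `c(x_start, x_end)` (m). The default extends a 50 mm channel
#'   at x in \[0, 50\] mm by a 10 mm margin on each side.
#' @param phase integer; shifts the element pattern by whole elements.
#'   Phase 0 places a vertically magnetized, strong-side-up element at the
#'   span midpoint.
#' @return A `magnet_array` object.
#' @export
#' @examples
#' arr <- halbach_array(1e-3, 2.75e-3, 2e-3, Br = 1.45)
#' arr
halbach_array <- function(element_width, h_vert = 2.75e-3, h_horz = 2e-3,
                          Br = 1.45, span = c(-10e-3, 60e-3), phase = 0L) {
  stopifnot(element_width > 0, h_vert > 0, h_horz > 0, Br > 0)
  M <- Br / MU0
  tl <- tile_span(span, element_width)
  el_pos <- halbach_elements(tl, element_width, h_vert, h_horz, M, 1, phase)
  el_neg <- halbach_elements(tl, element_width, h_vert, h_horz, M, -1, phase)
  rp <- side_means(el_pos, tl$mid, element_width, "halbach")
  rn <- side_means(el_neg, tl$mid, element_width, "halbach")
  el <- if (rp[["above"]] / rp[["below"]] >= rn[["above"]] / rn[["below"]]) {
    el_pos
  } else {
    el_neg
  }
  new_magnet_array(el, "halbach", element_width,
                   c(vertical = h_vert, horizontal = h_horz), Br,
                   range(el$x_min, el$x_max), as.integer(phase))
}

#' Build a conventional alternating array
#'
#' All elements are vertically magnetized with the sign flipping each
#' element. The field of this pattern is mirror-symmetric: both sides of the
#' array see the same field strength, unlike a Halbach array.
#'
#' @param element_width magnet width (m).
#' @param height element height (m). The default 2.375 mm is the mean of
#'   the optimized Halbach heights, giving an equal-magnet-volume
#'   comparison at twice the element width.
#' @inheritParams halbach_array
#' @return A `magnet_array` object.
#' @export
alternating_array <- function(element_width, height = 2.375e-3, Br = 1.45,
                              span = c(-10e-3, 60e-3), phase = 0L) {
  stopifnot(element_width > 0, height > 0, Br > 0)
  M <- Br / MU0
  tl <- tile_span(span, element_width)
  i_center <- findInterval(tl$mid, c(tl$x_left, tl$x_left[tl$n] + element_width),
                           rightmost.closed = TRUE)
  sgn <- ifelse((seq_len(tl$n) - i_center + phase) %% 2 == 0, 1, -1)
  el <- tibble(x_min = tl$x_left, x_max = tl$x_left + element_width,
               z_min = -height, z_max = 0, Mx = 0, Mz = sgn * M)
  new_magnet_array(el, "alternating", element_width, c(height = height), Br,
                   range(el$x_min, el$x_max), as.integer(phase))
}

# surface-charge segments of a set of elements:
# (type, a1, a2, pos, coef) with coef = mu0 * sigma / (2*pi)
segments_matrix_elements <- function(el) {
  segs <- list()
  cz <- el$Mz != 0
  if (any(cz)) {
    e <- el[cz, ]
    segs[[length(segs) + 1]] <- cbind(0, e$x_min, e$x_max, e$z_max,
                                      MU0 * e$Mz / (2 * pi))
    segs[[length(segs) + 1]] <- cbind(0, e$x_min, e$x_max, e$z_min,
                                      -MU0 * e$Mz / (2 * pi))
  }
  cx <- el$Mx != 0
  if (any(cx)) {
    e <- el[cx, ]
    segs[[length(segs) + 1]] <- cbind(1, e$z_min, e$z_max, e$x_max,
                                      MU0 * e$Mx / (2 * pi))
    segs[[length(segs) + 1]] <- cbind(1, e$z_min, e$z_max, e$x_min,
                                      -MU0 * e$Mx / (2 * pi))
  }
  do.call(rbind, segs)
}

segments_matrix <- function(array) {
  if (inherits(array, "magnet_array")) return(segments_matrix_elements(array$elements))
  if (inherits(array, "magnet_rect") || is.data.frame(array)) {
    return(segments_matrix_elements(array))
  }
  abort("`array` must be a magnet_array or magnet_rect")
}

as_points <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "z") %in% names(points)))
    points
  } else if (is.numeric(points) && length(points) == 2) {
    tibble(x = points[1], z = points[2])
  } else {
    abort("`points` must be a data frame with columns x, z (or a length-2 numeric)")
  }
}

#' Magnetic flux density of an array at points
#'
#' Evaluates the closed-form field of the equivalent surface-charge sheets
#' of every element (sheets carry charge `M . n` on the faces where the
#' magnetization meets the surface), summed over elements. Valid outside the
#' magnet bodies; points within 1 nm of a sheet corner are nudged 1 nm to
#' avoid the logarithmic corner singularity.
#'
#' @param points data frame with columns `x`, `z` (m), or a length-2 numeric.
#' @param array a `magnet_array` or `magnet_rect`.
#' @return The input points as a tibble with columns `Bx`, `Bz`, `B` (Tesla).
#' @export
#' @examples
#' arr <- halbach_array(1e-3, 2.75e-3, 2e-3)
#' field_at(data.frame(x = 25e-3, z = 3e-4), arr)
field_at <- function(points, array) {
  pts <- as_points(points)
  f <- cpp_field(segments_matrix(array), pts$x, pts$z)
  as_tibble(pts) |>
    mutate(Bx = f[, 1], Bz = f[, 2], B = sqrt(.data$Bx^2 + .data$Bz^2))
}

#' Gradient of the field magnitude
#'
#' Central finite differences of `|B|` with step `h` (default 1 um). At a
#' point where `|B| = 0` the two-sided difference is still returned but the
#' point is flagged `degenerate` (the gradient of a magnitude is undefined
#' at a zero).
#'
#' @inheritParams field_at
#' @param h finite-difference step (m).
#' @return Tibble with columns `dBdx`, `dBdz` (T/m) and `degenerate`.
#' @export
grad_bmag_at <- function(points, array, h = 1e-6) {
  pts <- as_points(points)
  segs <- segments_matrix(array)
  bm <- function(x, z) {
    f <- cpp_field(segs, x, z)
    sqrt(f[, 1]^2 + f[, 2]^2)
  }
  b0 <- bm(pts$x, pts$z)
  dBdx <- (bm(pts$x + h, pts$z) - bm(pts$x - h, pts$z)) / (2 * h)
  dBdz <- (bm(pts$x, pts$z + h) - bm(pts$x, pts$z - h)) / (2 * h)
  as_tibble(pts) |>
    mutate(dBdx = dBdx, dBdz = dBdz, degenerate = b0 == 0)
}

#' Field map over a rectangular region
#'
#' @param array a `magnet_array`.
#' @param xlim,zlim region limits (m).
#' @param nx,nz grid resolution.
#' @param gradient also compute `|grad |B||` by finite differences.
#' @return Tibble with one row per grid node: `x`, `z`, `Bx`, `Bz`, `B` and,
#'   if requested, `gradB`.
#' @export
field_map <- function(array, xlim = c(20e-3, 30e-3), zlim = c(2e-4, 1e-3),
                      nx = 101, nz = 41, gradient = TRUE) {
  grid <- tidyr::expand_grid(x = seq(xlim[1], xlim[2], length.out = nx),
                             z = seq(zlim[1], zlim[2], length.out = nz))
  out <- field_at(grid, array)
  if (gradient) {
    g <- grad_bmag_at(grid, array)
    out$gradB <- sqrt(g$dBdx^2 + g$dBdz^2)
  }
  out
}
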