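# Independent oracles used across the suite.

MU0_T <- 4e-7 * pi

# Field of uniformly magnetized rectangles by adaptive quadrature over the
# equivalent charge sheets (independent of the package's closed form).
oracle_field <- function(elements, x, z, rel.tol = 1e-12) {
  Bx <- 0
  Bz <- 0
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    if (el$Mz != 0) {
      for (sheet in list(c(el$z_max, el$Mz), c(el$z_min, -el$Mz))) {
        z0 <- sheet[1]
        c0 <- MU0_T * sheet[2] / (2 * pi)
        Bx <- Bx + integrate(function(xp) c0 * (x - xp) / ((x - xp)^2 + (z - z0)^2),
                             el$x_min, el$x_max, rel.tol = rel.tol)$value
        Bz <- Bz + integrate(function(xp) c0 * (z - z0) / ((x - xp)^2 + (z - z0)^2),
                             el$x_min, el$x_max, rel.tol = rel.tol)$value
      }
    }
    if (el$Mx != 0) {
      for (sheet in list(c(el$x_max, el$Mx), c(el$x_min, -el$Mx))) {
        x0 <- sheet[1]
        c0 <- MU0_T * sheet[2] / (2 * pi)
        Bx <- Bx + integrate(function(zp) c0 * (x - x0) / ((x - x0)^2 + (z - zp)^2),
                             el$z_min, el$z_max, rel.tol = rel.tol)$value
        Bz <- Bz + integrate(function(zp) c0 * (z - zp) / ((x - x0)^2 + (z - zp)^2),
                             el$z_min, el$z_max, rel.tol = rel.tol)$value
      }
    }
  }
  c(Bx = Bx, Bz = Bz)
}

oracle_bmag <- function(elements, x, z) {
  b <- oracle_field(elements, x, z)
  sqrt(sum(b^2))
}

# small three-element Halbach-like fixture for oracle comparisons
mini_elements <- function() {
  M <- 1.35 / MU0_T
  tibble::tibble(
    x_min = c(0, 1e-3, 2e-3), x_max = c(1e-3, 2e-3, 3e-3),
    z_min = c(-1.5e-3, -1e-3, -1.5e-3), z_max = 0,
    Mx = c(0, M, 0), Mz = c(M, 0, -M))
}

mini_array <- function() {
  structure(list(elements = mini_elements(), pattern = "halbach",
                 element_width = 1e-3,
                 heights = c(vertical = 1.5e-3, horizontal = 1e-3),
                 Br = 1.35, span = c(0, 3e-3), phase = 0L),
            class = "magnet_array")
}

# reference arrays of the study
optimized_halbach <- function() halbach_array(1e-3, 2.75e-3, 2e-3, Br = 1.45)
stock_halbach <- function() halbach_array(1e-3, 1.5e-3, 1.5e-3, Br = 1.35)
big_halbach <- function() halbach_array(4e-3, 4e-3, 4e-3, Br = 1.35)
optimized_alternating <- function() alternating_array(2e-3, 2.375e-3, Br = 1.45)

cell_with_moment <- function(ms_fAm2, variant = "arctan", density = 1077) {
  cell_model(density = density,
             magnetization = magnetization_model(variant, fAm2(ms_fAm2)))
}
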