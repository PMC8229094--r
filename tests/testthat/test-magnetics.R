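test_that("closed-form field matches charge-sheet quadrature", {
  # single magnet, point above the center of the top face
  m <- magnet_rect(0, 1e-3, -1.5e-3, 0, Mz = 1.45 / (4e-7 * pi))
  got <- field_at(data.frame(x = 0.5e-3, z = 0.2e-3), m)
  ref <- oracle_field(m, 0.5e-3, 0.2e-3)
  expect_equal(got$Bz, ref[["Bz"]], tolerance = 1e-6)
  expect_lt(abs(got$Bx - ref[["Bx"]]), 1e-6 * abs(ref[["Bz"]]))

  # random exterior points around a mixed-orientation mini array
  el <- mini_elements()
  arr <- mini_array()
  set.seed(42)
  pts <- data.frame(x = runif(25, -2e-3, 5e-3),
                    z = c(runif(13, 1e-5, 3e-3), runif(12, -4.5e-3, -1.6e-3)))
  got <- field_at(pts, arr)
  for (i in seq_len(nrow(pts))) {
    ref <- oracle_field(el, pts$x[i], pts$z[i])
    expect_equal(c(got$Bx[i], got$Bz[i]), unname(ref), tolerance = 1e-6)
  }
})

test_that("field symmetry and far-field decay", {
  m <- magnet_rect(-0.5e-3, 0.5e-3, -1.5e-3, 0, Mz = 1.45 / (4e-7 * pi))
  on_axis <- field_at(data.frame(x = 0, z = c(1e-4, 5e-4, 2e-3)), m)
  expect_true(all(abs(on_axis$Bx) < 1e-12 * on_axis$B))
  far <- field_at(data.frame(x = 0, z = 1), optimized_halbach())
  expect_lt(far$B, 1e-4)
})

test_that("array field is the superposition of element fields", {
  arr <- mini_array()
  pts <- data.frame(x = c(0.2e-3, 1.5e-3, 4e-3), z = c(2e-4, 1e-3, 5e-4))
  whole <- field_at(pts, arr)
  parts <- lapply(seq_len(3), function(i) field_at(pts, arr$elements[i, ]))
  expect_equal(whole$Bx, parts[[1]]$Bx + parts[[2]]$Bx + parts[[3]]$Bx,
               tolerance = 1e-12)
  expect_equal(whole$Bz, parts[[1]]$Bz + parts[[2]]$Bz + parts[[3]]$Bz,
               tolerance = 1e-12)
})

test_that("field is divergence- and curl-free outside the magnets", {
  arr <- optimized_halbach()
  h <- 1e-6
  pts <- data.frame(x = c(24.3e-3, 25.1e-3, 26.7e-3), z = 3e-4)
  for (i in seq_len(nrow(pts))) {
    x <- pts$x[i]; z <- pts$z[i]
    fx <- function(dx, dz) field_at(data.frame(x = x + dx, z = z + dz), arr)
    dBx_dx <- (fx(h, 0)$Bx - fx(-h, 0)$Bx) / (2 * h)
    dBz_dz <- (fx(0, h)$Bz - fx(0, -h)$Bz) / (2 * h)
    dBx_dz <- (fx(0, h)$Bx - fx(0, -h)$Bx) / (2 * h)
    dBz_dx <- (fx(h, 0)$Bz - fx(-h, 0)$Bz) / (2 * h)
    scale <- max(abs(c(dBx_dx, dBz_dz, dBx_dz, dBz_dx)))
    expect_lt(abs(dBx_dx + dBz_dz) / scale, 1e-3)
    expect_lt(abs(dBx_dz - dBz_dx) / scale, 1e-3)
  }
})

test_that("halbach builder tiles the span with the stated geometry", {
  arr <- halbach_array(1e-3, 2.75e-3, 2e-3, Br = 1.45, span = c(-10e-3, 60e-3))
  el <- arr$elements
  expect_equal(nrow(el), 70)
  expect_equal(el$x_min[-1], el$x_max[-70])             # no gaps or overlaps
  expect_true(all(el$z_max == 0))                       # top-aligned
  vert <- el$Mz != 0
  expect_equal(unique(el$z_min[vert]), -2.75e-3)
  expect_equal(unique(el$z_min[!vert]), -2e-3)
  expect_equal(sum(vert), 35)
  # magnetization magnitude Br/mu0 on every element
  expect_equal(sqrt(el$Mx^2 + el$Mz^2), rep(1.45 / (4e-7 * pi), 70),
               tolerance = 1e-9)
  # degenerate span
  expect_error(halbach_array(1e-3, span = c(0, 3e-3)), "period")
})

test_that("halbach arrays are one-sided, alternating arrays are not", {
  for (arr in list(optimized_halbach(), stock_halbach(), big_halbach())) {
    w <- arr$element_width
    xs <- seq(25e-3 - 2 * w, 25e-3 + 2 * w, length.out = 33)
    above <- field_at(data.frame(x = xs, z = 5e-4), arr)
    below <- field_at(data.frame(x = xs, z = min(arr$elements$z_min) - 5e-4), arr)
    expect_gt(mean(above$B), mean(below$B))
  }
  expect_gt(local({
    arr <- optimized_halbach()
    xs <- seq(23e-3, 27e-3, length.out = 33)
    mean(field_at(data.frame(x = xs, z = 5e-4), arr)$B) /
      mean(field_at(data.frame(x = xs, z = -2.75e-3 - 5e-4), arr)$B)
  }), 2)
  alt <- optimized_alternating()
  xs <- seq(21e-3, 29e-3, length.out = 33)
  up <- field_at(data.frame(x = xs, z = 5e-4), alt)
  dn <- field_at(data.frame(x = xs, z = -2.375e-3 - 5e-4), alt)
  expect_equal(up$B, dn$B, tolerance = 1e-9)
})

test_that("alternating builder flips sign each element, volume-matched", {
  alt <- alternating_array(2e-3, 2.375e-3, Br = 1.45)
  el <- alt$elements
  expect_true(all(el$Mx == 0))
  expect_equal(el$Mz[-1], -el$Mz[-nrow(el)])
  expect_equal(abs(el$Mz), rep(1.45 / (4e-7 * pi), nrow(el)), tolerance = 1e-9)
  # cross-section 2 x 2.375 mm = 4.75 mm^2 equals two optimized Halbach
  # elements (1 mm wide, heights 2.75 and 2 mm)
  expect_equal(2e-3 * 2.375e-3, 1e-3 * 2.75e-3 + 1e-3 * 2e-3)
})

test_that("field is periodic mid-span with the pattern period", {
  arr <- optimized_halbach()
  per <- 4 * arr$element_width
  b1 <- field_at(data.frame(x = 24e-3, z = 4e-4), arr)$B
  b2 <- field_at(data.frame(x = 24e-3 + per, z = 4e-4), arr)$B
  expect_equal(b1, b2, tolerance = 1e-3)
  alt <- optimized_alternating()
  a1 <- field_at(data.frame(x = 24e-3, z = 4e-4), alt)$B
  a2 <- field_at(data.frame(x = 24e-3 + 2 * alt$element_width, z = 4e-4), alt)$B
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("phase shift by two elements negates the field (half period)", {
  a0 <- halbach_array(1e-3, 2.75e-3, 2e-3, phase = 0L)
  a2 <- halbach_array(1e-3, 2.75e-3, 2e-3, phase = 2L)
  pt <- data.frame(x = c(24.2e-3, 25.7e-3), z = c(3e-4, 8e-4))
  f0 <- field_at(pt, a0)
  f2 <- field_at(pt, a2)
  expect_equal(f2$Bx, -f0$Bx, tolerance = 1e-12)
  expect_equal(f2$Bz, -f0$Bz, tolerance = 1e-12)
  # equivalently a translation by two element widths, up to end effects
  ft <- field_at(data.frame(x = pt$x + 2e-3, z = pt$z), a0)
  expect_equal(f2$B, ft$B, tolerance = 1e-2)
})

test_that("finite-difference gradient of |B| matches the analytic derivative", {
  arr <- optimized_halbach()
  pts <- data.frame(x = c(24.5e-3, 25e-3, 25.25e-3), z = 4e-4)
  fd <- grad_bmag_at(pts, arr)
  an <- magsep:::cpp_field(magsep:::segments_matrix(arr), pts$x, pts$z,
                           deriv = TRUE)
  B <- sqrt(an[, 1]^2 + an[, 2]^2)
  gx <- (an[, 1] * an[, 3] + an[, 2] * an[, 4]) / B
  gz <- (an[, 1] * an[, 4] - an[, 2] * an[, 3]) / B
  expect_equal(fd$dBdx, gx, tolerance = 1e-4)
  expect_equal(fd$dBdz, gz, tolerance = 1e-4)
  expect_false(any(fd$degenerate))
})

test_that("gradient vanishes by symmetry between mirror-image magnets", {
  M <- 1.45 / (4e-7 * pi)
  pair <- dplyr::bind_rows(
    magnet_rect(-2e-3, -1e-3, -1.5e-3, 0, Mz = M),
    magnet_rect(1e-3, 2e-3, -1.5e-3, 0, Mz = M))
  g <- grad_bmag_at(data.frame(x = 0, z = 5e-4), pair)
  expect_lt(abs(g$dBdx), 1e-6 * abs(g$dBdz))
})

test_that("smaller elements give larger gradients near the surface", {
  h2 <- halbach_array(2e-3, 2.375e-3, 2.375e-3)
  h4 <- halbach_array(4e-3, 2.375e-3, 2.375e-3)
  # x at an element junction of each array, 0.3 mm standoff
  jx2 <- h2$elements$x_max[which.min(abs(h2$elements$x_max - 25e-3))]
  jx4 <- h4$elements$x_max[which.min(abs(h4$elements$x_max - 25e-3))]
  g2 <- grad_bmag_at(data.frame(x = jx2, z = 3e-4), h2)
  g4 <- grad_bmag_at(data.frame(x = jx4, z = 3e-4), h4)
  expect_gt(sqrt(g2$dBdx^2 + g2$dBdz^2), sqrt(g4$dBdx^2 + g4$dBdz^2))
})
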