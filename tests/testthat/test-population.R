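# toy recovery curves (piecewise linear, plateau at 1) used through the
# population tests; cheap stand-ins with the shape of simulated curves
toy_curve <- function(thr) {
  tibble::tibble(moment_fAm2 = 1:40,
                 recovery = pmin(1, pmax(0, (1:40 - 1) / (thr - 1))))
}

test_that("intensity-to-moment mapping scales, offsets and clamps", {
  h <- fluorescence_histogram(c(1200, 3600), c(0.5, 0.5))
  m <- intensity_to_moments(h, scale = 120, offset = -6.5)
  expect_equal(m$moment_fAm2, c(3.5, 23.5))
  expect_equal(sum(m$weight), 1)
  # identity mapping
  id <- intensity_to_moments(fluorescence_histogram(1:5, rep(0.2, 5)), 1, 0)
  expect_equal(id$moment_fAm2, as.numeric(1:5))
  # everything below the background clamps to zero
  lo <- intensity_to_moments(h, scale = 120, offset = -40)
  expect_equal(lo$moment_fAm2, c(0, 0))
  expect_equal(sum(lo$weight), 1)  # weights conserved through clamping
})

test_that("population recovery is the weight-averaged interpolated curve", {
  cv3 <- tibble::tibble(moment_fAm2 = c(0, 10, 20), recovery = c(0, 0.5, 1))
  h <- fluorescence_histogram(c(1200, 3600), c(0.5, 0.5))
  # moments 3.5 and 23.5: R = 0.175 (interpolated) and 1 (plateau)
  got <- predict_population_recovery(h, cv3, scale = 120, offset = -6.5)
  expect_equal(got, 0.5 * 0.175 + 0.5 * 1)
  # all above threshold
  expect_equal(predict_population_recovery(h, toy_curve(15), 120, 100), 1)
  # all clamped to zero with zero recovery at zero moment
  expect_equal(predict_population_recovery(h, cv3, 120, -40), 0)
  expect_equal(predict_population_recovery(h, toy_curve(15), 120, -40,
                                           recovery_zero = 0.02), 0.02)
})

test_that("population recovery is monotone in offset and in 1/scale", {
  h <- synthesize_histogram(n_cells = 5000, seed = 7)
  cv <- toy_curve(15)
  offs <- seq(-20, 5, length.out = 8)
  ro <- vapply(offs, function(o) predict_population_recovery(h, cv, 120, o),
               numeric(1))
  expect_true(all(diff(ro) >= 0))
  scales <- c(60, 120, 240, 480)
  rs <- vapply(scales, function(s) predict_population_recovery(h, cv, s, -12),
               numeric(1))
  expect_true(all(diff(rs) <= 0))
})

test_that("synthetic histograms are reproducible and well-formed", {
  h1 <- synthesize_histogram(n_cells = 2000, seed = 11)
  h2 <- synthesize_histogram(n_cells = 2000, seed = 11)
  expect_identical(h1, h2)
  expect_false(identical(h1, synthesize_histogram(n_cells = 2000, seed = 12)))
  expect_equal(sum(h1$weight), 1)
  expect_true(all(diff(h1$intensity) > 0))
  # unlabeled sample is just the control peak
  h0 <- synthesize_histogram(n_cells = 20000, labeled_fraction = 0,
                             control_peak = 1440, control_width = 400,
                             seed = 3)
  expect_equal(sum(h0$intensity * h0$weight), 1440, tolerance = 0.02)
  # labeled mean matches control + log-normal mean within sampling error
  hl <- synthesize_histogram(n_cells = 20000, meanlog = log(2400),
                             sdlog = 1.1, seed = 4)
  expected <- 1440 + 2400 * exp(1.1^2 / 2)
  sdm <- 2400 * sqrt(exp(1.1^2) * (exp(1.1^2) - 1)) / sqrt(20000)
  expect_lt(abs(sum(hl$intensity * hl$weight) - expected),
            3 * sdm + 30)  # 30: binning quantization
})

test_that("scaling fit recovers known parameters on synthetic data", {
  curves <- list(weak = toy_curve(24), strong = toy_curve(11))
  truth_scale <- 120
  truth_offsets <- c(popA = -12, popB = -6.5)
  for (seed in 1:5) {
    hists <- list(
      popA = synthesize_histogram(n_cells = 8000, meanlog = log(1500),
                                  seed = seed),
      popB = synthesize_histogram(n_cells = 8000, meanlog = log(3600),
                                  seed = seed + 100))
    measured <- tidyr::expand_grid(population = c("popA", "popB"),
                                   array = c("weak", "strong"))
    measured$recovery <- mapply(function(p, a) {
      predict_population_recovery(hists[[p]], curves[[a]], truth_scale,
                                  truth_offsets[[p]])
    }, measured$population, measured$array)
    fit <- fit_scaling(hists, measured, curves)
    expect_lt(abs(fit$scale / truth_scale - 1), 0.10)
    expect_lt(max(abs(fit$offsets - truth_offsets)), 1)
    expect_lt(fit$residual, 1e-4)
  }
})

test_that("adding a constant intensity shifts the offset, not the scale", {
  curves <- list(weak = toy_curve(24), strong = toy_curve(11))
  shift <- 600
  h1 <- synthesize_histogram(n_cells = 8000, meanlog = log(2000), seed = 21)
  h2 <- fluorescence_histogram(h1$intensity + shift, h1$weight)
  # reparameterization identity: same predictions after offset compensation
  expect_equal(
    predict_population_recovery(h2, curves$weak, 120, -12 - shift / 120),
    predict_population_recovery(h1, curves$weak, 120, -12))
  hb <- synthesize_histogram(n_cells = 8000, meanlog = log(4000), seed = 22)
  measured <- tidyr::expand_grid(population = c("a", "b"),
                                 array = c("weak", "strong"))
  measured$recovery <- mapply(function(p, a) {
    predict_population_recovery(list(a = h1, b = hb)[[p]], curves[[a]],
                                120, c(a = -12, b = -6.5)[[p]])
  }, measured$population, measured$array)
  f1 <- fit_scaling(list(a = h1, b = hb), measured, curves)
  f2 <- fit_scaling(list(a = h2, b = hb), measured, curves)
  expect_lt(abs(f2$scale / f1$scale - 1), 0.05)
  expect_lt(abs((f2$offsets[["a"]] - f1$offsets[["a"]]) + shift / f1$scale),
            0.5)
})

test_that("fitted offsets track the negative-control peak intensity", {
  # ground truth built from per-cell signal moments; the background peak is
  # pure nuisance that the offset must absorb
  curves <- list(weak = toy_curve(24), strong = toy_curve(11))
  control_peak <- 1440
  truth_scale <- 120
  gen <- function(meanlog, seed) {
    set.seed(seed)
    n <- 8000
    bg <- pmax(rnorm(n, control_peak, 300), 0)
    sig <- rlnorm(n, meanlog, 1.0)
    list(intensity = bg + sig, moment = sig / truth_scale)
  }
  pa <- gen(log(1800), 31)
  pb <- gen(log(4500), 32)
  as_hist <- function(p) {
    br <- seq(0, max(p$intensity) * (1 + 1e-9), length.out = 201)
    cnt <- tabulate(findInterval(p$intensity, br, rightmost.closed = TRUE), 200)
    fluorescence_histogram((br[-1] + br[-201]) / 2, cnt / sum(cnt))
  }
  Rint <- function(cv) function(m) approx(c(0, cv$moment_fAm2),
                                          c(cv$recovery[1], cv$recovery),
                                          xout = pmin(m, 40), rule = 2)$y
  measured <- tidyr::expand_grid(population = c("a", "b"),
                                 array = c("weak", "strong"))
  measured$recovery <- mapply(function(p, a) {
    mean(Rint(curves[[a]])(list(a = pa, b = pb)[[p]]$moment))
  }, measured$population, measured$array)
  fit <- fit_scaling(list(a = as_hist(pa), b = as_hist(pb)), measured, curves)
  expect_lt(abs(fit$scale / truth_scale - 1), 0.15)
  expect_lt(max(abs(fit$offsets - (-control_peak / truth_scale))), 2.5)
})

test_that("degenerate histograms flag the fit as unidentifiable", {
  curves <- list(weak = toy_curve(24), strong = toy_curve(11))
  h <- fluorescence_histogram(1000, 1)
  measured <- tidyr::expand_grid(population = "a", array = c("weak", "strong"))
  measured$recovery <- c(0.4, 0.8)
  expect_warning(fit <- fit_scaling(list(a = h), measured, curves),
                 "unidentifiable")
  expect_true(fit$unidentifiable)
})

test_that("tidy and glance summarize a scaling fit", {
  curves <- list(weak = toy_curve(24), strong = toy_curve(11))
  h1 <- synthesize_histogram(n_cells = 4000, meanlog = log(1500), seed = 41)
  h2 <- synthesize_histogram(n_cells = 4000, meanlog = log(3600), seed = 42)
  measured <- tidyr::expand_grid(population = c("a", "b"),
                                 array = c("weak", "strong"))
  measured$recovery <- mapply(function(p, a) {
    predict_population_recovery(list(a = h1, b = h2)[[p]], curves[[a]],
                                120, c(a = -12, b = -6.5)[[p]])
  }, measured$population, measured$array)
  fit <- fit_scaling(list(a = h1, b = h2), measured, curves)
  td <- tidy(fit)
  expect_equal(td$term, c("scale", "offset", "offset"))
  expect_equal(td$estimate[1], fit$scale)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 4L)
  expect_false(gl$unidentifiable)
})
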