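# Geometry sweeps and recovery-vs-moment curves.
#
# All sweeps rebuild the array per grid point and reuse one deterministic
# seeding; moment curves reuse a single field table across the whole grid.

build_array <- function(pattern, element_width, heights, Br, span) {
  if (pattern == "halbach") {
    if (length(heights) == 1) heights <- rep(heights, 2)
    halbach_array(element_width, h_vert = heights[[1]], h_horz = heights[[2]],
                  Br = Br, span = span)
  } else {
    alternating_array(element_width, height = heights[[1]], Br = Br,
                      span = span)
  }
}

batch_recovery <- function(ctx, z_start_abs, m_s) {
  res <- run_batch(ctx, z_start_abs, m_s)
  n_stall <- colSums(res$outcome == 2L)
  if (any(n_stall > 0)) {
    warn(sprintf("%d trajectories stalled; counted as not captured",
                 sum(n_stall)))
  }
  colSums(res$outcome == 0L) / nrow(res$outcome)
}

new_sweep_result <- function(data, parameter, optimal, tie) {
  structure(data, parameter = parameter, optimal = optimal, tie = tie,
            class = c("sweep_result", class(data)))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s, optimum %.3g mm%s>\n", attr(x, "parameter"),
              attr(x, "optimal") * 1e3,
              if (attr(x, "tie")) " (tie, smaller taken)" else ""))
  NextMethod()
}

#' Optimal element width by recovery sweep
#'
#' Rebuilds the array at each width of a regular grid and computes the
#' capture recovery; the optimum is the argmax, with ties broken toward the
#' smaller width. Following the optimization guidance for this system, the
#' cell moment should be chosen so the best arrays approach 100% recovery
#' (default 10 fAm^2, arctangent law).
#'
#' @param pattern `"halbach"` or `"alternating"`.
#' @param widths width grid (m); default 0.4-2.0 mm at 0.05 mm.
#' @param heights element height(s) (m): for `"halbach"` either one common
#'   height or `c(vertical, horizontal)`; for `"alternating"` one height.
#' @param Br remanence (T).
#' @param cell a [cell_model()].
#' @param channel,fluid,config as in [recovery()].
#' @param span array span (m); default channel plus 10 mm margins.
#' @return A `sweep_result` tibble `(width, recovery)` with attributes
#'   `optimal` (m) and `tie`.
#' @export
sweep_width <- function(pattern = c("halbach", "alternating"),
                        widths = seq(0.4e-3, 2.0e-3, by = 0.05e-3),
                        heights = c(2.75e-3, 2e-3), Br = 1.45,
                        cell = cell_model(), channel = flow_channel(),
                        fluid = fluid_medium(), config = sim_config(),
                        span = c(-10e-3, 60e-3)) {
  pattern <- match.arg(pattern)
  stopifnot(all(diff(widths) > 0))
  seeds <- seed_inlet(channel, config$n_cells, cell$radius)
  z_abs <- channel$wall + seeds$z_start
  rec <- vapply(widths, function(w) {
    arr <- build_array(pattern, w, heights, Br, span)
    ctx <- sim_context(arr, channel, fluid, cell, config)
    batch_recovery(ctx, z_abs, cell$magnetization$m_s)
  }, numeric(1))
  data <- tibble(width = widths, recovery = rec)
  best <- max(rec)
  new_sweep_result(data, "width", widths[which.max(rec)],
                   sum(rec == best) > 1)
}

#' Optimal element height by recovery sweep
#'
#' Same protocol as [sweep_width()] but sweeping a common element height at
#' fixed width. Added magnet material sits farther from the channel, so
#' recovery gains saturate with height.
#'
#' @inheritParams sweep_width
#' @param heights height grid (m); default 0.5-3.0 mm at 0.25 mm.
#' @param width fixed element width (m).
#' @return A `sweep_result` tibble `(height, recovery)`.
#' @export
sweep_height <- function(pattern = c("halbach", "alternating"),
                         heights = seq(0.5e-3, 3.0e-3, by = 0.25e-3),
                         width = 1e-3, Br = 1.45,
                         cell = cell_model(), channel = flow_channel(),
                         fluid = fluid_medium(), config = sim_config(),
                         span = c(-10e-3, 60e-3)) {
  pattern <- match.arg(pattern)
  stopifnot(all(diff(heights) > 0))
  seeds <- seed_inlet(channel, config$n_cells, cell$radius)
  z_abs <- channel$wall + seeds$z_start
  rec <- vapply(heights, function(h) {
    arr <- build_array(pattern, width, h, Br, span)
    ctx <- sim_context(arr, channel, fluid, cell, config)
    batch_recovery(ctx, z_abs, cell$magnetization$m_s)
  }, numeric(1))
  data <- tibble(height = heights, recovery = rec)
  best <- max(rec)
  new_sweep_result(data, "height", heights[which.max(rec)],
                   sum(rec == best) > 1)
}

#' Recovery as a function of cell magnetic moment
#'
#' Computes the capture recovery on a grid of saturation moments for one
#' array, reusing a single field table. The threshold
#' `min_full_recovery_moment` is the smallest grid moment at which every
#' seeded cell is captured.
#'
#' @param array a `magnet_array`.
#' @param cell_template a [cell_model()]; its `m_s` is replaced by each grid
#'   value.
#' @param moments_fAm2 moment grid in fAm^2 (default 1-40, step 1).
#' @inheritParams sweep_width
#' @return A `moment_curve` tibble `(moment_fAm2, recovery)` with attribute
#'   `min_full_recovery_moment` (fAm^2; `NA` if full recovery is not
#'   reached on the grid).
#' @export
recovery_vs_moment <- function(array, cell_template = cell_model(),
                               moments_fAm2 = 1:40,
                               channel = flow_channel(),
                               fluid = fluid_medium(),
                               config = sim_config()) {
  stopifnot(all(diff(moments_fAm2) > 0))
  ctx <- sim_context(array, channel, fluid, cell_template, config)
  seeds <- seed_inlet(channel, config$n_cells, cell_template$radius)
  rec <- batch_recovery(ctx, channel$wall + seeds$z_start,
                        fAm2(moments_fAm2))
  data <- tibble(moment_fAm2 = as.numeric(moments_fAm2), recovery = rec)
  full <- which(rec >= 1 - 1e-12)
  thr <- if (length(full)) moments_fAm2[min(full)] else NA_real_
  structure(data, min_full_recovery_moment = as.numeric(thr),
            class = c("moment_curve", class(data)))
}

#' @export
print.moment_curve <- function(x, ...) {
  cat(sprintf("<moment_curve: full recovery from %s fAm^2>\n",
              format(attr(x, "min_full_recovery_moment"))))
  NextMethod()
}

#' Threshold moment of a moment curve
#'
#' @param curve a `moment_curve`.
#' @return Smallest grid moment (fAm^2) with full recovery.
#' @export
min_full_recovery_moment <- function(curve) {
  attr(curve, "min_full_recovery_moment")
}

#' Compare recovery curves of several arrays
#'
#' @param arrays named list of `magnet_array` objects (>= 2).
#' @inheritParams recovery_vs_moment
#' @return A list of class `array_comparison`: `curves` (long tibble:
#'   `array`, `moment_fAm2`, `recovery`), `thresholds` (per-array
#'   `min_full_recovery_moment`), and `pairs` with, per array pair, the
#'   crossover moment (smallest moment at which both reach full recovery)
#'   and the `low_moment_winner` (higher mean recovery over the grid points
#'   below the smaller threshold).
#' @export
compare_arrays <- function(arrays, cell_template = cell_model(),
                           moments_fAm2 = 1:40, channel = flow_channel(),
                           fluid = fluid_medium(), config = sim_config()) {
  if (length(arrays) < 2) abort("need >= 2 arrays to compare")
  if (is.null(names(arrays)) || any(names(arrays) == "")) {
    names(arrays) <- paste0("array", seq_along(arrays))
  }
  curves <- purrr::imap(arrays, function(a, nm) {
    cv <- recovery_vs_moment(a, cell_template, moments_fAm2, channel, fluid,
                             config)
    tibble(array = nm, moment_fAm2 = cv$moment_fAm2, recovery = cv$recovery,
           threshold = min_full_recovery_moment(cv))
  })
  long <- bind_rows(curves)
  thresholds <- long |>
    group_by(.data$array) |>
    summarise(min_full_recovery_moment = .data$threshold[1], .groups = "drop")
  nm <- names(arrays)
  combs <- utils::combn(nm, 2, simplify = FALSE)
  pairs <- purrr::map_dfr(combs, function(pr) {
    t1 <- thresholds$min_full_recovery_moment[thresholds$array == pr[1]]
    t2 <- thresholds$min_full_recovery_moment[thresholds$array == pr[2]]
    lo <- min(t1, t2, max(moments_fAm2))
    idx <- long$moment_fAm2 < lo
    r1 <- mean(long$recovery[idx & long$array == pr[1]])
    r2 <- mean(long$recovery[idx & long$array == pr[2]])
    tibble(array_a = pr[1], array_b = pr[2],
           crossover_fAm2 = max(t1, t2),
           low_moment_winner = if (isTRUE(r2 > r1)) pr[2] else pr[1])
  })
  structure(list(curves = long[setdiff(names(long), "threshold")],
                 thresholds = thresholds, pairs = pairs),
            class = "array_comparison")
}

#' @export
print.array_comparison <- function(x, ...) {
  cat("<array_comparison>\n")
  print(x$thresholds)
  print(x$pairs)
  invisible(x)
}

#' Optimal magnet width versus channel height
#'
#' Runs [sweep_width()] for several channel heights at a fixed magnet height
#' and fits a least-squares line to the per-height optimal widths. Over the
#' commercial channel-height range the relation is close to linear.
#'
#' @param channel_heights channel heights (m); default the 0.2-0.8 mm
#'   commercial presets.
#' @param magnet_height common element height (m); default 1.5 mm.
#' @param widths sweep grid (m).
#' @inheritParams sweep_width
#' @return A list of class `width_height_fit`: `data` (tibble
#'   `channel_height`, `optimal_width`), `fit` (an `lm`), `r_squared`.
#' @export
optimal_width_vs_channel_height <- function(channel_heights = c(2, 4, 6, 8) * 1e-4,
                                            magnet_height = 1.5e-3,
                                            widths = seq(0.4e-3, 2.0e-3, by = 0.05e-3),
                                            Br = 1.45, cell = cell_model(),
                                            fluid = fluid_medium(),
                                            config = sim_config(),
                                            wall = 200e-6) {
  if (length(channel_heights) < 3) abort("need >= 3 channel heights")
  opt <- vapply(channel_heights, function(h) {
    ch <- flow_channel(height = h, wall = wall)
    sw <- sweep_width("halbach", widths = widths,
                      heights = magnet_height, Br = Br, cell = cell,
                      channel = ch, fluid = fluid, config = config)
    attr(sw, "optimal")
  }, numeric(1))
  data <- tibble(channel_height = channel_heights, optimal_width = opt)
  fit <- lm(optimal_width ~ channel_height, data = data)
  structure(list(data = data, fit = fit,
                 r_squared = summary(fit)$r.squared),
            class = "width_height_fit")
}

#' @export
print.width_height_fit <- function(x, ...) {
  cat(sprintf("<width_height_fit: slope %.3g, intercept %.3g mm, R^2 = %.3f>\n",
              stats::coef(x$fit)[2], stats::coef(x$fit)[1] * 1e3, x$r_squared))
  print(x$data)
  invisible(x)
}
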