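#' Ordinary least-squares calibration line
#'
#' Fits `y = slope * x + intercept` by ordinary least squares, the workhorse
#' of the fluorescence-OD calibration: within its linear range, PI
#' fluorescence of stained dead cells is proportional to cell density, and
#' plate OD600 is an affine function of the reference cuvette OD600.
#'
#' @param x,y Numeric vectors of equal length (>= 3 points).
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `n_points`, `range_lo`, `range_hi` (the x
#'   extent of the fitted points), `excluded_points` (empty tibble here;
#'   populated by [detect_linear_range()]) and `data`.
#' @examples
#' fit_line(1:10, 2 * (1:10))
#' @export
fit_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    picls_abort("calibration fit needs >= 3 finite points",
                "picls_degenerate_input_error")
  }
  if (var(x) == 0) {
    picls_abort("calibration fit needs variation in x",
                "picls_degenerate_input_error")
  }
  if (var(y) == 0) {
    picls_abort("constant response: R-squared undefined (degenerate calibration)",
                "picls_degenerate_input_error")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = 1 - ss_res / ss_tot,
         n_points = length(x),
         range_lo = min(x),
         range_hi = max(x),
         excluded_points = tibble(x = numeric(), y = numeric()),
         data = tibble(x = x, y = y)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> y = %.4g * x + %.4g  (R^2 = %.4f, n = %d, range [%.3g, %.3g], %d excluded)\n",
    x$slope, x$intercept, x$r_squared, x$n_points,
    x$range_lo, x$range_hi, nrow(x$excluded_points)))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n.points = x$n_points,
         range.lo = x$range_lo, range.hi = x$range_hi,
         n.excluded = nrow(x$excluded_points))
}

# pick (x, y) columns for a calibration axis
calibration_axis_xy <- function(points, axis) {
  switch(axis,
         plate_od_vs_cuvette = list(x = points$cuvette_od, y = points$plate_od),
         fluorescence_vs_od = list(x = points$cuvette_od, y = points$fluorescence))
}

#' Detect the linear range of a dilution-series calibration
#'
#' Plate-reader optics compress the response at high cell density: plate
#' OD600 tracks cuvette OD600 linearly only up to a saturation knee, above
#' which the trend breaks down. Given a dilution series, this detects the
#' upper validity bound by greedy trimming: the highest-cuvette-OD point is
#' removed until the OLS fit over the remainder reaches `r2_threshold`. The
#' lower bound is the smallest retained point whose signal exceeds 3x the
#' blank standard deviation when a blank SD is supplied, else the smallest
#' retained point.
#'
#' @param points A data frame of calibration points with columns
#'   `cuvette_od`, `plate_od`, `fluorescence` (the latter only needed for
#'   the fluorescence axis).
#' @param r2_threshold Minimum R-squared for the retained fit (default
#'   0.98).
#' @param axis Which response to regress on cuvette OD:
#'   `"plate_od_vs_cuvette"` (default) or `"fluorescence_vs_od"`.
#' @param blank_sd Optional standard deviation of blank wells in the units
#'   of the chosen response, used for the 3-sigma lower detection bound.
#' @return A `calibration_fit` whose `range_lo`/`range_hi` are in cuvette OD
#'   units and whose `excluded_points` lists the trimmed points.
#' @export
detect_linear_range <- function(points, r2_threshold = 0.98,
                                axis = c("plate_od_vs_cuvette",
                                         "fluorescence_vs_od"),
                                blank_sd = NULL) {
  axis <- match.arg(axis)
  points <- as_tibble(points)
  if (nrow(points) < 4) {
    picls_abort("linear-range detection needs >= 4 points",
                "picls_degenerate_input_error")
  }
  xy <- calibration_axis_xy(points, axis)
  ord <- order(xy$x)
  d <- tibble(cuvette_od = xy$x[ord], response = xy$y[ord])
  kept <- d
  excluded <- d[0, ]
  repeat {
    if (nrow(kept) < 4) {
      picls_abort(
        paste0("no subset of >= 4 points reaches R^2 >= ", r2_threshold),
        "picls_no_linear_range_error")
    }
    fit <- fit_line(kept$cuvette_od, kept$response)
    if (fit$r_squared >= r2_threshold) break
    excluded <- bind_rows(excluded, kept[nrow(kept), ])
    kept <- kept[-nrow(kept), ]
  }
  range_lo <- min(kept$cuvette_od)
  if (!is.null(blank_sd) && is.finite(blank_sd)) {
    above <- kept$cuvette_od[kept$response > 3 * blank_sd]
    if (length(above) > 0) range_lo <- min(above)
  }
  fit$range_lo <- range_lo
  fit$range_hi <- max(kept$cuvette_od)
  fit$excluded_points <- tibble(cuvette_od = excluded$cuvette_od,
                                response = excluded$response)
  fit$axis <- axis
  fit
}

#' Convert between plate and cuvette OD600
#'
#' Uses a `plate_od_vs_cuvette` calibration fit (`plate = slope * cuvette +
#' intercept`) to map readings from one geometry to the other. Values whose
#' cuvette-scale equivalent falls outside the fit's validated linear range
#' are still converted but flagged.
#'
#' @param value Numeric vector of OD600 readings.
#' @param fit A `calibration_fit` from [fit_line()] or
#'   [detect_linear_range()] on the `plate_od_vs_cuvette` axis.
#' @param direction `"plate_to_cuvette"` or `"cuvette_to_plate"`.
#' @return A tibble with columns `input`, `output`, `out_of_range`.
#' @export
convert_od <- function(value, fit,
                       direction = c("plate_to_cuvette", "cuvette_to_plate")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) {
    picls_abort("calibration slope is zero: conversion not invertible",
                "picls_degenerate_input_error")
  }
  out <- switch(direction,
                plate_to_cuvette = (value - fit$intercept) / fit$slope,
                cuvette_to_plate = fit$slope * value + fit$intercept)
  cuvette_scale <- if (direction == "plate_to_cuvette") out else value
  tibble(input = value, output = out,
         out_of_range = cuvette_scale < fit$range_lo |
           cuvette_scale > fit$range_hi)
}

#' Compare calibrations from two microplate types
#'
#' Black plates quench autofluorescence; clear plates are cheaper. To decide
#' whether the two are interchangeable for this assay, the calibration
#' slopes are compared as a ratio with a bootstrap confidence interval
#' (resampling calibration points within each plate type), and the verdict
#' is equivalence when the whole interval lies within `1 +/- margin` --
#' a practical-interchangeability criterion rather than a null-hypothesis
#' test.
#'
#' @param points_black,points_clear Calibration-point tables (columns
#'   `cuvette_od` plus the response for `axis`) from the two plate types.
#' @param axis Calibration axis, as in [detect_linear_range()]; default
#'   `"fluorescence_vs_od"`.
#' @param margin Equivalence margin on the slope ratio (default 0.2).
#' @param n_boot Bootstrap draws (default 1000).
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row tibble of class `plate_type_comparison`: `slope_black`,
#'   `slope_clear`, `ratio` (clear / black), `ci_low`, `ci_high`, `margin`,
#'   `verdict` (`"equivalent"` or `"different"`), `n_boot`.
#' @export
compare_plate_types <- function(points_black, points_clear,
                                axis = c("fluorescence_vs_od",
                                         "plate_od_vs_cuvette"),
                                margin = 0.2, n_boot = 1000, conf = 0.95,
                                seed = NULL) {
  axis <- match.arg(axis)
  b <- calibration_axis_xy(as_tibble(points_black), axis)
  c_ <- calibration_axis_xy(as_tibble(points_clear), axis)
  overlap_lo <- max(min(b$x), min(c_$x))
  overlap_hi <- min(max(b$x), max(c_$x))
  if (overlap_lo >= overlap_hi) {
    picls_abort("plate-type calibrations cover non-overlapping OD ranges",
                "picls_incomparable_error")
  }
  slope_b <- fit_line(b$x, b$y)$slope
  slope_c <- fit_line(c_$x, c_$y)$slope
  if (!is.null(seed)) set.seed(seed)
  ols_slope <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc^2)
  }
  nb <- length(b$x); nc <- length(c_$x)
  ratios <- vapply(seq_len(n_boot), function(i) {
    ib <- sample.int(nb, nb, replace = TRUE)
    ic <- sample.int(nc, nc, replace = TRUE)
    sb <- ols_slope(b$x[ib], b$y[ib])
    sc <- ols_slope(c_$x[ic], c_$y[ic])
    sc / sb
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  alpha <- 1 - conf
  ci <- unname(quantile(ratios, c(alpha / 2, 1 - alpha / 2)))
  out <- tibble(slope_black = slope_b, slope_clear = slope_c,
                ratio = slope_c / slope_b,
                ci_low = ci[1], ci_high = ci[2], margin = margin,
                verdict = if (ci[1] >= 1 - margin && ci[2] <= 1 + margin)
                  "equivalent" else "different",
                n_boot = n_boot)
  class(out) <- c("plate_type_comparison", class(out))
  out
}
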