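#' Optic disc tilt from the circumpapillary RPE trajectory
#'
#' On a circular B-scan around a tilted optic disc, the retinal pigment
#' epithelium (RPE) traces a sinusoid once the scan is unwrapped: a circular
#' section of a tilted plane has exactly one period per circle. The amplitude
#' of the least-squares sinusoid fitted to manually marked RPE points is used
#' as the disc tilt metric, in axial pixels: the larger the amplitude, the
#' greater the tilt.
#'
#' @name tilt_fit
NULL

#' Marked RPE points from an unwrapped B-scan
#'
#' @param x A-scan positions (pixels along the unwrapped scan), strictly
#'   increasing, within `[0, scan_width_px]`.
#' @param y Depths (pixels) of the marked RPE at each position.
#' @param scan_width_px Total unwrapped scan width in pixels.
#' @return An object of class `marked_rpe_points`.
#' @export
marked_rpe_points <- function(x, y, scan_width_px) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)),
            is.numeric(scan_width_px), scan_width_px > 0)
  if (length(x) > 1 && any(diff(x) <= 0)) {
    stop("x positions must be strictly increasing", call. = FALSE)
  }
  if (min(x) < -scan_width_px / 2 - 1e-9 || max(x) > scan_width_px + 1e-9) {
    stop("x positions outside the scan width", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 scan_width_px = as.numeric(scan_width_px)),
            class = "marked_rpe_points")
}

#' Recenter marked RPE coordinates
#'
#' Shifts the coordinates to a frame with zero at the center of the wave:
#' x so that the scan midpoint (`scan_width_px / 2`) maps to 0, and y by
#' subtracting its mean. Point ordering is preserved.
#'
#' @param points A [marked_rpe_points()] object.
#' @return A recentered `marked_rpe_points` object.
#' @export
recenter <- function(points) {
  stopifnot(inherits(points, "marked_rpe_points"))
  points$x <- points$x - points$scan_width_px / 2
  points$y <- points$y - mean(points$y)
  points
}

#' Least-squares sine fit of the RPE trajectory
#'
#' Fits `y = a * sin(b * x - c)` by least squares. For any fixed angular
#' frequency `b` the model is linear in `(A, B)` where
#' `y = A sin(bx) + B cos(bx)`, so the conditional problem is solved exactly by
#' its 2x2 normal equations; the residual sum of squares, profiled over the
#' linear pair, is then minimized over `b` on a bounded interval around one
#' period per scan (`2 * pi / scan_width_px`), by a coarse grid refined with
#' golden-section search. This makes the fit deterministic and globally optimal
#' in `(a, c)` for the selected frequency; amplitude is reported non-negative
#' with the sign absorbed into the phase.
#'
#' The frequency is bounded to `b_bounds` times one period per circle because
#' a circular section of a tilted plane has exactly one period; an unbounded
#' frequency would let marking noise lock onto higher harmonics.
#'
#' Points are fitted in the coordinates given; apply [recenter()] first so the
#' zero-mean, intercept-free model is appropriate.
#'
#' @param points A (recentered) [marked_rpe_points()] object with >= 6 points
#'   spanning at least half the scan width.
#' @param b_bounds Multiplicative bounds on the frequency relative to
#'   `2 * pi / scan_width_px`. Default `c(0.5, 2)`.
#' @return An object of class `sine_fit`: list with `a` (amplitude, pixels,
#'   >= 0), `b` (rad/pixel), `c` (phase, rad, in `[0, 2pi)`), `rms_residual`
#'   (pixels) and `converged`.
#' @examples
#' x <- seq(0, 1023, length.out = 64)
#' p <- marked_rpe_points(x, 30 * sin(2 * pi * x / 1024 - 1), 1024)
#' fit_sine(recenter(p))
#' @export
fit_sine <- function(points, b_bounds = c(0.5, 2)) {
  stopifnot(inherits(points, "marked_rpe_points"),
            length(b_bounds) == 2, b_bounds[1] > 0, b_bounds[1] < b_bounds[2])
  x <- points$x
  y <- points$y
  n <- length(x)
  if (n < 6) stop("at least 6 marked points are required", call. = FALSE)
  if (diff(range(x)) < points$scan_width_px / 2) {
    stop("marked points must span at least half the scan width", call. = FALSE)
  }
  b0 <- 2 * pi / points$scan_width_px

  if (stats::sd(y) == 0) {
    # flat trajectory: zero-amplitude fit is exact
    return(new_sine_fit(a = 0, b = b0, c = 0, rms = 0, converged = TRUE))
  }

  sse_b <- function(b) conditional_fit(x, y, b)$sse
  bs <- seq(b_bounds[1] * b0, b_bounds[2] * b0, length.out = 49)
  sses <- vapply(bs, sse_b, numeric(1))
  i <- which.min(sses)
  lo <- bs[max(1, i - 1)]
  hi <- bs[min(length(bs), i + 1)]
  opt <- stats::optimize(sse_b, lower = lo, upper = hi, tol = b0 * 1e-10)
  b_hat <- opt$minimum
  cf <- conditional_fit(x, y, b_hat)
  if (!is.finite(cf$sse)) {
    return(new_sine_fit(a = NA_real_, b = NA_real_, c = NA_real_,
                        rms = NA_real_, converged = FALSE))
  }
  # y = A sin(bx) + B cos(bx) = a sin(bx - c) with A = a cos(c), B = -a sin(c)
  a_hat <- sqrt(cf$A^2 + cf$B^2)
  c_hat <- atan2(-cf$B, cf$A) %% (2 * pi)
  new_sine_fit(a = a_hat, b = b_hat, c = c_hat,
               rms = sqrt(max(cf$sse, 0) / n), converged = TRUE)
}

# Exact least squares for (A, B) in y = A sin(bx) + B cos(bx) at fixed b.
conditional_fit <- function(x, y, b) {
  s <- sin(b * x)
  co <- cos(b * x)
  g11 <- sum(s * s); g12 <- sum(s * co); g22 <- sum(co * co)
  h1 <- sum(y * s); h2 <- sum(y * co)
  det <- g11 * g22 - g12 * g12
  if (det <= .Machine$double.eps * (g11 + g22)^2) {
    return(list(A = NA_real_, B = NA_real_, sse = Inf))
  }
  A <- (g22 * h1 - g12 * h2) / det
  B <- (g11 * h2 - g12 * h1) / det
  r <- y - A * s - B * co
  list(A = A, B = B, sse = sum(r * r))
}

new_sine_fit <- function(a, b, c, rms, converged) {
  structure(list(a = a, b = b, c = c, rms_residual = rms,
                 converged = converged),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Sine fit: did not converge\n")
  } else {
    cat(sprintf(
      "Sine fit: a = %.3f px, b = %.6g rad/px, c = %.4f rad, rms = %.3f px\n",
      x$a, x$b, x$c, x$rms_residual))
  }
  invisible(x)
}

#' Evaluate a fitted sinusoid
#'
#' @param fit A `sine_fit` object.
#' @param x Positions (pixels) at which to evaluate.
#' @return Predicted depths (pixels).
#' @export
sine_eval <- function(fit, x) {
  stopifnot(inherits(fit, "sine_fit"), fit$converged)
  fit$a * sin(fit$b * x - fit$c)
}

#' Expected sine amplitude for a given planar tilt
#'
#' Forward geometric model: a plane tilted by `tilt_deg` intersected along a
#' circle of radius `circle_radius_um` produces a sinusoidal depth profile of
#' amplitude `radius * tan(tilt)` microns, i.e. `radius * tan(tilt) /
#' axial_scale` axial pixels. Used to generate synthetic traces and to check
#' inverse-fit recovery.
#'
#' @param tilt_deg Tilt of the RPE plane in degrees, `0 <= tilt_deg < 90`.
#' @param circle_radius_um Scan circle radius (microns; 1700 for the 3.4 mm
#'   protocol).
#' @param axial_scale_um_per_px Axial pixel pitch (microns per pixel).
#' @return Expected amplitude in axial pixels.
#' @examples
#' expected_amplitude(5, 1700, 2.6) # ~ 57.2 px
#' @export
expected_amplitude <- function(tilt_deg, circle_radius_um = 1700,
                               axial_scale_um_per_px = 2.6) {
  stopifnot(circle_radius_um > 0, axial_scale_um_per_px > 0)
  if (any(tilt_deg < 0) || any(tilt_deg >= 90)) {
    stop("tilt_deg must be in [0, 90)", call. = FALSE)
  }
  circle_radius_um * tan(tilt_deg * pi / 180) / axial_scale_um_per_px
}
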