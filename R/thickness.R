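#' Peripapillary choroidal thickness from boundary traces
#'
#' The choroid on a circumpapillary circle scan is bounded by the outer RPE
#' boundary above and the sclerochoroidal interface below. Thickness is the
#' axial distance between the two boundaries, converted to microns, sampled at
#' (or around) the eight sector centers of the [build_sector_map()] frame.
#'
#' @name thickness
NULL

#' Circumpapillary boundary trace
#'
#' Per-A-scan depths of the outer RPE boundary and the sclerochoroidal
#' interface along the scan circle, with the axial pixel scale. Depth grows
#' with distance from the vitreous, so the interface is never shallower than
#' the RPE.
#'
#' @param z_rpe Depth (pixels) of the outer RPE boundary per A-scan.
#' @param z_csi Depth (pixels) of the sclerochoroidal interface per A-scan;
#'   must satisfy `z_csi >= z_rpe` everywhere.
#' @param axial_scale Microns per axial pixel.
#' @param circle_diameter_mm Scan circle diameter (default 3.4).
#' @return An object of class `circumpapillary_trace`.
#' @export
circumpapillary_trace <- function(z_rpe, z_csi, axial_scale,
                                  circle_diameter_mm = 3.4) {
  stopifnot(is.numeric(z_rpe), is.numeric(z_csi),
            length(z_rpe) == length(z_csi), length(z_rpe) >= 8,
            all(is.finite(z_rpe)), all(is.finite(z_csi)),
            is.numeric(axial_scale), axial_scale > 0,
            circle_diameter_mm > 0)
  if (any(z_csi < z_rpe - 1e-9)) {
    stop("invalid trace: z_csi < z_rpe (negative choroidal thickness)",
         call. = FALSE)
  }
  structure(list(z_rpe = as.numeric(z_rpe), z_csi = as.numeric(z_csi),
                 n_ascans = length(z_rpe), axial_scale = axial_scale,
                 circle_diameter_mm = circle_diameter_mm),
            class = "circumpapillary_trace")
}

#' Measure sector ppCT from a boundary trace
#'
#' For each sector the thickness is the median, over A-scans within
#' `window_deg` degrees of the sector's central angle, of
#' `(z_csi - z_rpe) * axial_scale`. With `window_deg = 0` (the default, the
#' single-position convention of manual grading) only the nearest A-scan is
#' used; a positive window gives a locally smoothed measurement robust to
#' marking noise.
#'
#' @param trace A [circumpapillary_trace()] object.
#' @param sectors A `sector_map` from [build_sector_map()].
#' @param window_deg Angular half-width of the measurement window, in
#'   `[0, 22.5)` degrees.
#' @return Named numeric vector of class `sector_thickness`: ppCT in microns
#'   for sectors T, ST, S, SN, N, IN, I, IT.
#' @export
measure_ppct <- function(trace, sectors, window_deg = 0) {
  stopifnot(inherits(trace, "circumpapillary_trace"),
            inherits(sectors, "sector_map"),
            is.numeric(window_deg), length(window_deg) == 1,
            window_deg >= 0, window_deg < 22.5)
  n <- trace$n_ascans
  ascan_angle <- trace_index_to_angle(0:(n - 1), n)
  thick_um <- (trace$z_csi - trace$z_rpe) * trace$axial_scale
  out <- vapply(as.numeric(sectors), function(center) {
    d <- abs(((ascan_angle - center + 180) %% 360) - 180)
    if (window_deg == 0) {
      thick_um[which.min(d)]
    } else {
      stats::median(thick_um[d <= window_deg])
    }
  }, numeric(1))
  names(out) <- names(sectors)
  structure(out, class = "sector_thickness")
}

#' Temporal ppCT ratio
#'
#' Per-eye asymmetry statistic: the temporal-sector ppCT divided by the mean
#' ppCT of the other seven sectors. A ratio below 1 indicates a relatively
#' thinned temporal choroid.
#'
#' @param sectors Named numeric vector of 8 sector ppCT values (microns)
#'   containing a `"T"` element, e.g. a `sector_thickness`.
#' @return The scalar ratio.
#' @examples
#' temporal_ratio(c(T = 100, ST = 200, S = 200, SN = 200, N = 200,
#'                  IN = 200, I = 200, IT = 200)) # 0.5
#' @export
temporal_ratio <- function(sectors) {
  stopifnot(!is.null(names(sectors)), "T" %in% names(sectors),
            length(sectors) == 8)
  others <- mean(sectors[setdiff(names(sectors), "T")])
  if (!is.finite(others) || others <= 0) {
    stop("mean of non-temporal sectors must be positive", call. = FALSE)
  }
  unname(sectors[["T"]] / others)
}
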