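#' Fundus landmark geometry
#'
#' Landmarks are expressed in the fundus-photograph frame: x increases to the
#' image right, y increases inferiorly (screen convention), units are microns.
#' The papillo-macular position (PMP) angle and the eight-sector map on the
#' 3.4 mm circumpapillary scan circle are both derived from the disc-center and
#' fovea coordinates.
#'
#' @name geometry
NULL

#' Sector names in TSNIT order
#'
#' Temporal, superotemporal, superior, superonasal, nasal, inferonasal,
#' inferior, inferotemporal: the order in which the circumpapillary circle is
#' traversed starting at the temporal anchor and proceeding superiorly.
#'
#' @return Character vector of the 8 sector codes.
#' @export
sector_names <- function() {
  c("T", "ST", "S", "SN", "N", "IN", "I", "IT")
}

#' Construct fundus landmarks
#'
#' @param disc_x,disc_y Optic disc center (microns, y increases inferiorly).
#' @param fovea_x,fovea_y Fovea position (same frame).
#' @param laterality `"right"` or `"left"`.
#' @return An object of class `fundus_landmarks`.
#' @examples
#' fundus_landmarks(0, 0, -4000, 380, "right")
#' @export
fundus_landmarks <- function(disc_x, disc_y, fovea_x, fovea_y,
                             laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(is.numeric(disc_x), is.numeric(disc_y),
            is.numeric(fovea_x), is.numeric(fovea_y),
            all(is.finite(c(disc_x, disc_y, fovea_x, fovea_y))))
  if (disc_x == fovea_x && disc_y == fovea_y) {
    stop("degenerate geometry: disc center and fovea coincide", call. = FALSE)
  }
  dx <- fovea_x - disc_x
  expected_sign <- if (laterality == "right") -1 else 1
  if (dx != 0 && sign(dx) != expected_sign) {
    warning("fovea is not temporal to the disc for the stated laterality",
            call. = FALSE)
  }
  structure(
    list(disc = c(x = disc_x, y = disc_y),
         fovea = c(x = fovea_x, y = fovea_y),
         laterality = laterality),
    class = "fundus_landmarks"
  )
}

#' Papillo-macular position (PMP) angle
#'
#' Signed angle, in degrees, between the horizontal line through the disc
#' center and the disc-center-to-fovea line. Positive when the fovea lies
#' inferior to the horizontal (the anatomically typical configuration), so that
#' a typical healthy cohort has a positive mean PMP.
#'
#' @param landmarks A [fundus_landmarks()] object.
#' @return Signed angle in degrees, in (-90, 90).
#' @examples
#' pmp_angle(fundus_landmarks(0, 0, -4000, 380.2, "right")) # ~ +5.43
#' @export
pmp_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "fundus_landmarks"))
  dx <- landmarks$fovea[["x"]] - landmarks$disc[["x"]]
  dy <- landmarks$fovea[["y"]] - landmarks$disc[["y"]]
  if (dx == 0) {
    stop("degenerate geometry: fovea lies on the vertical through the disc",
         call. = FALSE)
  }
  # |dx| makes the convention laterality-neutral: the temporal horizontal is
  # the reference direction for both eyes; y-down means dy > 0 is inferior.
  atan2(dy, abs(dx)) * 180 / pi
}

#' Eight-sector map on the circumpapillary circle
#'
#' Sector centers on the scan circle, in the anatomically anchored angular
#' frame: 0 degrees at the temporal horizontal direction, increasing toward
#' superior. The temporal (T) sector is centered at the intersection of the
#' disc-to-fovea line with the scan circle; the remaining sectors follow at 45
#' degree steps in TSNIT order (T, ST, S, SN, N, IN, I, IT). A fovea inferior
#' to the disc (positive PMP) places the T anchor at a negative frame angle.
#'
#' Because the frame is anatomical, a left eye that is the mirror image of a
#' right eye yields the same map; the image-space mirroring (nasal/temporal
#' swap) is absorbed by the frame definition.
#'
#' @param landmarks A [fundus_landmarks()] object.
#' @return A named numeric vector of class `sector_map`: sector center angles
#'   in degrees, in `[0, 360)`, named by sector code.
#' @examples
#' build_sector_map(fundus_landmarks(0, 0, -4000, 0, "right"))
#' @export
build_sector_map <- function(landmarks) {
  pmp <- pmp_angle(landmarks)
  # fovea inferior (pmp > 0) => disc->fovea direction below the horizontal,
  # i.e. negative angle in the superior-positive frame
  anchor <- -pmp
  ang <- (anchor + 45 * (0:7)) %% 360
  names(ang) <- sector_names()
  structure(ang, class = "sector_map", laterality = landmarks$laterality)
}

#' Map an A-scan index to its circle angle
#'
#' A-scan `index` (0-based) of an `n_ascans`-sample circle scan lies at
#' `index * 360 / n_ascans` degrees in the sector-map frame.
#'
#' @param index Integer vector, 0-based A-scan index in `[0, n_ascans)`.
#' @param n_ascans Number of A-scans per circle (1024 for the 3.4 mm protocol).
#' @return Angle(s) in degrees, in `[0, 360)`.
#' @export
trace_index_to_angle <- function(index, n_ascans) {
  stopifnot(n_ascans >= 1, all(index == floor(index)))
  if (any(index < 0) || any(index >= n_ascans)) {
    stop("A-scan index out of range [0, n_ascans)", call. = FALSE)
  }
  index * 360 / n_ascans
}

#' Map a circle angle to the nearest A-scan index
#'
#' Inverse of [trace_index_to_angle()] up to wraparound: returns the 0-based
#' index of the A-scan nearest to `angle`.
#'
#' @param angle Angle(s) in degrees (any real value; reduced modulo 360).
#' @param n_ascans Number of A-scans per circle.
#' @return Integer A-scan index in `[0, n_ascans)`.
#' @export
angle_to_trace_index <- function(angle, n_ascans) {
  stopifnot(n_ascans >= 1)
  as.integer(round(angle / 360 * n_ascans) %% n_ascans)
}
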