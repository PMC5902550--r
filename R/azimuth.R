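#' Normalize an azimuth to [0, 360)
#'
#' Azimuths throughout the package are compass bearings: degrees clockwise
#' from geographic north. Arithmetic on azimuths is modular, so any real
#' number of degrees maps back into `[0, 360)`.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in `[0, 360)`.
#' @examples
#' normalize_azimuth(c(-90, 360, 725))
#' @export
normalize_azimuth <- function(deg) {
  stopifnot(is.numeric(deg), all(is.finite(deg)))
  out <- deg %% 360
  # %% can return 360 when deg is a tiny negative number, guard exactly
  out[out >= 360] <- 0
  out
}

#' Convert between azimuths and mathematical angles
#'
#' An azimuth a (degrees clockwise from north) corresponds to the unit vector
#' (sin a, cos a) in the projected x/y (easting/northing) plane. These
#' helpers make that conversion explicit so that no trigonometric call in
#' the package mixes up the two conventions.
#'
#' @param az numeric vector of azimuths in degrees.
#' @param dx,dy numeric vectors of planar displacements in metres.
#' @return `azimuth_to_unit()` returns a two-column matrix of unit vectors;
#'   `azimuth_from_displacement()` returns azimuths in `[0, 360)`.
#' @examples
#' azimuth_to_unit(c(0, 90))          # north, east
#' azimuth_from_displacement(1, 1)    # 45
#' @export
azimuth_to_unit <- function(az) {
  rad <- az * pi / 180
  cbind(x = sin(rad), y = cos(rad))
}

#' @rdname azimuth_to_unit
#' @export
azimuth_from_displacement <- function(dx, dy) {
  stopifnot(length(dx) == length(dy))
  if (any(dx == 0 & dy == 0)) {
    stop("azimuth undefined for a zero displacement")
  }
  normalize_azimuth(atan2(dx, dy) * 180 / pi)
}

#' Clockwise angular span from one azimuth to another
#'
#' @param from,to azimuths in degrees.
#' @return degrees in `[0, 360)` travelled clockwise from `from` to `to`.
#' @export
clockwise_span <- function(from, to) {
  normalize_azimuth(to - from)
}

#' Test whether an azimuth lies in a clockwise circular interval
#'
#' The interval runs clockwise from `min` to `max` and includes both
#' endpoints, so it handles wrap-around intervals such as 350--10 degrees.
#' A degenerate interval with `min == max` contains only that exact azimuth.
#'
#' @param angle azimuth(s) to test, degrees.
#' @param min,max interval endpoints, degrees clockwise from north.
#' @return logical vector.
#' @examples
#' azimuth_in_interval(0, 350, 10)    # TRUE
#' azimuth_in_interval(180, 350, 10)  # FALSE
#' @export
azimuth_in_interval <- function(angle, min, max) {
  angle <- normalize_azimuth(angle)
  min <- normalize_azimuth(min)
  max <- normalize_azimuth(max)
  clockwise_span(min, angle) <= clockwise_span(min, max) |
    (clockwise_span(min, max) == 0 & angle == min)
}
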