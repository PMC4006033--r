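# Interaural-polar coordinates: every target, response and template direction
# is a (lateral, polar) pair.  Lateral in [-90, 90] degrees (positive = left)
# selects the sagittal plane; polar in [-90, 270) degrees indexes the position
# within the plane (-30 = front below eye level, 90 = overhead, 210 = rear
# below eye level).

#' Construct a direction in interaural-polar coordinates
#'
#' @param lateral lateral angle(s) in degrees, within \[-90, 90\];
#'   positive values point to the listener's left.
#' @param polar polar angle(s) in degrees, within \[-90, 270): -30 is in
#'   front below eye level, 90 overhead, 210 behind below eye level.
#' @return a data.frame with columns `lateral` and `polar` of class
#'   `direction`.
#' @examples
#' direction(0, c(-30, 0, 90, 210))
#' @export
direction <- function(lateral, polar) {
  n <- max(length(lateral), length(polar))
  lateral <- rep_len(as.numeric(lateral), n)
  polar <- rep_len(as.numeric(polar), n)
  validate_angles(lateral, polar)
  structure(data.frame(lateral = lateral, polar = polar),
            class = c("direction", "data.frame"))
}

validate_angles <- function(lateral, polar, where = NULL) {
  bad_lat <- which(!is.finite(lateral) | lateral < -90 | lateral > 90)
  bad_pol <- which(!is.finite(polar) | polar < -90 | polar >= 270)
  if (length(bad_lat) || length(bad_pol)) {
    idx <- sort(unique(c(bad_lat, bad_pol)))
    ctx <- if (is.null(where)) "" else paste0(" in ", where)
    stop(sprintf(
      "angle out of range%s (lateral must lie in [-90, 90], polar in [-90, 270)); offending row(s): %s",
      ctx, paste(idx, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Wrapped polar-angle difference
#'
#' Computes `response - target` on the polar circle, wrapped into
#' (-180, 180]. Used for all polar localization errors; e.g. a target at
#' 210 deg answered at -30 deg yields +120 deg (the raw -240 wraps around).
#'
#' @param target_polar target polar angle(s), degrees.
#' @param response_polar response polar angle(s), degrees.
#' @return signed wrapped difference(s) in degrees, in (-180, 180].
#' @export
polar_error <- function(target_polar, response_polar) {
  e <- (response_polar - target_polar) %% 360
  e[e > 180] <- e[e > 180] - 360
  e
}

#' Convert spherical (azimuth/elevation) to interaural-polar coordinates
#'
#' Azimuth follows the usual acoustics convention (0 = front, counted
#' counter-clockwise, so +90 = left), elevation in \[-90, 90\].
#'
#' @param azimuth degrees.
#' @param elevation degrees.
#' @return data.frame with `lateral` and `polar` columns (degrees).
#' @export
sph_to_interaural <- function(azimuth, elevation) {
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  x <- cos(el) * cos(az)   # front
  y <- cos(el) * sin(az)   # left
  z <- sin(el)             # up
  lateral <- asin(pmin(pmax(y, -1), 1)) * 180 / pi
  polar <- atan2(z, x) * 180 / pi
  polar[polar < -90] <- polar[polar < -90] + 360
  data.frame(lateral = lateral, polar = polar)
}

#' Convert interaural-polar to spherical (azimuth/elevation) coordinates
#'
#' Inverse of [sph_to_interaural()].
#'
#' @param lateral degrees in \[-90, 90\].
#' @param polar degrees in \[-90, 270).
#' @return data.frame with `azimuth` (degrees in \[0, 360)) and
#'   `elevation` (degrees) columns.
#' @export
interaural_to_sph <- function(lateral, polar) {
  lat <- lateral * pi / 180
  pol <- polar * pi / 180
  x <- cos(lat) * cos(pol)
  y <- sin(lat)
  z <- cos(lat) * sin(pol)
  azimuth <- (atan2(y, x) * 180 / pi) %% 360
  elevation <- asin(pmin(pmax(z, -1), 1)) * 180 / pi
  data.frame(azimuth = azimuth, elevation = elevation)
}
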