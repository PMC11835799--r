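#' Wrap angles to the interval (-pi, pi]
#'
#' All azimuths and phases in the package follow one convention: radians,
#' counterclockwise positive, azimuth measured from the +x axis, and wrapped
#' to the half-open interval (-pi, pi].
#'
#' @param angle Numeric vector of angles in radians. Must be finite.
#' @return Numeric vector of the same length, congruent to `angle` modulo
#'   2*pi and lying in (-pi, pi].
#' @examples
#' wrap_angle(3 * pi / 2) # -pi/2
#' wrap_angle(-pi)        # pi (half-open convention)
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle) || anyNA(angle) || any(!is.finite(angle))) {
    stop("wrap_angle(): 'angle' must be finite numeric", call. = FALSE)
  }
  # map to [-pi, pi), then move the closed end to +pi
  out <- angle - 2 * pi * floor((angle + pi) / (2 * pi))
  out[out == -pi] <- pi
  out
}

#' Convert degrees to radians
#' @param deg Numeric vector of angles in degrees.
#' @return Angles in radians (not wrapped).
#' @keywords internal
deg2rad <- function(deg) deg * pi / 180
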