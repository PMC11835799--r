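#' Phase coupling kernel
#'
#' The raised-cosine window `(1 + cos(theta)) / 2`: 1 for agents in phase,
#' 0 for agents in antiphase, even and 2*pi-periodic. It weights both the
#' phase-and-gaze-dependent attraction and the rotational coupling.
#'
#' @param phase_diff Phase difference(s) in radians (any finite value;
#'   the kernel is periodic so no wrapping is required).
#' @return Weights in `[0, 1]`.
#' @examples
#' phase_coupling(c(0, pi / 2, pi)) # 1, 0.5, 0
#' @export
phase_coupling <- function(phase_diff) {
  (1 + cos(phase_diff)) / 2
}

# Cache of gaze-kernel normalization constants, keyed by constriction value.
.gaze_norm_cache <- new.env(parent = emptyenv())

#' Normalization constant of the gaze kernel
#'
#' The integral of `((1 + cos(theta)) / 2)^c` over (-pi, pi]. Closed forms
#' are used for c = 0 (2*pi) and c = 1 (pi); other values are computed by
#' adaptive quadrature and cached per `c`.
#'
#' @param c Constriction, a scalar >= 0.
#' @return The scalar normalization constant.
#' @keywords internal
gaze_norm_const <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    stop("constriction 'c' must be a finite scalar >= 0", call. = FALSE)
  }
  if (c == 0) return(2 * pi)
  if (c == 1) return(pi)
  key <- format(c, digits = 17)
  if (!is.null(.gaze_norm_cache[[key]])) return(.gaze_norm_cache[[key]])
  val <- stats::integrate(function(th) ((1 + cos(th)) / 2)^c,
                          lower = -pi, upper = pi,
                          rel.tol = 1e-12, abs.tol = 1e-12)$value
  assign(key, val, envir = .gaze_norm_cache)
  val
}

#' Gaze coupling kernel (restricted visual field)
#'
#' A raised-cosine window raised to the constriction power `c` and
#' normalized to integrate to 1 over (-pi, pi]:
#' `Upsilon(theta; c) = ((1 + cos theta)/2)^c / Z(c)`. The argument is the
#' angle between an agent's gaze direction and the direction toward a
#' target. `c = 0` gives a uniform (omnidirectional) density `1/(2*pi)`;
#' increasing `c` narrows the field of view while keeping the mean value
#' of the kernel independent of `c`.
#'
#' @param angle Angle(s) in radians between gaze and target direction.
#' @param c Constriction, a scalar >= 0.
#' @return Non-negative densities; for `c > 0` the kernel is 0 directly
#'   behind the agent (`angle = pi`).
#' @examples
#' gaze_coupling(0, c = 0)   # 1/(2*pi)
#' gaze_coupling(0, c = 1)   # 1/pi
#' gaze_coupling(pi, c = 2)  # 0
#' @export
gaze_coupling <- function(angle, c) {
  z <- gaze_norm_const(c)
  base <- (1 + cos(angle)) / 2
  if (c == 0) {
    out <- rep(1, length(angle))
    out[] <- out / z
    if (is.matrix(angle)) dim(out) <- dim(angle)
    return(out)
  }
  base^c / z
}

#' Derivative kernel of the gaze coupling (rotational attraction)
#'
#' The kernel that drives the rotational dynamics:
#' `Upsilon'(theta; c) = (c sin(theta) / 2) * ((1 + cos theta)/2)^(c - 1)`.
#' With this (positive) sign the gaze rotates toward targets: the rate is
#' positive for targets counterclockwise of the gaze (`theta` in (0, pi)).
#' It is odd, 2*pi-periodic, and vanishes at `theta = 0` and (for c >= 1)
#' at `theta = pi`.
#'
#' For `c < 1/2` the kernel diverges as `theta` approaches pi; the exact
#' antipode (`(1 + cos theta)/2 == 0` in floating point) is mapped to 0,
#' since the gaze kernel itself vanishes there.
#'
#' When `normalized = TRUE` the value is divided by the same constant that
#' normalizes [gaze_coupling()], giving the (negated) exact derivative of
#' the normalized kernel; the default is the unnormalized form.
#'
#' @param angle Angle(s) in radians.
#' @param c Constriction, scalar >= 0.
#' @param normalized Divide by the gaze-kernel normalization constant?
#' @return Signed rates (rad/s scale factors).
#' @examples
#' gaze_coupling_derivative(pi / 2, c = 1) # 0.5
#' gaze_coupling_derivative(0, c = 1)      # 0
#' @export
gaze_coupling_derivative <- function(angle, c, normalized = FALSE) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    stop("constriction 'c' must be a finite scalar >= 0", call. = FALSE)
  }
  if (c == 0) {
    out <- angle * 0
    return(out)
  }
  base <- (1 + cos(angle)) / 2
  out <- (c * sin(angle) / 2) * base^(c - 1)
  out[base == 0] <- 0
  if (normalized) out <- out / gaze_norm_const(c)
  out
}
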