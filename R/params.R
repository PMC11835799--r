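#' Model parameters for the directional swarmalator system
#'
#' Bundles every coupling constant and exponent of the translational,
#' rotational and oscillatory dynamics, plus the constriction of the gaze
#' kernel and the spontaneous-frequency distribution. Defaults are the
#' fixed values used when fitting the model to silent-disco recordings;
#' the two free parameters of that fit, constriction `c` and gaze strength
#' `D`, default to their rounded fitted values of 0.25.
#'
#' @param A Global attraction strength toward the origin (1/s).
#' @param a Attraction range exponent (dimensionless); velocity grows as
#'   distance^a from the origin.
#' @param R Repulsion strength (1/s).
#' @param r Repulsion spatial decay exponent (proximity^r weighting).
#' @param P Phase-and-gaze-dependent attraction strength (1/s).
#' @param p Spatial decay exponent of the phase-and-gaze attraction.
#' @param D Gaze (rotational) attraction strength (rad/s); this is the
#'   "g" parameter of the calibration.
#' @param d Spatial decay exponent of the rotational coupling.
#' @param U Auditory entrainment strength (rad/s).
#' @param V Visual entrainment strength (rad/s).
#' @param v Spatial decay exponent of the visual entrainment.
#' @param c Constriction of the gaze kernel (dimensionless, >= 0). Larger
#'   values narrow the effective visual field; c = 0 gives omnidirectional
#'   vision.
#' @param freq_mean Mean of the spontaneous oscillation frequency
#'   distribution (rad/s). Defaults to 4*pi, the angular rate of a 120 BPM
#'   (2 Hz) bounce.
#' @param freq_sd Standard deviation of the spontaneous frequency (rad/s).
#' @param eps Minimum distance guard (length units) used wherever an
#'   inverse distance or unit vector is formed, so coincident agents never
#'   produce infinite forces.
#' @param normalized_gaze_derivative Logical; if `TRUE` the rotational
#'   kernel is divided by the same normalization constant as the gaze
#'   kernel itself. The default `FALSE` uses the unnormalized attractive
#'   form.
#' @return An object of class `swarm_params` (a validated list).
#' @examples
#' pars <- swarm_params()
#' pars$A
#' swarm_params(c = 0.5, D = 0.3)
#' @export
swarm_params <- function(A = 0.1, a = 1, R = 1.5, r = 2,
                         P = 0.5, p = 1,
                         D = 0.25, d = 1,
                         U = 0.8, V = 0.4, v = 1,
                         c = 0.25,
                         freq_mean = 4 * pi, freq_sd = 0.2,
                         eps = 1e-6,
                         normalized_gaze_derivative = FALSE) {
  pars <- list(A = A, a = a, R = R, r = r, P = P, p = p, D = D, d = d,
               U = U, V = V, v = v, c = c,
               freq_mean = freq_mean, freq_sd = freq_sd, eps = eps,
               normalized_gaze_derivative = isTRUE(normalized_gaze_derivative))
  num <- pars[setdiff(names(pars), "normalized_gaze_derivative")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("swarm_params(): non-finite or non-scalar parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nonneg <- c("A", "R", "P", "D", "U", "V", "c", "freq_sd", "eps")
  neg <- nonneg[vapply(nonneg, function(nm) pars[[nm]] < 0, logical(1))]
  if (length(neg)) {
    stop("swarm_params(): parameter(s) must be >= 0: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  if (pars$eps <= 0) stop("swarm_params(): 'eps' must be > 0", call. = FALSE)
  structure(pars, class = "swarm_params")
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("Directional swarmalator parameters:\n")
  flds <- setdiff(names(x), "normalized_gaze_derivative")
  cat(paste0("  ", format(flds, width = 10), " = ",
             vapply(x[flds], format, character(1))), sep = "\n")
  if (x$normalized_gaze_derivative) cat("  (normalized gaze derivative)\n")
  invisible(x)
}

# Names of swarm_params fields that hold angles when read from a config file.
# (none at present; kept for schedule/scenario configs which do hold angles)
.param_field_names <- function() {
  c("A", "a", "R", "r", "P", "p", "D", "d", "U", "V", "v", "c",
    "freq_mean", "freq_sd", "eps", "normalized_gaze_derivative")
}

#' Read model parameters (and optional run settings) from a YAML config
#'
#' The config may contain any subset of the `swarm_params()` fields under a
#' top-level `params:` key (or at the top level); unknown keys are rejected.
#' Angle-valued scenario fields (`phase_shift_deg`) may be given in degrees
#' and are converted on load.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` (`swarm_params`) and `scenario`
#'   (a named list of scenario overrides, possibly empty).
#' @seealso [swarm_params()], [scenario_spec()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_config(): file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  par_fields <- .param_field_names()
  raw_params <- if (!is.null(cfg$params)) cfg$params else cfg[names(cfg) %in% par_fields]
  scen <- if (!is.null(cfg$scenario)) cfg$scenario else list()
  known_top <- c("params", "scenario", par_fields)
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    stop("read_config(): unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_p <- setdiff(names(raw_params), par_fields)
  if (length(unknown_p)) {
    stop("read_config(): unknown parameter key(s): ",
         paste(unknown_p, collapse = ", "), call. = FALSE)
  }
  params <- do.call(swarm_params, raw_params)
  scen_fields <- c("n_agents", "group_sizes", "bpm", "phase_shift_deg",
                   "freq_ratio", "condition", "arena_radius", "phase_jitter_sd")
  unknown_s <- setdiff(names(scen), scen_fields)
  if (length(unknown_s)) {
    stop("read_config(): unknown scenario key(s): ",
         paste(unknown_s, collapse = ", "), call. = FALSE)
  }
  list(params = params, scenario = scen)
}
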