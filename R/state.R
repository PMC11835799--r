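#' Instantaneous state of a swarm of directional swarmalators
#'
#' Each agent carries five state variables: a 2-D position, an oscillation
#' phase, a gaze azimuth, a spontaneous oscillation frequency, and the
#' phase of the external stimulus it currently hears. Agents are assigned
#' to stimulus groups (e.g. the two headphone channels of a silent disco).
#'
#' @param positions Numeric matrix, N x 2, agent positions (length units).
#' @param phases Numeric vector of N oscillation phases (rad).
#' @param gazes Numeric vector of N gaze azimuths (rad); wrapped to
#'   (-pi, pi] on construction.
#' @param omega Numeric vector of N spontaneous frequencies (rad/s).
#' @param group_ids Integer vector of N stimulus-group labels.
#' @param stimulus_phases Numeric vector of N external stimulus phases
#'   (rad), usually filled in by the simulator from a
#'   [stimulus_schedule()]. Defaults to 0.
#' @return An object of class `swarm_state`.
#' @examples
#' st <- swarm_state(positions = cbind(c(0, 1), c(0, 0)),
#'                   phases = c(0, pi / 2), gazes = c(0, pi),
#'                   omega = c(4 * pi, 4 * pi), group_ids = c(1L, 2L))
#' st$n
#' @export
swarm_state <- function(positions, phases, gazes, omega,
                        group_ids = rep(1L, nrow(positions)),
                        stimulus_phases = rep(0, nrow(positions))) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) {
    stop("swarm_state(): 'positions' must be an N x 2 matrix", call. = FALSE)
  }
  n <- nrow(positions)
  if (n < 1L) stop("swarm_state(): need at least one agent", call. = FALSE)
  for (nm in c("phases", "gazes", "omega", "stimulus_phases")) {
    val <- get(nm)
    if (length(val) != n || !is.numeric(val) || any(!is.finite(val))) {
      stop("swarm_state(): '", nm, "' must be finite numeric of length N = ",
           n, call. = FALSE)
    }
  }
  if (any(!is.finite(positions))) {
    stop("swarm_state(): non-finite positions", call. = FALSE)
  }
  if (length(group_ids) != n || anyNA(group_ids)) {
    stop("swarm_state(): 'group_ids' must assign every agent to a group",
         call. = FALSE)
  }
  structure(list(
    positions = unname(positions),
    phases = as.numeric(phases),
    gazes = wrap_angle(as.numeric(gazes)),
    omega = as.numeric(omega),
    group_ids = as.integer(group_ids),
    stimulus_phases = as.numeric(stimulus_phases),
    n = n
  ), class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat("swarm_state:", x$n, "agents,",
      length(unique(x$group_ids)), "stimulus group(s)\n")
  invisible(x)
}

#' Pairwise geometry of a swarm configuration
#'
#' Computes the full pairwise Euclidean distance matrix, the proximity
#' matrix (inverse distance, guarded below by `eps` so coincident agents
#' never produce infinite proximity), and the azimuth matrix. Entry
#' `azimuth[j, k]` is the azimuth of the vector pointing from agent j to
#' agent k, measured counterclockwise from the +x axis; consequently
#' `azimuth[k, j] = wrap_angle(azimuth[j, k] + pi)`. Diagonal entries of
#' the proximity and azimuth matrices are not meaningful and are set to
#' `NA` for distances/azimuths and 0 for proximity weights.
#'
#' @param positions Numeric N x 2 matrix of positions.
#' @param eps Minimum-distance guard (length units).
#' @return A list of class `pairwise_geometry` with elements `dist`
#'   (N x N), `prox` (N x N, zero diagonal), `azimuth` (N x N, `NA`
#'   diagonal), plus the guarded distance `dist_guarded` and the unit
#'   displacement components `ux`, `uy` (from row-agent toward
#'   column-agent), which the dynamics reuse.
#' @examples
#' g <- pairwise_geometry(rbind(c(0, 0), c(3, 4)))
#' g$dist[1, 2]     # 5
#' g$prox[1, 2]     # 0.2
#' g$azimuth[1, 2]  # atan2(4, 3)
#' @export
pairwise_geometry <- function(positions, eps = 1e-6) {
  positions <- as.matrix(positions)
  if (any(!is.finite(positions))) {
    stop("pairwise_geometry(): non-finite positions", call. = FALSE)
  }
  n <- nrow(positions)
  dxx <- matrix(positions[, 1], n, n, byrow = TRUE) - positions[, 1]
  dyy <- matrix(positions[, 2], n, n, byrow = TRUE) - positions[, 2]
  dist <- sqrt(dxx * dxx + dyy * dyy)
  distg <- pmax(dist, eps)
  prox <- 1 / distg
  diag(prox) <- 0
  azimuth <- atan2(dyy, dxx)
  diag(azimuth) <- NA_real_
  ux <- dxx / distg
  uy <- dyy / distg
  diag(dist) <- NA_real_
  structure(list(dist = dist, dist_guarded = distg, prox = prox,
                 azimuth = azimuth, ux = ux, uy = uy, n = n, eps = eps),
            class = "pairwise_geometry")
}
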