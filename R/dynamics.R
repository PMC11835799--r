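#' Translational dynamics: global attraction toward the origin
#'
#' Each agent is pulled toward the origin of the arena with speed
#' `A * |x|^a`, i.e. velocity `-A * x * |x|^(a - 1)`. This bounds the
#' swarm without modelling walls. For `a < 1` the distance is guarded by
#' `eps` so agents at the origin produce a finite (zero) velocity.
#'
#' @param state A [swarm_state()].
#' @param params A [swarm_params()].
#' @return N x 2 matrix of velocities (length/s).
#' @export
attraction_velocity <- function(state, params) {
  x <- state$positions
  nx <- sqrt(rowSums(x * x))
  scale <- if (params$a == 1) {
    rep(params$A, length(nx))
  } else {
    params$A * pmax(nx, params$eps)^(params$a - 1)
  }
  -x * scale
}

#' Translational dynamics: short-range pairwise repulsion
#'
#' Repulsion keeps agents from coalescing: agent j is pushed away from
#' each neighbour k along the unit vector from k to j with weight equal to
#' proximity (inverse distance) to the power `r`, averaged over the swarm:
#' `-(R/N) * sum_{k != j} w_jk^r * (x_k - x_j)/|x_k - x_j|`.
#'
#' @inheritParams attraction_velocity
#' @param geometry A [pairwise_geometry()] for `state$positions`.
#' @return N x 2 matrix of velocities (length/s). Zero for a single agent.
#' @export
repulsion_velocity <- function(state, geometry, params) {
  n <- state$n
  if (n == 1L) return(matrix(0, 1, 2))
  M <- geometry$prox^params$r
  diag(M) <- 0
  cbind(-(params$R / n) * rowSums(M * geometry$ux),
        -(params$R / n) * rowSums(M * geometry$uy))
}

#' Translational dynamics: phase-and-gaze-dependent attraction
#'
#' Agent j is attracted toward agents it can see (gaze kernel of the angle
#' between its gaze and the direction to the target) that oscillate in a
#' similar phase (raised-cosine phase kernel), with proximity weighting:
#' `(P/N) * sum_{k != j} w_jk^p * Omega(theta_k - theta_j) *
#' Upsilon(alpha_kj - delta_j) * (x_k - x_j)/|x_k - x_j|`.
#'
#' @inheritParams repulsion_velocity
#' @return N x 2 matrix of velocities (length/s).
#' @export
phase_gaze_velocity <- function(state, geometry, params) {
  n <- state$n
  if (n == 1L) return(matrix(0, 1, 2))
  thd <- matrix(state$phases, n, n, byrow = TRUE) - state$phases
  arg <- geometry$azimuth - state$gazes
  arg[is.na(arg)] <- 0  # diagonal; masked below
  M <- geometry$prox^params$p * phase_coupling(thd) *
    gaze_coupling(arg, params$c)
  diag(M) <- 0
  cbind((params$P / n) * rowSums(M * geometry$ux),
        (params$P / n) * rowSums(M * geometry$uy))
}

#' Total instantaneous velocity (attraction + repulsion + phase-gaze)
#'
#' @inheritParams repulsion_velocity
#' @return N x 2 matrix: the exact componentwise sum of
#'   [attraction_velocity()], [repulsion_velocity()] and
#'   [phase_gaze_velocity()].
#' @export
total_velocity <- function(state, geometry, params) {
  attraction_velocity(state, params) +
    repulsion_velocity(state, geometry, params) +
    phase_gaze_velocity(state, geometry, params)
}

#' Rotational dynamics: gaze attraction rate
#'
#' The gaze of agent j is rotated toward neighbours, most strongly toward
#' those that are proximal and similar in phase:
#' `(D/N) * sum_{k != j} w_jk^d * Upsilon'(alpha_kj - delta_j) *
#' Omega(theta_k - theta_j)`, with the derivative kernel from
#' [gaze_coupling_derivative()].
#'
#' @inheritParams repulsion_velocity
#' @return Numeric vector of N gaze rates (rad/s).
#' @export
gaze_rate <- function(state, geometry, params) {
  n <- state$n
  if (n == 1L) return(0)
  thd <- matrix(state$phases, n, n, byrow = TRUE) - state$phases
  arg <- geometry$azimuth - state$gazes
  arg[is.na(arg)] <- 0
  M <- geometry$prox^params$d *
    gaze_coupling_derivative(arg, params$c,
                             normalized = params$normalized_gaze_derivative) *
    phase_coupling(thd)
  diag(M) <- 0
  (params$D / n) * rowSums(M)
}

#' Oscillatory dynamics: auditory entrainment to the external stimulus
#'
#' Kuramoto-type coupling of each agent's phase to the beat it hears:
#' `U * sin(phi_j - theta_j)`.
#'
#' @inheritParams attraction_velocity
#' @return Numeric vector of N phase rates (rad/s).
#' @export
auditory_phase_rate <- function(state, params) {
  params$U * sin(state$stimulus_phases - state$phases)
}

#' Oscillatory dynamics: visual entrainment to visible neighbours
#'
#' `(V/N) * sum_{k != j} w_jk^v * Upsilon(alpha_kj - delta_j) *
#' sin(theta_k - theta_j)`: each agent's phase is pulled toward the phases
#' of neighbours it can see, with proximity weighting.
#'
#' @inheritParams repulsion_velocity
#' @return Numeric vector of N phase rates (rad/s).
#' @export
visual_phase_rate <- function(state, geometry, params) {
  n <- state$n
  if (n == 1L) return(0)
  thd <- matrix(state$phases, n, n, byrow = TRUE) - state$phases
  arg <- geometry$azimuth - state$gazes
  arg[is.na(arg)] <- 0
  M <- geometry$prox^params$v * gaze_coupling(arg, params$c) * sin(thd)
  diag(M) <- 0
  (params$V / n) * rowSums(M)
}

#' Total phase rate (spontaneous + auditory + visual)
#'
#' @inheritParams repulsion_velocity
#' @return Numeric vector of N phase rates (rad/s): the exact sum of the
#'   spontaneous frequencies, [auditory_phase_rate()] and
#'   [visual_phase_rate()].
#' @export
total_phase_rate <- function(state, geometry, params) {
  state$omega + auditory_phase_rate(state, params) +
    visual_phase_rate(state, geometry, params)
}

#' All derivatives of the swarm state at one instant
#'
#' Computes the full right-hand side of the coupled system in one pass,
#' sharing the pairwise geometry and kernels across terms. Component
#' contributions are returned alongside the totals (the totals are their
#' exact sums), which makes the individual terms loggable for diagnostics.
#'
#' @inheritParams attraction_velocity
#' @param geometry Optional precomputed [pairwise_geometry()]; computed
#'   from the state if missing.
#' @return A list of class `swarm_derivatives` with elements `velocity`
#'   (N x 2), `gaze_rate` (N), `phase_rate` (N) and a `components` list
#'   holding `velocity_attraction`, `velocity_repulsion`,
#'   `velocity_phase_gaze`, `phase_rate_auditory`, `phase_rate_visual`.
#' @export
swarm_derivatives <- function(state, params, geometry = NULL) {
  n <- state$n
  if (is.null(geometry)) geometry <- pairwise_geometry(state$positions, params$eps)
  vA <- attraction_velocity(state, params)
  if (n == 1L) {
    vR <- vP <- matrix(0, 1, 2)
    drate <- 0
    aud <- auditory_phase_rate(state, params)
    vis <- 0
  } else {
    thd <- matrix(state$phases, n, n, byrow = TRUE) - state$phases
    Om <- phase_coupling(thd)
    arg <- geometry$azimuth - state$gazes
    arg[is.na(arg)] <- 0
    Ups <- gaze_coupling(arg, params$c)
    Upsp <- gaze_coupling_derivative(arg, params$c,
                                     normalized = params$normalized_gaze_derivative)
    Mr <- geometry$prox^params$r
    diag(Mr) <- 0
    Mp <- geometry$prox^params$p * Om * Ups
    diag(Mp) <- 0
    Mg <- geometry$prox^params$d * Upsp * Om
    diag(Mg) <- 0
    Mv <- geometry$prox^params$v * Ups * sin(thd)
    diag(Mv) <- 0
    vR <- cbind(-(params$R / n) * rowSums(Mr * geometry$ux),
                -(params$R / n) * rowSums(Mr * geometry$uy))
    vP <- cbind((params$P / n) * rowSums(Mp * geometry$ux),
                (params$P / n) * rowSums(Mp * geometry$uy))
    drate <- (params$D / n) * rowSums(Mg)
    aud <- auditory_phase_rate(state, params)
    vis <- (params$V / n) * rowSums(Mv)
  }
  structure(list(
    velocity = vA + vR + vP,
    gaze_rate = drate,
    phase_rate = state$omega + aud + vis,
    components = list(velocity_attraction = vA,
                      velocity_repulsion = vR,
                      velocity_phase_gaze = vP,
                      phase_rate_auditory = aud,
                      phase_rate_visual = vis)
  ), class = "swarm_derivatives")
}
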