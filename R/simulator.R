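#' Per-group external stimulus schedule
#'
#' Defines the beat each stimulus group hears: a frequency in Hz (120 BPM
#' corresponds to 2 Hz) and a phase offset in radians. The phase of the
#' stimulus for group g at time t is `wrap(2*pi*f_g*t + offset_g)`; it is
#' prescribed, not integrated.
#'
#' @param freq_hz Numeric vector of beat frequencies, one per group (Hz,
#'   all > 0).
#' @param offset Numeric vector of phase offsets, one per group (rad);
#'   wrapped on construction. Recycled to the length of `freq_hz`.
#' @param group_ids Optional integer vector of the group labels these
#'   entries correspond to; defaults to `1:length(freq_hz)`.
#' @return An object of class `stimulus_schedule`.
#' @examples
#' # two groups, 120 BPM, second group 180 degrees out of phase
#' sched <- stimulus_schedule(freq_hz = c(2, 2), offset = c(0, pi))
#' stimulus_phase(sched, group = 2, t = 0) # pi
#' @export
stimulus_schedule <- function(freq_hz, offset = 0,
                              group_ids = seq_along(freq_hz)) {
  if (any(!is.finite(freq_hz)) || any(freq_hz <= 0)) {
    stop("stimulus_schedule(): frequencies must be positive and finite",
         call. = FALSE)
  }
  offset <- rep_len(offset, length(freq_hz))
  structure(list(freq_hz = as.numeric(freq_hz),
                 offset = wrap_angle(as.numeric(offset)),
                 group_ids = as.integer(group_ids)),
            class = "stimulus_schedule")
}

#' Stimulus phase for a group at a given time
#'
#' @param schedule A [stimulus_schedule()].
#' @param group Integer group label(s).
#' @param t Time(s) in seconds, >= 0.
#' @return Phase(s) in radians, wrapped to (-pi, pi]. Vectorized over
#'   `group` and `t` (recycled against each other).
#' @export
stimulus_phase <- function(schedule, group, t) {
  idx <- match(as.integer(group), schedule$group_ids)
  if (anyNA(idx)) {
    stop("stimulus_phase(): unknown group id(s): ",
         paste(unique(group[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  wrap_angle(2 * pi * schedule$freq_hz[idx] * t + schedule$offset[idx])
}

# Internal unvalidated Euler update used by the integration loop.
# Returns the raw state fields; `phi` must be the stimulus phases at time t.
.euler_update <- function(x, theta, delta, omega, phi, params, dt, geometry) {
  st <- list(positions = x, phases = theta, gazes = delta, omega = omega,
             stimulus_phases = phi, n = nrow(x))
  dv <- swarm_derivatives(structure(st, class = "swarm_state"), params,
                          geometry = geometry)
  list(x = x + dv$velocity * dt,
       theta = theta + dv$phase_rate * dt,
       delta = delta + dv$gaze_rate * dt,
       deriv = dv)
}

#' One explicit Euler step of the swarm dynamics
#'
#' Advances positions, gaze azimuths and oscillation phases by `dt` using
#' the forward Euler method; gaze and phase are wrapped to (-pi, pi]
#' after the update. The external stimulus phase is not integrated: it is
#' re-evaluated from the schedule at `t + dt`.
#'
#' @param state A [swarm_state()] at time `t`. Its `stimulus_phases` are
#'   recomputed from the schedule at `t` before the step, so a stale field
#'   cannot leak into the derivative.
#' @param schedule A [stimulus_schedule()] covering every group in the
#'   state.
#' @param params A [swarm_params()].
#' @param t Current time (s).
#' @param dt Step size (s), > 0.
#' @return The [swarm_state()] at `t + dt`.
#' @export
euler_step <- function(state, schedule, params, t, dt) {
  if (!is.numeric(dt) || dt <= 0) {
    stop("euler_step(): 'dt' must be > 0", call. = FALSE)
  }
  phi <- stimulus_phase(schedule, state$group_ids, t)
  up <- .euler_update(state$positions, state$phases, state$gazes,
                      state$omega, phi, params, dt,
                      geometry = pairwise_geometry(state$positions, params$eps))
  .check_finite_derivatives(up$deriv, frame = NA_integer_)
  swarm_state(positions = up$x,
              phases = wrap_angle(up$theta),
              gazes = wrap_angle(up$delta),
              omega = state$omega,
              group_ids = state$group_ids,
              stimulus_phases = stimulus_phase(schedule, state$group_ids, t + dt))
}

.check_finite_derivatives <- function(dv, frame) {
  terms <- c(velocity = all(is.finite(dv$velocity)),
             gaze_rate = all(is.finite(dv$gaze_rate)),
             phase_rate = all(is.finite(dv$phase_rate)))
  if (!all(terms)) {
    stop("non-finite derivative in term(s): ",
         paste(names(terms)[!terms], collapse = ", "),
         if (!is.na(frame)) paste0(" at frame ", frame) else "",
         call. = FALSE)
  }
}

#' Simulate a swarm trajectory with fixed-step Euler integration
#'
#' Integrates the coupled translational, rotational and oscillatory
#' dynamics from an initial configuration for `duration` seconds with
#' step `dt` (default 1/120 s, the motion-capture frame period), storing
#' every frame. If the initial state carries no spontaneous frequencies
#' (`omega = NULL` in `initial_state`, see below), they are drawn once
#' from Normal(`freq_mean`, `freq_sd`) using `seed`.
#'
#' @param initial_state A [swarm_state()] providing positions, gazes,
#'   phases and group assignments at t = 0. Its `omega` field is used as
#'   the spontaneous frequencies unless `draw_omega = TRUE`.
#' @param schedule A [stimulus_schedule()].
#' @param params A [swarm_params()].
#' @param duration Total simulated time (s), > 0.
#' @param dt Step size (s); `duration/dt` should be integral.
#' @param seed Optional integer seed; with `draw_omega = TRUE` it makes
#'   the frequency draw (and hence the whole trajectory) reproducible.
#' @param draw_omega If `TRUE`, ignore `initial_state$omega` and draw
#'   spontaneous frequencies from the parameter distribution.
#' @param divergence_bound Abort (with the offending frame index) if any
#'   position coordinate exceeds this magnitude.
#' @return An object of class `swarm_trajectory`: a list with `times`
#'   (length T), `positions` (N x 2 x T), `phases`, `gazes`, `phi`
#'   (N x T each), `omega`, `group_ids`, `params`, `schedule`, `seed`.
#'   A run of 60 s at dt = 1/120 yields T = 7201 frames.
#' @examples
#' st <- swarm_state(positions = cbind(runif(3), runif(3)),
#'                   phases = rep(0, 3), gazes = rep(0, 3),
#'                   omega = rep(4 * pi, 3), group_ids = rep(1L, 3))
#' traj <- run_simulation(st, stimulus_schedule(2), swarm_params(),
#'                        duration = 1, dt = 1 / 120)
#' dim(traj$positions) # 3 x 2 x 121
#' @export
run_simulation <- function(initial_state, schedule, params,
                           duration = 60, dt = 1 / 120,
                           seed = NULL, draw_omega = FALSE,
                           divergence_bound = 1e3) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("run_simulation(): 'duration' must be > 0", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) {
    stop("run_simulation(): 'dt' must be > 0", call. = FALSE)
  }
  n <- initial_state$n
  nsteps <- round(duration / dt)
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  omega <- initial_state$omega
  if (draw_omega) {
    if (!is.null(seed)) set.seed(seed)
    omega <- stats::rnorm(n, params$freq_mean, params$freq_sd)
  }
  x <- initial_state$positions
  theta <- initial_state$phases
  delta <- initial_state$gazes
  grp <- initial_state$group_ids
  pos_arr <- array(NA_real_, c(n, 2L, nsteps + 1L))
  th_arr <- matrix(NA_real_, n, nsteps + 1L)
  de_arr <- matrix(NA_real_, n, nsteps + 1L)
  ph_arr <- matrix(NA_real_, n, nsteps + 1L)
  idx <- match(grp, schedule$group_ids)
  if (anyNA(idx)) stop("run_simulation(): state contains group ids absent from schedule",
                       call. = FALSE)
  f <- schedule$freq_hz[idx]
  off <- schedule$offset[idx]
  phi <- wrap_angle(off)
  pos_arr[, , 1L] <- x
  th_arr[, 1L] <- theta
  de_arr[, 1L] <- delta
  ph_arr[, 1L] <- phi
  eps <- params$eps
  for (s in seq_len(nsteps)) {
    geom <- pairwise_geometry(x, eps)
    up <- .euler_update(x, theta, delta, omega, phi, params, dt, geom)
    x <- up$x
    theta <- wrap_angle2(up$theta)
    delta <- wrap_angle2(up$delta)
    if (anyNA(x) || max(abs(x)) > divergence_bound) {
      if (any(!is.finite(up$x)) || any(!is.finite(theta)) || any(!is.finite(delta))) {
        .check_finite_derivatives(up$deriv, frame = s)
      }
      stop("run_simulation(): trajectory diverged (|x| > ", divergence_bound,
           ") at frame ", s, call. = FALSE)
    }
    phi <- wrap_angle2(2 * pi * f * times[s + 1L] + off)
    pos_arr[, , s + 1L] <- x
    th_arr[, s + 1L] <- theta
    de_arr[, s + 1L] <- delta
    ph_arr[, s + 1L] <- phi
  }
  structure(list(times = times, positions = pos_arr, phases = th_arr,
                 gazes = de_arr, phi = ph_arr, omega = omega,
                 group_ids = grp, params = params, schedule = schedule,
                 dt = dt, seed = seed),
            class = "swarm_trajectory")
}

# wrap without validity checks (hot path); NaN/Inf pass through and are
# caught by the divergence check
wrap_angle2 <- function(angle) {
  out <- angle - 2 * pi * floor((angle + pi) / (2 * pi))
  out[out == -pi] <- pi
  out
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat("swarm_trajectory:", dim(x$positions)[1], "agents,",
      length(x$times), "frames, dt =", format(x$dt), "s\n")
  invisible(x)
}

#' Extract one frame of a trajectory as a swarm_state
#'
#' @param trajectory A [run_simulation()] result.
#' @param frame Frame index (1-based; defaults to the final frame).
#' @return A [swarm_state()].
#' @export
trajectory_frame <- function(trajectory, frame = length(trajectory$times)) {
  swarm_state(positions = matrix(trajectory$positions[, , frame], ncol = 2),
              phases = trajectory$phases[, frame],
              gazes = trajectory$gazes[, frame],
              omega = trajectory$omega,
              group_ids = trajectory$group_ids,
              stimulus_phases = trajectory$phi[, frame])
}

#' Write a trajectory to the state CSV schema
#'
#' One row per agent per frame with columns `time_s, agent_id, group_id,
#' x, y, theta_rad, delta_rad, omega_rad_s, phi_rad`.
#'
#' @param trajectory A `swarm_trajectory`.
#' @param path Output file path.
#' @param header_comment Optional character vector written as `#`-prefixed
#'   comment lines before the header.
#' @return `path`, invisibly.
#' @export
write_states <- function(trajectory, path, header_comment = NULL) {
  df <- as.data.frame(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.swarm_trajectory <- function(x, ...) {
  n <- dim(x$positions)[1]
  tt <- length(x$times)
  data.frame(
    time_s = rep(x$times, each = n),
    agent_id = rep(seq_len(n), times = tt),
    group_id = rep(x$group_ids, times = tt),
    x = as.vector(x$positions[, 1, ]),
    y = as.vector(x$positions[, 2, ]),
    theta_rad = as.vector(x$phases),
    delta_rad = as.vector(x$gazes),
    omega_rad_s = rep(x$omega, times = tt),
    phi_rad = as.vector(x$phi)
  )
}

#' Read a state CSV back into a trajectory-like object
#'
#' Accepts the schema written by [write_states()] (and by the marker
#' ingestion workflow, where `omega_rad_s`/`phi_rad` may be `NA`).
#' Comment lines starting with `#` are skipped.
#'
#' @param path Path to a state CSV.
#' @return A `swarm_trajectory` (with `params`, `schedule`, `seed` set to
#'   `NULL`); time-dependent fields are reconstructed from the rows.
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "agent_id", "group_id", "x", "y", "theta_rad", "delta_rad")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_states(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  agents <- sort(unique(df$agent_id))
  n <- length(agents)
  times <- sort(unique(df$time_s))
  tt <- length(times)
  if (nrow(df) != n * tt) {
    stop("read_states(): expected one row per agent per frame", call. = FALSE)
  }
  df <- df[order(df$time_s, df$agent_id), ]
  grab <- function(col) matrix(df[[col]], n, tt)
  pos <- array(NA_real_, c(n, 2L, tt))
  pos[, 1, ] <- grab("x")
  pos[, 2, ] <- grab("y")
  omega <- if ("omega_rad_s" %in% names(df)) grab("omega_rad_s")[, 1] else rep(NA_real_, n)
  phi <- if ("phi_rad" %in% names(df)) grab("phi_rad") else matrix(NA_real_, n, tt)
  structure(list(times = times, positions = pos, phases = grab("theta_rad"),
                 gazes = grab("delta_rad"), phi = phi, omega = omega,
                 group_ids = grab("group_id")[, 1], params = NULL,
                 schedule = NULL,
                 dt = if (tt > 1) stats::median(diff(times)) else NA_real_,
                 seed = NULL),
            class = "swarm_trajectory")
}
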