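#' Scenario specification for a synthetic silent-disco session
#'
#' Describes the study conditions the generators emulate: a dozen
#' participants split into two headphone groups bouncing to a 120 BPM
#' beat, with the second group hearing the stimulus phase-shifted (90 or
#' 180 degrees) or sped up.
#'
#' @param n_agents Number of agents (default 12).
#' @param group_sizes Sizes of the stimulus groups; must sum to
#'   `n_agents`. Default: an even split into two groups.
#' @param bpm Stimulus tempo in beats per minute (> 0); 120 BPM is the
#'   tactus of the recordings the generators emulate.
#' @param condition One of `"phase_90"`, `"phase_180"`, `"sped_up"`,
#'   `"uniform"`: how group 2's stimulus differs from group 1's.
#' @param freq_ratio Frequency ratio of the sped-up stimulus (group 2
#'   tempo = `bpm * freq_ratio`).
#' @param phase_shift_deg Optional explicit phase shift for group 2's
#'   stimulus, in degrees (overrides the shift implied by `condition`).
#' @param arena_radius Radius of the disc initial positions are drawn
#'   from (length units).
#' @param phase_jitter_sd SD of the initial phase jitter around each
#'   agent's stimulus phase (rad).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_agents = 12L, group_sizes = NULL, bpm = 120,
                          condition = c("phase_90", "phase_180", "sped_up",
                                        "uniform"),
                          freq_ratio = 1.25, phase_shift_deg = NULL,
                          arena_radius = 3, phase_jitter_sd = 0.2) {
  condition <- match.arg(condition)
  n_agents <- as.integer(n_agents)
  if (n_agents < 1L) stop("scenario_spec(): n_agents must be >= 1",
                          call. = FALSE)
  if (is.null(group_sizes)) {
    group_sizes <- if (condition == "uniform" || n_agents == 1L) n_agents else
      c(ceiling(n_agents / 2), floor(n_agents / 2))
  }
  if (sum(group_sizes) != n_agents) {
    stop("scenario_spec(): group sizes must sum to n_agents", call. = FALSE)
  }
  if (bpm <= 0) stop("scenario_spec(): bpm must be > 0", call. = FALSE)
  structure(list(n_agents = n_agents, group_sizes = as.integer(group_sizes),
                 bpm = bpm, condition = condition, freq_ratio = freq_ratio,
                 phase_shift_deg = phase_shift_deg,
                 arena_radius = arena_radius,
                 phase_jitter_sd = phase_jitter_sd),
            class = "scenario_spec")
}

#' Stimulus schedule implied by a scenario
#'
#' Group 1 hears the base tempo with zero offset; group 2 hears it with a
#' 90- or 180-degree phase shift or sped up, depending on the condition.
#'
#' @param spec A [scenario_spec()].
#' @return A [stimulus_schedule()] with one entry per group.
#' @export
scenario_schedule <- function(spec) {
  f <- spec$bpm / 60
  ng <- length(spec$group_sizes)
  if (ng == 1L) return(stimulus_schedule(f, 0))
  freq <- rep(f, ng)
  off <- rep(0, ng)
  if (spec$condition == "phase_90") off[2] <- pi / 2
  if (spec$condition == "phase_180") off[2] <- pi
  if (spec$condition == "sped_up") freq[2] <- f * spec$freq_ratio
  if (!is.null(spec$phase_shift_deg)) off[2] <- deg2rad(spec$phase_shift_deg)
  stimulus_schedule(freq, off)
}

.scenario_groups <- function(spec) {
  rep(seq_along(spec$group_sizes), spec$group_sizes)
}

#' Generate a random initial swarm configuration
#'
#' Positions are drawn uniformly in a disc of the arena radius, gaze
#' azimuths uniformly on (-pi, pi], oscillation phases at each agent's
#' stimulus phase at t = 0 plus Gaussian jitter, and spontaneous
#' frequencies from Normal(`freq_mean`, `freq_sd`). Deterministic given
#' the seed.
#'
#' @param spec A [scenario_spec()].
#' @param params A [swarm_params()] (supplies the frequency
#'   distribution).
#' @param seed Integer seed.
#' @return A [swarm_state()] (with `stimulus_phases` at t = 0).
#' @export
generate_initial_config <- function(spec, params = swarm_params(),
                                    seed = 1L) {
  set.seed(seed)
  n <- spec$n_agents
  grp <- .scenario_groups(spec)
  sched <- scenario_schedule(spec)
  rr <- spec$arena_radius * sqrt(stats::runif(n))
  aa <- stats::runif(n, -pi, pi)
  pos <- cbind(rr * cos(aa), rr * sin(aa))
  gazes <- stats::runif(n, -pi, pi)
  phi0 <- stimulus_phase(sched, grp, 0)
  phases <- wrap_angle(phi0 + stats::rnorm(n, 0, spec$phase_jitter_sd))
  omega <- stats::rnorm(n, params$freq_mean, params$freq_sd)
  swarm_state(positions = pos, phases = phases, gazes = gazes,
              omega = omega, group_ids = grp, stimulus_phases = phi0)
}

#' Generate synthetic head-marker recordings of bouncing agents
#'
#' Emulates the raw material of a silent-disco motion capture: each agent
#' stands at a position that drifts slowly and smoothly, carries a fixed
#' heading, and bounces vertically as a sinusoid at its group's stimulus
#' frequency and phase offset. Two head markers (left/right) sit at a
#' fixed horizontal half-width perpendicular to the heading; Gaussian
#' measurement noise of configurable SD is added to every coordinate.
#' Deterministic given the seed.
#'
#' @param spec A [scenario_spec()].
#' @param duration Recording length (s).
#' @param rate Sampling rate (Hz), nominally 120.
#' @param noise_sd Marker noise SD (length units).
#' @param bounce_amp Vertical bounce amplitude (length units).
#' @param head_halfwidth Half the inter-marker distance (length units).
#' @param drift_amp Amplitude of the slow horizontal drift.
#' @param seed Integer seed.
#' @return A `marker_series` data.frame (schema of
#'   [read_marker_series()]) with attribute `rate_hz`.
#' @export
generate_bounce_markers <- function(spec, duration = 60, rate = 120,
                                    noise_sd = 0, bounce_amp = 0.05,
                                    head_halfwidth = 0.08,
                                    drift_amp = 0.3, seed = 1L) {
  set.seed(seed)
  n <- spec$n_agents
  grp <- .scenario_groups(spec)
  sched <- scenario_schedule(spec)
  tgrid <- seq(0, duration, by = 1 / rate)
  nt <- length(tgrid)
  rr <- spec$arena_radius * sqrt(stats::runif(n))
  aa <- stats::runif(n, -pi, pi)
  cx <- rr * cos(aa)
  cy <- rr * sin(aa)
  heading <- stats::runif(n, -pi, pi)
  drift_f <- stats::runif(n, 0.02, 0.06)    # Hz, well below the beat
  drift_ph <- stats::runif(n, -pi, pi)
  base_z <- 1.5
  pieces <- vector("list", 2L * n)
  for (j in seq_len(n)) {
    phase_t <- 2 * pi * sched$freq_hz[grp[j]] * tgrid +
      sched$offset[grp[j]]
    px <- cx[j] + drift_amp * cos(2 * pi * drift_f[j] * tgrid + drift_ph[j])
    py <- cy[j] + drift_amp * sin(2 * pi * drift_f[j] * tgrid + drift_ph[j])
    pz <- base_z - bounce_amp * cos(phase_t)
    # left marker sits at heading + 90 degrees, right at heading - 90
    ox <- head_halfwidth * cos(heading[j] + pi / 2)
    oy <- head_halfwidth * sin(heading[j] + pi / 2)
    for (side in c("L", "R")) {
      sgn <- if (side == "L") 1 else -1
      pieces[[2L * (j - 1L) + (side == "R") + 1L]] <- data.frame(
        time_s = tgrid, agent_id = j, group_id = grp[j], marker = side,
        x = px + sgn * ox + stats::rnorm(nt, 0, noise_sd),
        y = py + sgn * oy + stats::rnorm(nt, 0, noise_sd),
        z = pz + stats::rnorm(nt, 0, noise_sd))
    }
  }
  res <- do.call(rbind, pieces)
  res <- res[order(res$time_s, res$agent_id, res$marker), ]
  rownames(res) <- NULL
  structure(res, class = c("marker_series", "data.frame"),
            rate_hz = rate, n_interpolated = 0L)
}

#' Generate synthetic calibration targets from known parameters
#'
#' Stands in for empirical calibration datasets: for each scenario, draws
#' an initial configuration, simulates the model with known constriction
#' `c_true` and gaze strength `g_true` (all other parameters fixed), and
#' records the three target metrics — spatial variance, grouping
#' coefficient and centroidal alignment — at the evaluation time. By
#' construction the composite error at `(c_true, g_true)` is exactly 0.
#'
#' @param specs A [scenario_spec()] or list of them (one per dataset).
#' @param c_true,g_true Generating constriction and gaze strength, both
#'   in `[0, 1]`.
#' @param params Base [swarm_params()]; its `c` and `D` are overridden.
#' @param duration,dt Simulation length and step (s).
#' @param eval_window Seconds at the end of the run over which target
#'   metrics are averaged (0 = final frame only).
#' @param seed Integer seed (dataset i uses `seed + i - 1`).
#' @return An object of class `calibration_targets`: a list with
#'   `datasets` (each holding `id`, `initial_state`, `schedule`,
#'   `targets` = named vector of the three metrics), `duration`, `dt`,
#'   `eval_window`, `c_true`, `g_true`.
#' @export
generate_calibration_scenario <- function(specs = scenario_spec(),
                                          c_true = 0.25, g_true = 0.25,
                                          params = swarm_params(),
                                          duration = 60, dt = 1 / 120,
                                          eval_window = 0, seed = 1L) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (any(c(c_true, g_true) < 0)) {
    stop("generate_calibration_scenario(): c_true and g_true must be >= 0",
         call. = FALSE)
  }
  gen_params <- params
  gen_params$c <- c_true
  gen_params$D <- g_true
  datasets <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    st <- generate_initial_config(specs[[i]], params = params,
                                  seed = seed + i - 1L)
    sched <- scenario_schedule(specs[[i]])
    traj <- run_simulation(st, sched, gen_params, duration = duration,
                           dt = dt)
    datasets[[i]] <- list(id = paste0("synthetic_", specs[[i]]$condition,
                                      "_", i),
                          initial_state = st, schedule = sched,
                          targets = .target_metrics(traj, eval_window))
  }
  structure(list(datasets = datasets, duration = duration, dt = dt,
                 eval_window = eval_window, c_true = c_true,
                 g_true = g_true),
            class = "calibration_targets")
}

# spatial variance, grouping coefficient, centroidal alignment at the end
# of a run (optionally averaged over the trailing eval_window seconds)
.target_metrics <- function(traj, eval_window = 0) {
  tt <- length(traj$times)
  frames <- if (eval_window > 0) {
    which(traj$times >= traj$times[tt] - eval_window)
  } else tt
  multi <- length(unique(traj$group_ids)) >= 2L
  acc <- matrix(NA_real_, length(frames), 3L)
  for (i in seq_along(frames)) {
    fr <- frames[i]
    pos <- traj$positions[, , fr, drop = TRUE]
    acc[i, ] <- c(spatial_variance(pos),
                  if (multi) grouping_coefficient(pos, traj$group_ids) else NA_real_,
                  centroidal_alignment(pos, traj$gazes[, fr]))
  }
  stats::setNames(colMeans(acc), c("spatial_variance", "rho", "chi"))
}
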