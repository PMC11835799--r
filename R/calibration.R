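#' Composite configuration error for a candidate (c, g)
#'
#' Simulates every calibration dataset from its stored initial
#' configuration with constriction `c` and gaze strength `g` (all other
#' parameters fixed), evaluates spatial variance, grouping coefficient
#' and centroidal alignment at the end of the run, and sums the absolute
#' differences from the dataset's targets; the total error is the sum
#' over datasets. Oscillatory measures are deliberately excluded.
#' Deterministic: the spontaneous frequencies live in each dataset's
#' initial state, so repeated evaluations at the same (c, g) agree
#' exactly.
#'
#' @param c_val Constriction candidate (>= 0).
#' @param g_val Gaze strength candidate (>= 0).
#' @param targets A `calibration_targets` object (see
#'   [generate_calibration_scenario()] and [read_targets()]).
#' @param params Base [swarm_params()]; `c` and `D` are overridden.
#' @return Non-negative scalar error, with attribute `per_dataset` (named
#'   vector). A diverging simulation contributes `Inf` (with a warning
#'   naming the dataset).
#' @export
composite_error <- function(c_val, g_val, targets,
                            params = swarm_params()) {
  if (c_val < 0 || g_val < 0) {
    stop("composite_error(): c and g must be >= 0", call. = FALSE)
  }
  pars <- params
  pars$c <- c_val
  pars$D <- g_val
  per <- vapply(targets$datasets, function(ds) {
    traj <- tryCatch(
      run_simulation(ds$initial_state, ds$schedule, pars,
                     duration = targets$duration, dt = targets$dt),
      error = function(e) {
        warning("composite_error(): dataset '", ds$id, "' failed at (c = ",
                format(c_val), ", g = ", format(g_val), "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(traj)) return(Inf)
    m <- .target_metrics(traj, targets$eval_window)
    sum(abs(m - ds$targets[names(m)]))
  }, numeric(1))
  names(per) <- vapply(targets$datasets, `[[`, character(1), "id")
  structure(sum(per), per_dataset = per)
}

#' Calibrate constriction and gaze strength by simulated annealing
#'
#' Minimizes [composite_error()] over `(c, g)` within box bounds
#' (default the unit square) using simulated annealing (`stats::optim`,
#' method `"SANN"`) with a Gaussian proposal clipped to the bounds.
#' Every evaluation is logged and the best point in the log is returned,
#' so the result can never be worse than the starting point.
#'
#' @param targets A `calibration_targets` object.
#' @param params Base [swarm_params()].
#' @param bounds Numeric `c(lo, hi)` applied to both parameters, or a
#'   2 x 2 matrix (rows = c, g; cols = lo, hi).
#' @param seed Integer seed controlling the annealing proposals.
#' @param budget Number of error evaluations spent by the annealer
#'   (>= 1).
#' @param init Optional starting point `c(c, g)`; defaults to the
#'   midpoint of the bounds.
#' @param temp Initial annealing temperature (scale of error increases
#'   accepted early on).
#' @param tmax Function evaluations per temperature level.
#' @param step_sd SD of the Gaussian proposal (parameter units).
#' @return An object of class `calibration_result`: list with `best`
#'   (named vector `c`, `g`), `best_error`, `per_dataset` (breakdown at
#'   the optimum), `log` (data.frame `c`, `g`, `error` in evaluation
#'   order), `seed`, `bounds`.
#' @export
calibrate <- function(targets, params = swarm_params(),
                      bounds = c(0, 1), seed = 1L, budget = 200L,
                      init = NULL, temp = 1, tmax = 5, step_sd = 0.1) {
  if (!length(targets$datasets)) {
    stop("calibrate(): no calibration datasets", call. = FALSE)
  }
  if (budget < 1L) stop("calibrate(): budget must be >= 1", call. = FALSE)
  if (is.matrix(bounds)) {
    lo <- bounds[, 1]
    hi <- bounds[, 2]
  } else {
    lo <- rep(bounds[1], 2)
    hi <- rep(bounds[2], 2)
  }
  if (is.null(init)) init <- (lo + hi) / 2
  log_c <- numeric(0)
  log_g <- numeric(0)
  log_e <- numeric(0)
  nev <- 0L
  fn <- function(par) {
    if (nev >= budget) return(Inf)  # budget exhausted: reject everything
    nev <<- nev + 1L
    err <- as.numeric(composite_error(par[1], par[2], targets, params))
    log_c[nev] <<- par[1]
    log_g[nev] <<- par[2]
    log_e[nev] <<- err
    err
  }
  gr <- function(par, ...) {
    pmin(pmax(par + stats::rnorm(2, 0, step_sd), lo), hi)
  }
  set.seed(seed)
  maxit <- max(budget - 1L, 1L)
  suppressWarnings(
    stats::optim(init, fn, gr, method = "SANN",
                 control = list(maxit = maxit, temp = temp, tmax = tmax))
  )
  log_df <- data.frame(c = log_c, g = log_g, error = log_e)
  if (nrow(log_df) > 1L && diff(range(log_df$error)) == 0) {
    warning("calibrate(): error surface is flat over all evaluated points; ",
            "returning the initial point")
    best_i <- 1L
  } else {
    best_i <- which.min(log_df$error)
  }
  best <- c(c = log_df$c[best_i], g = log_df$g[best_i])
  err <- composite_error(best[["c"]], best[["g"]], targets, params)
  structure(list(best = best, best_error = as.numeric(err),
                 per_dataset = attr(err, "per_dataset"), log = log_df,
                 seed = seed, bounds = cbind(lo = lo, hi = hi)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result: best c =", format(x$best[["c"]]),
      ", g =", format(x$best[["g"]]),
      ", error =", format(x$best_error),
      "(", nrow(x$log), "evaluations )\n")
  invisible(x)
}

#' Exhaustive error surface over a (c, g) grid
#'
#' Evaluates [composite_error()] on a regular grid, e.g. to map the
#' sensitivity of the fit to constriction versus gaze strength.
#'
#' @param targets A `calibration_targets` object.
#' @param params Base [swarm_params()].
#' @param grid Either a single integer (number of points per axis,
#'   >= 2, spanning `bounds`) or a list with numeric vectors `c` and `g`.
#' @param bounds Numeric `c(lo, hi)` used when `grid` is an integer.
#' @return A data.frame with columns `c`, `g`, `error` (one row per grid
#'   node, row-major in `g` then `c`).
#' @export
error_surface <- function(targets, params = swarm_params(), grid = 11L,
                          bounds = c(0, 1)) {
  if (is.numeric(grid) && length(grid) == 1L) {
    if (grid < 2) stop("error_surface(): grid resolution must be >= 2",
                       call. = FALSE)
    cs <- seq(bounds[1], bounds[2], length.out = grid)
    gs <- cs
  } else {
    cs <- grid$c
    gs <- grid$g
    if (length(cs) < 2L || length(gs) < 2L) {
      stop("error_surface(): need >= 2 points per axis", call. = FALSE)
    }
  }
  out <- expand.grid(c = cs, g = gs, KEEP.OUT.ATTRS = FALSE)
  out$error <- mapply(function(cv, gv)
    as.numeric(composite_error(cv, gv, targets, params)),
    out$c, out$g)
  out
}

#' Write / read calibration targets
#'
#' The on-disk form is a targets CSV (`dataset_id, spatial_variance, rho,
#' chi, states_path`) where `states_path` points to each dataset's
#' initial-state CSV (state schema, one frame; `phi_rad` gives the
#' stimulus phase at t = 0 and a sidecar of columns `stim_freq_hz`,
#' `stim_offset_rad` per agent reconstructs the schedule).
#'
#' @param targets A `calibration_targets` object.
#' @param path Output CSV path for the targets table.
#' @param states_dir Directory for the per-dataset initial-state CSVs
#'   (created if needed).
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path, states_dir = dirname(path)) {
  dir.create(states_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(targets$datasets, function(ds) {
    sp <- file.path(states_dir, paste0(ds$id, "_initial.csv"))
    st <- ds$initial_state
    idx <- match(st$group_ids, ds$schedule$group_ids)
    df <- data.frame(time_s = 0, agent_id = seq_len(st$n),
                     group_id = st$group_ids,
                     x = st$positions[, 1], y = st$positions[, 2],
                     theta_rad = st$phases, delta_rad = st$gazes,
                     omega_rad_s = st$omega, phi_rad = st$stimulus_phases,
                     stim_freq_hz = ds$schedule$freq_hz[idx],
                     stim_offset_rad = ds$schedule$offset[idx])
    utils::write.csv(df, sp, row.names = FALSE, quote = FALSE)
    data.frame(dataset_id = ds$id,
               spatial_variance = ds$targets[["spatial_variance"]],
               rho = ds$targets[["rho"]], chi = ds$targets[["chi"]],
               states_path = sp)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration=%.10g dt=%.10g eval_window=%.10g",
                     targets$duration, targets$dt, targets$eval_window), con)
  utils::write.csv(do.call(rbind, rows), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @param duration,dt,eval_window Simulation settings used when the
#'   targets file carries no settings row.
#' @return `read_targets()` returns a `calibration_targets` object.
#' @export
read_targets <- function(path, duration = 60, dt = 1 / 120,
                         eval_window = 0) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    grab <- function(key, default) {
      m <- regmatches(first, regexec(paste0(key, "=([0-9.eE+-]+)"), first))[[1]]
      if (length(m) == 2L) as.numeric(m[2]) else default
    }
    duration <- grab("duration", duration)
    dt <- grab("dt", dt)
    eval_window <- grab("eval_window", eval_window)
  }
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("dataset_id", "spatial_variance", "rho", "chi", "states_path")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("read_targets(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(tab)) stop("read_targets(): no datasets", call. = FALSE)
  datasets <- lapply(seq_len(nrow(tab)), function(i) {
    df <- utils::read.csv(tab$states_path[i], comment.char = "#")
    df <- df[order(df$agent_id), ]
    st <- swarm_state(positions = cbind(df$x, df$y), phases = df$theta_rad,
                      gazes = df$delta_rad, omega = df$omega_rad_s,
                      group_ids = df$group_id,
                      stimulus_phases = df$phi_rad)
    gidx <- !duplicated(df$group_id)
    sched <- stimulus_schedule(df$stim_freq_hz[gidx],
                               df$stim_offset_rad[gidx],
                               group_ids = df$group_id[gidx])
    list(id = tab$dataset_id[i], initial_state = st, schedule = sched,
         targets = c(spatial_variance = tab$spatial_variance[i],
                     rho = tab$rho[i], chi = tab$chi[i]))
  })
  structure(list(datasets = datasets, duration = duration, dt = dt,
                 eval_window = eval_window, c_true = NA_real_,
                 g_true = NA_real_),
            class = "calibration_targets")
}
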