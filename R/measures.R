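#' Circularity of a spatial configuration
#'
#' The population standard deviation of agent distances from the group
#' centroid. It is exactly 0 when the agents lie on a circle centred at
#' their centroid (the hallmark of circle formations in group dance), and
#' grows as the configuration departs from a circle.
#'
#' @param positions Numeric N x 2 matrix (N >= 2).
#' @return Non-negative scalar (length units).
#' @examples
#' ang <- 2 * pi * (0:11) / 12
#' circularity(cbind(cos(ang), sin(ang))) # 0
#' @export
circularity <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) {
    stop("circularity(): need at least 2 agents", call. = FALSE)
  }
  d <- .centroid_distances(positions)
  sqrt(mean((d - mean(d))^2))
}

.centroid_distances <- function(positions) {
  ctr <- colMeans(positions)
  sqrt((positions[, 1] - ctr[1])^2 + (positions[, 2] - ctr[2])^2)
}

#' Grouping coefficient (intracluster correlation of positions)
#'
#' Measures how strongly agents driven by the same stimulus cluster
#' together in space: the ratio of between-group to total positional
#' variance, `rho = sigma_b^2 / (sigma_b^2 + sigma_w^2)`, using the
#' multivariate (2-D) population variance decomposition. Clusters are the
#' stimulus groups. `rho = 0` when group centroids coincide; `rho = 1`
#' when every agent sits exactly on its group centroid.
#'
#' @param positions Numeric N x 2 matrix.
#' @param group_ids Vector of group labels (>= 2 distinct, each nonempty).
#' @return Scalar in `[0, 1]` (`NaN` only if all agents coincide).
#' @examples
#' pos <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
#' grouping_coefficient(pos, c(1, 1, 2, 2)) # 25/26
#' @export
grouping_coefficient <- function(positions, group_ids) {
  positions <- as.matrix(positions)
  groups <- unique(group_ids)
  if (length(groups) < 2L) {
    stop("grouping_coefficient(): need at least 2 stimulus groups",
         call. = FALSE)
  }
  n <- nrow(positions)
  ctr <- colMeans(positions)
  ssw <- 0
  ssb <- 0
  for (g in groups) {
    sel <- group_ids == g
    if (!any(sel)) stop("grouping_coefficient(): empty group", call. = FALSE)
    sub <- positions[sel, , drop = FALSE]
    cg <- colMeans(sub)
    ssw <- ssw + sum((sub[, 1] - cg[1])^2 + (sub[, 2] - cg[2])^2)
    ssb <- ssb + sum(sel) * sum((cg - ctr)^2)
  }
  sw2 <- ssw / n
  sb2 <- ssb / n
  sb2 / (sb2 + sw2)
}

#' Gaze locking coefficient
#'
#' The mean, over all ordered pairs, of the cosine of the angle between
#' agent j's gaze and the direction from j to k:
#' `gamma = 1/(N(N-1)) * sum_{k != j} cos(alpha_kj - delta_j)`. It is 1
#' when every agent faces every other agent (only attainable pairwise)
#' and -1 when all face away.
#'
#' @param positions Numeric N x 2 matrix (N >= 2).
#' @param gazes Numeric vector of N gaze azimuths (rad).
#' @return Scalar in `[-1, 1]`.
#' @export
gaze_locking <- function(positions, gazes) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("gaze_locking(): need at least 2 agents", call. = FALSE)
  geom <- pairwise_geometry(positions)
  cosmat <- cos(geom$azimuth - gazes)
  diag(cosmat) <- 0
  sum(cosmat) / (n * (n - 1))
}

#' Centroidal alignment
#'
#' The mean cosine of the angle between each agent's gaze and the
#' direction from the agent to the group centroid:
#' `chi = 1/N * sum_j cos(eps_j - delta_j)`. It is 1 when all agents face
#' the centroid (as in a closed dance circle) and -1 when all face away.
#' Agents lying exactly on the centroid have no defined direction and are
#' skipped with a warning.
#'
#' @inheritParams gaze_locking
#' @return Scalar in `[-1, 1]`.
#' @export
centroidal_alignment <- function(positions, gazes) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("centroidal_alignment(): need at least 2 agents",
                   call. = FALSE)
  ctr <- colMeans(positions)
  dx <- ctr[1] - positions[, 1]
  dy <- ctr[2] - positions[, 2]
  at_ctr <- dx == 0 & dy == 0
  if (all(at_ctr)) {
    stop("centroidal_alignment(): all agents at the centroid", call. = FALSE)
  }
  if (any(at_ctr)) {
    warning("centroidal_alignment(): skipping ", sum(at_ctr),
            " agent(s) exactly at the centroid")
  }
  epsang <- atan2(dy[!at_ctr], dx[!at_ctr])
  mean(cos(epsang - gazes[!at_ctr]))
}

#' Global phase coherence (Kuramoto order parameter norm)
#'
#' `R = |sum_j exp(i * theta_j)| / N`: 1 for perfectly phase-locked
#' agents, near 0 for incoherent or balanced antiphase configurations.
#'
#' @param phases Numeric vector of phases (rad).
#' @return Scalar in `[0, 1]`.
#' @export
phase_coherence <- function(phases) {
  Mod(mean(exp(1i * phases)))
}

#' Local phase coherence with a Gaussian spatial kernel
#'
#' Per-agent coherence weighted by spatial proximity,
#' `R_j = |sum_k K_jk exp(i theta_k)| / sum_k K_jk` with
#' `K_jk = exp(-|x_j - x_k|^2 / (2 sigma^2))` (the sum includes k = j,
#' whose weight is 1), averaged over agents. Small `sigma` probes local
#' pockets of synchrony; as `sigma` grows the measure converges to the
#' global [phase_coherence()].
#'
#' @param positions Numeric N x 2 matrix.
#' @param phases Numeric vector of N phases (rad).
#' @param sigma Kernel width (length units), > 0.
#' @return Scalar in `[0, 1]`.
#' @export
local_phase_coherence <- function(positions, phases, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("local_phase_coherence(): 'sigma' must be > 0", call. = FALSE)
  }
  positions <- as.matrix(positions)
  n <- nrow(positions)
  dxx <- matrix(positions[, 1], n, n, byrow = TRUE) - positions[, 1]
  dyy <- matrix(positions[, 2], n, n, byrow = TRUE) - positions[, 2]
  K <- exp(-(dxx * dxx + dyy * dyy) / (2 * sigma^2))
  z <- K %*% exp(1i * phases)
  mean(Mod(z) / rowSums(K))
}

#' Spatial variance of positions (group size)
#'
#' The mean squared distance of agents from the global centroid — the
#' trace of the population positional covariance. Used as the "group
#' size" component of the calibration error.
#'
#' @param positions Numeric N x 2 matrix (N >= 2).
#' @return Non-negative scalar (length units squared).
#' @export
spatial_variance <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) {
    stop("spatial_variance(): need at least 2 agents", call. = FALSE)
  }
  mean(.centroid_distances(positions)^2)
}

#' All self-organization measures for one configuration
#'
#' @param state A [swarm_state()] (or a list with `positions`, `phases`,
#'   `gazes`, `group_ids`).
#' @param sigma Kernel width for [local_phase_coherence()].
#' @return A one-row data.frame with columns `kappa`, `rho`, `gamma`,
#'   `chi`, `R`, `R_sigma`, `spatial_variance` (`rho` is `NA` when only
#'   one stimulus group is present).
#' @export
measure_frame <- function(state, sigma = 1) {
  pos <- state$positions
  rho <- if (length(unique(state$group_ids)) >= 2L) {
    grouping_coefficient(pos, state$group_ids)
  } else NA_real_
  data.frame(
    kappa = circularity(pos),
    rho = rho,
    gamma = gaze_locking(pos, state$gazes),
    chi = centroidal_alignment(pos, state$gazes),
    R = phase_coherence(state$phases),
    R_sigma = local_phase_coherence(pos, state$phases, sigma),
    spatial_variance = spatial_variance(pos)
  )
}

#' Measure time series for a trajectory
#'
#' Evaluates every self-organization measure on each stored frame
#' (optionally downsampled), globally and — when more than one stimulus
#' group is present — within each group (the grouping coefficient is
#' global by construction; per-group columns are suffixed `_g<id>`).
#'
#' @param trajectory A `swarm_trajectory` from [run_simulation()] or
#'   [read_states()].
#' @param sigma Kernel width for the local phase coherence.
#' @param every Keep every `every`-th frame (1 = all frames).
#' @param per_group Also compute per-group measures?
#' @return A data.frame with one row per evaluated frame: `time_s`,
#'   `kappa`, `rho`, `gamma`, `chi`, `R`, `R_sigma`, `spatial_variance`,
#'   plus per-group variants of `kappa`, `gamma`, `chi`, `R`, `R_sigma`,
#'   `spatial_variance`.
#' @export
measure_series <- function(trajectory, sigma = 1, every = 1L,
                           per_group = TRUE) {
  frames <- seq(1L, length(trajectory$times), by = as.integer(every))
  grp <- trajectory$group_ids
  groups <- sort(unique(grp))
  multi <- length(groups) >= 2L
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[i]
    pos <- trajectory$positions[, , fr, drop = TRUE]
    th <- trajectory$phases[, fr]
    de <- trajectory$gazes[, fr]
    row <- data.frame(
      time_s = trajectory$times[fr],
      kappa = circularity(pos),
      rho = if (multi) grouping_coefficient(pos, grp) else NA_real_,
      gamma = gaze_locking(pos, de),
      chi = centroidal_alignment(pos, de),
      R = phase_coherence(th),
      R_sigma = local_phase_coherence(pos, th, sigma),
      spatial_variance = spatial_variance(pos)
    )
    if (per_group && multi) {
      for (g in groups) {
        sel <- grp == g
        if (sum(sel) >= 2L) {
          pg <- pos[sel, , drop = FALSE]
          row[[paste0("kappa_g", g)]] <- circularity(pg)
          row[[paste0("gamma_g", g)]] <- gaze_locking(pg, de[sel])
          row[[paste0("chi_g", g)]] <- centroidal_alignment(pg, de[sel])
          row[[paste0("R_g", g)]] <- phase_coherence(th[sel])
          row[[paste0("R_sigma_g", g)]] <- local_phase_coherence(pg, th[sel], sigma)
          row[[paste0("spatial_variance_g", g)]] <- spatial_variance(pg)
        }
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
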