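# Naive scalar double-loop reference implementation of the right-hand
# sides, written directly from the model definitions and independent of
# the package's vectorized code paths. Used as the oracle in the
# equivalence tests.

ref_gaze_kernel <- function(th, cc) {
  z <- integrate(function(u) ((1 + cos(u)) / 2)^cc, -pi, pi,
                 rel.tol = 1e-12)$value
  ((1 + cos(th)) / 2)^cc / z
}

ref_gaze_kernel_deriv <- function(th, cc) {
  if (cc == 0) return(0)
  b <- (1 + cos(th)) / 2
  if (b == 0) return(0)
  (cc * sin(th) / 2) * b^(cc - 1)
}

ref_derivatives <- function(state, params) {
  n <- state$n
  x <- state$positions
  th <- state$phases
  de <- state$gazes
  vel <- matrix(0, n, 2)
  drate <- numeric(n)
  trate <- numeric(n)
  for (j in seq_len(n)) {
    nx <- sqrt(sum(x[j, ]^2))
    scale <- if (params$a == 1) params$A else
      params$A * max(nx, params$eps)^(params$a - 1)
    vj <- -x[j, ] * scale
    dj <- 0
    visj <- 0
    for (k in seq_len(n)) {
      if (k == j) next
      dvec <- x[k, ] - x[j, ]
      dist <- max(sqrt(sum(dvec^2)), params$eps)
      w <- 1 / dist
      u <- dvec / dist
      alpha <- atan2(dvec[2], dvec[1])
      Om <- (1 + cos(th[k] - th[j])) / 2
      Ups <- ref_gaze_kernel(alpha - de[j], params$c)
      vj <- vj - (params$R / n) * w^params$r * u
      vj <- vj + (params$P / n) * w^params$p * Om * Ups * u
      dj <- dj + (params$D / n) * w^params$d *
        ref_gaze_kernel_deriv(alpha - de[j], params$c) * Om
      visj <- visj + (params$V / n) * w^params$v * Ups * sin(th[k] - th[j])
    }
    vel[j, ] <- vj
    drate[j] <- dj
    trate[j] <- state$omega[j] +
      params$U * sin(state$stimulus_phases[j] - th[j]) + visj
  }
  list(velocity = vel, gaze_rate = drate, phase_rate = trate)
}

# random swarm state for property tests
random_state <- function(n = 6L, ngroups = 2L, spread = 2) {
  swarm_state(positions = matrix(stats::rnorm(2 * n, sd = spread), n, 2),
              phases = stats::runif(n, -pi, pi),
              gazes = stats::runif(n, -pi, pi),
              omega = stats::rnorm(n, 4 * pi, 0.3),
              group_ids = rep_len(seq_len(ngroups), n),
              stimulus_phases = stats::runif(n, -pi, pi))
}

# rotate a state (positions and gazes) by beta about the origin
rotate_state <- function(state, beta) {
  Rm <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
  swarm_state(positions = state$positions %*% t(Rm),
              phases = state$phases,
              gazes = wrap_angle(state$gazes + beta),
              omega = state$omega,
              group_ids = state$group_ids,
              stimulus_phases = state$stimulus_phases)
}
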