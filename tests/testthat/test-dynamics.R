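pars0 <- swarm_params()

test_that("attraction velocity pulls toward the origin with the stated law", {
  st <- swarm_state(rbind(c(1, 0)), 0, 0, 0)
  expect_equal(attraction_velocity(st, pars0), rbind(c(-0.1, 0)))
  st0 <- swarm_state(rbind(c(0, 0)), 0, 0, 0)
  expect_equal(attraction_velocity(st0, pars0), rbind(c(0, 0)))
  st2 <- swarm_state(rbind(c(0, 2)), 0, 0, 0)
  expect_equal(attraction_velocity(st2, swarm_params(a = 2)),
               rbind(c(0, -0.4)))
  # sublinear exponent at the origin stays finite thanks to the guard
  expect_true(all(is.finite(attraction_velocity(st0, swarm_params(a = 0.5)))))
})

test_that("repulsion velocity pushes agents apart with proximity^r weighting", {
  st <- swarm_state(rbind(c(0, 0), c(1, 0)), c(0, 0), c(0, 0), c(0, 0))
  geo <- pairwise_geometry(st$positions)
  expect_equal(repulsion_velocity(st, geo, pars0)[1, ], c(-0.75, 0))
  expect_equal(repulsion_velocity(st, geo, pars0)[2, ], c(0.75, 0))
  st2 <- swarm_state(rbind(c(0, 0), c(2, 0)), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(repulsion_velocity(st2, pairwise_geometry(st2$positions),
                                  pars0)[1, ],
               c(-0.1875, 0))
  single <- swarm_state(rbind(c(3, 3)), 0, 0, 0)
  expect_equal(repulsion_velocity(single, pairwise_geometry(single$positions),
                                  pars0),
               matrix(0, 1, 2))
})

test_that("phase-gaze attraction needs phase similarity and visual contact", {
  # gaze of agent 1 aimed at agent 2, same phase, omnidirectional field
  st <- swarm_state(rbind(c(0, 0), c(1, 0)), c(0, 0), c(0, 0), c(0, 0))
  geo <- pairwise_geometry(st$positions)
  v <- phase_gaze_velocity(st, geo, swarm_params(c = 0))
  expect_equal(v[1, ], c(0.25 / (2 * pi), 0), tolerance = 1e-12)
  # antiphase pair: no attraction
  st_anti <- swarm_state(rbind(c(0, 0), c(1, 0)), c(0, pi), c(0, 0), c(0, 0))
  expect_equal(phase_gaze_velocity(st_anti, geo, swarm_params(c = 0)),
               matrix(0, 2, 2))
  # target dead behind with constricted field: no attraction for agent 1
  st_behind <- swarm_state(rbind(c(0, 0), c(1, 0)), c(0, 0), c(pi, 0),
                           c(0, 0))
  v2 <- phase_gaze_velocity(st_behind, geo, swarm_params(c = 2))
  expect_equal(v2[1, ], c(0, 0))
})

test_that("total velocity is the exact sum of its three components", {
  set.seed(3)
  for (i in 1:5) {
    st <- random_state(n = 5L)
    geo <- pairwise_geometry(st$positions, pars0$eps)
    expect_identical(total_velocity(st, geo, pars0),
                     attraction_velocity(st, pars0) +
                       repulsion_velocity(st, geo, pars0) +
                       phase_gaze_velocity(st, geo, pars0))
  }
  zero <- swarm_params(A = 0, R = 0, P = 0, D = 0, U = 0, V = 0)
  st <- random_state(n = 4L)
  geo <- pairwise_geometry(st$positions, zero$eps)
  expect_equal(total_velocity(st, geo, zero), matrix(0, 4, 2))
})

test_that("gaze rate rotates toward visible in-phase targets", {
  p1 <- swarm_params(c = 1, D = 0.25)
  # target at alpha - delta = pi/2, same phase, distance 1
  st <- swarm_state(rbind(c(0, 0), c(0, 1)), c(0, 0), c(0, 0), c(0, 0))
  geo <- pairwise_geometry(st$positions)
  expect_equal(gaze_rate(st, geo, p1)[1], 0.0625)
  # dead ahead: no torque
  st_ahead <- swarm_state(rbind(c(0, 0), c(1, 0)), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(gaze_rate(st_ahead, pairwise_geometry(st_ahead$positions),
                         p1)[1], 0)
  # antiphase target: no torque
  st_anti <- swarm_state(rbind(c(0, 0), c(0, 1)), c(0, pi), c(0, 0), c(0, 0))
  expect_equal(gaze_rate(st_anti, pairwise_geometry(st_anti$positions),
                         p1)[1], 0)
})

test_that("auditory and visual phase rates follow the coupling laws", {
  st <- swarm_state(rbind(c(0, 0)), phases = 0, gazes = 0, omega = 0,
                    stimulus_phases = pi / 2)
  expect_equal(auditory_phase_rate(st, pars0), 0.8)
  st$stimulus_phases <- -pi / 2
  expect_equal(auditory_phase_rate(st, pars0), -0.8)
  st$stimulus_phases <- 0
  expect_equal(auditory_phase_rate(st, pars0), 0)

  # gaze on partner, quarter-phase lead, omnidirectional field
  stv <- swarm_state(rbind(c(0, 0), c(1, 0)), c(0, pi / 2), c(0, 0), c(0, 0))
  geo <- pairwise_geometry(stv$positions)
  expect_equal(visual_phase_rate(stv, geo, swarm_params(c = 0))[1],
               0.2 / (2 * pi), tolerance = 1e-12)
  same <- swarm_state(rbind(c(0, 0), c(1, 0)), c(1, 1), c(0, 0), c(0, 0))
  expect_equal(visual_phase_rate(same, geo, swarm_params(c = 0)),
               c(0, 0))
})

test_that("total phase rate sums spontaneous, auditory and visual terms exactly", {
  set.seed(9)
  st <- random_state(n = 6L)
  geo <- pairwise_geometry(st$positions, pars0$eps)
  expect_identical(total_phase_rate(st, geo, pars0),
                   st$omega + auditory_phase_rate(st, pars0) +
                     visual_phase_rate(st, geo, pars0))
  quiet <- swarm_params(U = 0, V = 0)
  expect_equal(total_phase_rate(st, geo, quiet), st$omega)
})

test_that("vectorized right-hand sides match the naive double-loop reference", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    st <- random_state(n = n)
    pp <- swarm_params(c = runif(1, 0, 2), D = runif(1, 0, 0.5))
    dv <- swarm_derivatives(st, pp)
    ref <- ref_derivatives(st, pp)
    expect_equal(dv$velocity, ref$velocity, tolerance = 1e-12)
    expect_equal(dv$gaze_rate, ref$gaze_rate, tolerance = 1e-12)
    expect_equal(dv$phase_rate, ref$phase_rate, tolerance = 1e-12)
    expect_equal(dv$velocity,
                 dv$components$velocity_attraction +
                   dv$components$velocity_repulsion +
                   dv$components$velocity_phase_gaze)
  }
})

test_that("dynamics are equivariant under rotation, translation and permutation", {
  set.seed(11)
  beta <- 0.8
  Rm <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
  for (i in 1:5) {
    st <- random_state(n = 6L)
    dv <- swarm_derivatives(st, pars0)
    # rotation: velocities rotate, scalar rates invariant
    dvr <- swarm_derivatives(rotate_state(st, beta), pars0)
    expect_equal(dvr$velocity, dv$velocity %*% t(Rm), tolerance = 1e-10)
    expect_equal(dvr$gaze_rate, dv$gaze_rate, tolerance = 1e-10)
    expect_equal(dvr$phase_rate, dv$phase_rate, tolerance = 1e-10)
    # translation: only the origin-attraction term changes
    sht <- swarm_state(st$positions + rep(c(2, -1), each = st$n),
                       st$phases, st$gazes, st$omega, st$group_ids,
                       st$stimulus_phases)
    dvt <- swarm_derivatives(sht, pars0)
    expect_equal(dvt$components$velocity_repulsion,
                 dv$components$velocity_repulsion, tolerance = 1e-10)
    expect_equal(dvt$components$velocity_phase_gaze,
                 dv$components$velocity_phase_gaze, tolerance = 1e-10)
    expect_equal(dvt$gaze_rate, dv$gaze_rate, tolerance = 1e-10)
    expect_equal(dvt$phase_rate, dv$phase_rate, tolerance = 1e-10)
    # permutation
    perm <- sample(st$n)
    stp <- swarm_state(st$positions[perm, ], st$phases[perm],
                       st$gazes[perm], st$omega[perm], st$group_ids[perm],
                       st$stimulus_phases[perm])
    dvp <- swarm_derivatives(stp, pars0)
    expect_equal(dvp$velocity, dv$velocity[perm, ], tolerance = 1e-12)
    expect_equal(dvp$gaze_rate, dv$gaze_rate[perm], tolerance = 1e-12)
    expect_equal(dvp$phase_rate, dv$phase_rate[perm], tolerance = 1e-12)
  }
})

test_that("with only linear attraction, positions decay exponentially at rate A", {
  p <- swarm_params(P = 0, D = 0, V = 0, U = 0, R = 0, a = 1)
  st <- swarm_state(rbind(c(2, 0), c(0, -1)), c(0, 0), c(0, 0), c(0, 0))
  tr <- run_simulation(st, stimulus_schedule(2), p, duration = 5, dt = 1e-3)
  expected <- st$positions * exp(-p$A * 5)
  expect_equal(tr$positions[, , length(tr$times)], expected,
               tolerance = 1e-3)
})
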