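test_that("circularity is zero on circles and matches a hand computation", {
  ang <- 2 * pi * (0:11) / 12
  expect_equal(circularity(cbind(cos(ang), sin(ang))), 0,
               tolerance = 1e-12)
  square <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(circularity(square), 0, tolerance = 1e-12)
  # centroid (2, 0); distances {2, 1, 3}; population SD = sqrt(2/3)
  expect_equal(circularity(rbind(c(0, 0), c(1, 0), c(5, 0))), sqrt(2 / 3))
  expect_error(circularity(rbind(c(0, 0))), "at least 2")
})

test_that("grouping coefficient is the multivariate intracluster correlation", {
  pos <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  expect_equal(grouping_coefficient(pos, c(1, 1, 2, 2)), 25 / 26)
  # coincident group centroids, spread members: 0
  sym <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  expect_equal(grouping_coefficient(sym, c(1, 1, 2, 2)), 0)
  # members on their centroids, centroids apart: 1
  tight <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(grouping_coefficient(tight, c(1, 1, 2, 2)), 1)
  expect_error(grouping_coefficient(pos, rep(1, 4)), "2 stimulus groups")
})

test_that("gaze locking distinguishes facing-each-other from back-to-back", {
  pos <- rbind(c(0, 0), c(1, 0))
  expect_equal(gaze_locking(pos, c(0, pi)), 1)    # facing each other
  expect_equal(gaze_locking(pos, c(pi, 0)), -1)   # back to back
  expect_equal(gaze_locking(pos, c(0, 0)), 0)     # one toward, one away
})

test_that("centroidal alignment measures facing toward the centroid", {
  ang <- 2 * pi * (0:5) / 6
  pos <- cbind(cos(ang), sin(ang))
  inward <- wrap_angle(ang + pi)
  expect_equal(centroidal_alignment(pos, inward), 1)
  expect_equal(centroidal_alignment(pos, ang), -1)
  expect_equal(centroidal_alignment(pos, wrap_angle(ang + pi / 2)), 0,
               tolerance = 1e-12)
  # an agent exactly at the centroid is skipped with a warning
  pos2 <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  expect_warning(val <- centroidal_alignment(pos2, c(0, pi, 0)),
                 "centroid")
  expect_equal(val, 1)
})

test_that("phase coherence is the Kuramoto order parameter norm", {
  expect_equal(phase_coherence(rep(1.3, 8)), 1)
  expect_equal(phase_coherence(c(0, pi)), 0)
  expect_equal(phase_coherence(c(0, pi / 2)), sqrt(2) / 2)
})

test_that("local phase coherence interpolates between self-term and global coherence", {
  set.seed(21)
  pos <- matrix(rnorm(24, sd = 2), 12, 2)
  th <- runif(12, -pi, pi)
  expect_equal(local_phase_coherence(pos, th, 1e6), phase_coherence(th),
               tolerance = 1e-6)
  expect_equal(local_phase_coherence(pos, th, 1e-6), 1, tolerance = 1e-12)
  # two separated internally synchronized antiphase clusters
  clus <- rbind(matrix(rnorm(10, sd = .05), 5, 2),
                matrix(rnorm(10, sd = .05) + 100, 5, 2))
  phases <- c(rep(0, 5), rep(pi, 5))
  expect_lt(phase_coherence(phases), 1e-12)
  expect_gt(local_phase_coherence(clus, phases, 0.5), 0.99)
  # monotone convergence toward R along a sigma ladder
  sig <- c(0.5, 1, 2, 5, 20, 100, 1e4)
  gap <- vapply(sig, function(s)
    abs(local_phase_coherence(pos, th, s) - phase_coherence(th)), numeric(1))
  expect_true(all(diff(gap) <= 1e-12))
  expect_error(local_phase_coherence(pos, th, 0), "> 0")
})

test_that("spatial variance is the mean squared centroid distance with quadratic scaling", {
  ang <- 2 * pi * (0:7) / 8
  circle <- cbind(cos(ang), sin(ang))
  expect_equal(spatial_variance(circle), 1)
  expect_equal(spatial_variance(2 * circle), 4)
  expect_equal(spatial_variance(rbind(c(3, 3), c(3, 3))), 0)
})

test_that("measures respect their ranges on random configurations", {
  set.seed(31)
  for (i in 1:500) {
    n <- sample(3:15, 1)
    pos <- matrix(rnorm(2 * n, sd = runif(1, 0.1, 10)), n, 2)
    th <- runif(n, -pi, pi)
    de <- runif(n, -pi, pi)
    grp <- rep_len(1:2, n)
    rho <- grouping_coefficient(pos, grp)
    expect_true(rho >= 0 && rho <= 1)
    g <- gaze_locking(pos, de)
    expect_true(g >= -1 && g <= 1)
    ch <- centroidal_alignment(pos, de)
    expect_true(ch >= -1 && ch <= 1)
    R <- phase_coherence(th)
    expect_true(R >= 0 && R <= 1)
    Rs <- local_phase_coherence(pos, th, runif(1, 0.1, 10))
    expect_true(Rs >= 0 && Rs <= 1)
    expect_gte(circularity(pos), 0)
  }
})

test_that("measures are invariant under global translation, rotation and phase shift", {
  set.seed(41)
  beta <- 1.1
  Rm <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
  for (i in 1:10) {
    n <- 9
    pos <- matrix(rnorm(2 * n, sd = 2), n, 2)
    th <- runif(n, -pi, pi)
    de <- runif(n, -pi, pi)
    grp <- rep_len(1:3, n)
    pos2 <- pos %*% t(Rm) + rep(c(5, -2), each = n)
    de2 <- wrap_angle(de + beta)
    expect_equal(circularity(pos2), circularity(pos), tolerance = 1e-10)
    expect_equal(grouping_coefficient(pos2, grp),
                 grouping_coefficient(pos, grp), tolerance = 1e-10)
    expect_equal(gaze_locking(pos2, de2), gaze_locking(pos, de),
                 tolerance = 1e-10)
    expect_equal(centroidal_alignment(pos2, de2),
                 centroidal_alignment(pos, de), tolerance = 1e-10)
    expect_equal(spatial_variance(pos2), spatial_variance(pos),
                 tolerance = 1e-10)
    shift <- runif(1, -pi, pi)
    expect_equal(phase_coherence(th + shift), phase_coherence(th),
                 tolerance = 1e-12)
    expect_equal(local_phase_coherence(pos2, th + shift, 1.5),
                 local_phase_coherence(pos, th, 1.5), tolerance = 1e-10)
  }
})

test_that("measure series agrees with single-frame calls and respects downsampling", {
  spec <- scenario_spec(n_agents = 6L, condition = "phase_180")
  p <- swarm_params()
  st <- generate_initial_config(spec, p, seed = 6L)
  tr <- run_simulation(st, scenario_schedule(spec), p, duration = 1,
                       dt = 1 / 120)
  ms <- measure_series(tr, sigma = 1)
  expect_equal(nrow(ms), length(tr$times))
  ms2 <- measure_series(tr, sigma = 1, every = 12L)
  expect_equal(nrow(ms2), ceiling(length(tr$times) / 12))
  # frame 1 equals direct calls
  f1 <- measure_frame(trajectory_frame(tr, 1), sigma = 1)
  expect_equal(ms$kappa[1], f1$kappa)
  expect_equal(ms$rho[1], f1$rho)
  expect_equal(ms$gamma[1], f1$gamma)
  expect_equal(ms$chi[1], f1$chi)
  expect_equal(ms$R[1], f1$R)
  expect_equal(ms$R_sigma[1], f1$R_sigma)
  expect_equal(ms$spatial_variance[1], f1$spatial_variance)
  # per-group columns present for both groups
  expect_true(all(c("kappa_g1", "R_g2", "spatial_variance_g1") %in% names(ms)))
  # a constant trajectory yields a constant series
  tr_const <- tr
  for (fr in seq_along(tr$times)) {
    tr_const$positions[, , fr] <- tr$positions[, , 1]
    tr_const$phases[, fr] <- tr$phases[, 1]
    tr_const$gazes[, fr] <- tr$gazes[, 1]
  }
  msc <- measure_series(tr_const, sigma = 1, every = 30L)
  expect_equal(var(msc$kappa), 0)
  expect_equal(var(msc$R), 0)
})
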