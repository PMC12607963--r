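test_that("zero guiding reduces SGLD to LD and SGMD to MD exactly", {
  sys <- sdw_system()
  runs <- lapply(c("LD", "SGLD"), function(mode) {
    cfg <- sg_config(n_steps = 1e4,
                     guiding = guiding_params(mode, gamma = 10), seed = 7,
                     record_every = 50, record_positions = TRUE)
    run_simulation(sys, cfg)
  })
  expect_lt(max(abs(runs[[1]]$pos_traj - runs[[2]]$pos_traj)), 1e-12)
  expect_equal(runs[[1]]$frames$E_p, runs[[2]]$frames$E_p)

  hs <- harmonic_system(2, mass = 20)
  runs_md <- lapply(c("MD", "SGMD"), function(mode) {
    cfg <- sg_config(n_steps = 1e4, guiding = guiding_params(mode), seed = 7,
                     record_every = 50, record_positions = TRUE)
    run_simulation(hs, cfg, positions = matrix(c(0.4, 0, 0), 1))
  })
  expect_lt(max(abs(runs_md[[1]]$pos_traj - runs_md[[2]]$pos_traj)), 1e-12)
})

test_that("SGLD-GLE at lambda = 0 is plain LD under a shared seed", {
  sys <- harmonic_system(1, mass = 39.948)
  get <- function(mode) {
    cfg <- sg_config(n_steps = 5000,
                     guiding = guiding_params(mode, gamma = 10), seed = 3,
                     record_every = 10, record_positions = TRUE)
    run_simulation(sys, cfg)$pos_traj
  }
  expect_lt(max(abs(get("LD") - get("SGLD-GLE"))), 1e-12)
})

test_that("plain MD leap-frog conserves the harmonic energy", {
  k <- 1; m <- 10
  omega <- sqrt(k * sg_constants()$f_conv / m)
  period <- 2 * pi / omega
  cfg <- sg_config(n_steps = 1e5, dt = 0.001 * period, temperature = 300,
                   guiding = guiding_params("MD", t_L = 0.2), seed = 1,
                   record_every = 100)
  run <- run_simulation(harmonic_system(k, mass = m), cfg,
                        positions = matrix(c(1, 0, 0), 1),
                        velocities = matrix(0, 1, 3))
  fr <- run$frames
  drift <- unname(coef(lm(fr$E_tot ~ fr$t))[2]) * max(fr$t)
  expect_lt(abs(drift) / fr$E_tot[1], 1e-5)
})

test_that("leap-frog staggering: velocities advance before positions", {
  # free particle (vanishing spring), one hand-computed step
  sys <- harmonic_system(1e-12, mass = 2)
  cfg <- sg_config(n_steps = 1, dt = 0.001, guiding = guiding_params("MD"),
                   record_every = 1, record_positions = TRUE,
                   record_velocities = TRUE)
  r0 <- matrix(c(1, 2, 3), 1); v0 <- matrix(c(10, -20, 5), 1)
  run <- sg_leapfrog_step(sys, cfg, r0, v0)
  expect_equal(run$velocities, v0, tolerance = 1e-9)
  expect_equal(run$positions, r0 + v0 * 0.001, tolerance = 1e-9)
})

test_that("langevin random forces have the stated variance and determinism", {
  expect_equal(langevin_random_force(0, 39.948, 300, 0.001),
               matrix(0, 1, 3))
  set.seed(9)
  R <- langevin_random_force(10, 39.948, 300, 0.001, n_atoms = 4e5)
  v_target <- 2 * 10 * 39.948 * sg_constants()$kB *
    sg_constants()$f_conv * 300 / 0.001
  expect_lt(abs(stats::var(c(R)) - v_target) / v_target, 0.01)
  set.seed(33); a <- langevin_random_force(5, 1, 100, 0.001, n_atoms = 10)
  set.seed(33); b <- langevin_random_force(5, 1, 100, 0.001, n_atoms = 10)
  expect_identical(a, b)
})

test_that("LD samples the harmonic canonical distribution", {
  kT <- sg_constants()$kB * 300
  cfg <- sg_config(n_steps = 3e5, temperature = 300,
                   guiding = guiding_params("LD", gamma = 10), seed = 14,
                   record_every = 10, record_positions = TRUE)
  run <- run_simulation(harmonic_system(2, mass = 20), cfg)
  sel <- run$frames$t >= 5
  x2 <- rowMeans(run$pos_traj[sel, 1, ]^2)
  expect_lt(abs(mean(x2) - kT / 2), 3 * block_se(x2))
  Tk <- run$frames$T_kin[sel]
  expect_lt(abs(mean(Tk) - 300), 3 * block_se(Tk))
})

test_that("runs are deterministic and n_steps = 0 yields the initial frame", {
  sys <- sdw_system()
  cfg <- sg_config(n_steps = 2000,
                   guiding = guiding_params("SGLD", lambda = 0.5, gamma = 10),
                   seed = 12, record_every = 10, record_positions = TRUE)
  r1 <- run_simulation(sys, cfg); r2 <- run_simulation(sys, cfg)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$pos_traj, r2$pos_traj)

  cfg0 <- sg_config(n_steps = 0, guiding = guiding_params("LD", gamma = 10),
                    seed = 1)
  r0 <- run_simulation(sys, cfg0)
  expect_equal(nrow(r0$frames), 1)
  expect_equal(r0$frames$t, 0)
})

test_that("continuation via the returned state matches one long run", {
  sys <- sdw_system()
  g <- guiding_params("SGLD", lambda = 1, gamma = 10)
  cfg <- sg_config(n_steps = 4000, guiding = g, seed = 6, record_every = 100)
  long <- run_simulation(sys, cfg)
  cfg1 <- sg_config(n_steps = 2000, guiding = g, seed = 6, record_every = 100)
  part1 <- run_simulation(sys, cfg1)
  cfg2 <- sg_config(n_steps = 2000, guiding = g, record_every = 100)
  part2 <- run_simulation(sys, cfg2, part1$positions, part1$velocities,
                          state = part1$state)
  expect_equal(part2$frames$E_p[-1],
               long$frames$E_p[long$frames$t > 2], tolerance = 1e-12)
})

test_that("eta keeps SGMD energy-conserving against disabled scaling", {
  ar <- argon_fixture(64)
  drift <- function(eta_on) {
    cfg <- sg_config(n_steps = 1e4, temperature = 100,
                     guiding = guiding_params("SGMD", lambda = 1),
                     record_every = 50, eta = eta_on)
    fr <- run_simulation(ar$system, cfg, ar$positions, ar$velocities)$frames
    abs(unname(coef(lm(fr$E_tot ~ fr$t))[2]))
  }
  expect_gt(drift(FALSE) / drift(TRUE), 10)
})

test_that("invalid configurations are rejected", {
  expect_error(guiding_params("SGMD", gamma = 5), "exactly 0")
  expect_error(guiding_params("LD", gamma = 0), "positive")
  expect_error(guiding_params("SGLD-GLE", lambda = 1.2, gamma = 10),
               "lambda <= 1")
  expect_error(guiding_params("SGLD-GLE", mu = 0.1, gamma = 10), "mu must be 0")
  expect_error(guiding_params("LD", lambda = 0.5, gamma = 10), "must be 0")
  expect_error(sg_config(100, dt = 0.3, guiding = guiding_params("LD")),
               "t_L")
  expect_error(run_simulation(lj_system(8, 25), sg_config(10)),
               "initial positions")
})
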