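test_that("local average recursion follows the exponential filter", {
  expect_equal(local_average_update(0, 1, 0.001, 0.2), 0.005)
  # constant signal is a fixed point
  avg <- 3.7
  for (i in 1:100) avg <- local_average_update(avg, 3.7, 0.01, 0.2)
  expect_equal(avg, 3.7)
  # boundary weight 1 at dt = t_L
  expect_equal(local_average_update(5, 1, 0.2, 0.2), 1)
  expect_error(local_average_update(0, 1, 0.3, 0.2), "must not exceed")
  expect_error(local_average_update(c(0, 0), 1, 0.001, 0.2), "same shape")
})

test_that("recursive filter equals the explicit discrete convolution", {
  dt <- 0.001; t_L <- 0.2; a <- dt / t_L
  n <- 1e4
  x <- sin(2 * pi * (1:n) * dt / 0.8) + 0.3 * sin(2 * pi * (1:n) * dt / 0.05)
  rec <- numeric(n); avg <- 0
  for (i in 1:n) {
    avg <- local_average_update(avg, x[i], dt, t_L)
    rec[i] <- avg
  }
  # oracle: weights a (1-a)^k applied to the stored history
  w <- a * (1 - a)^(0:(n - 1))
  conv <- stats::convolve(x, rev(w), type = "open")[seq_len(n)]
  expect_lt(max(abs(rec - conv)) / max(abs(rec)), 1e-10)
})

test_that("position and energy averages advance in the written order", {
  st <- list(r_avg = matrix(1, 1, 3), r_avg2 = matrix(1, 1, 3),
             E_avg = 2, E_avg2 = 2)
  # constants stay put
  st2 <- update_position_and_energy_averages(st, matrix(1, 1, 3), 2, 0.001, 0.2)
  expect_equal(st2, st)
  # one step from cold start moves by (dt/t_L)(v - old); the second-order
  # averages see the just-updated first-order ones
  a <- 0.001 / 0.2
  st3 <- update_position_and_energy_averages(st, matrix(2, 1, 3), 4, 0.001, 0.2)
  expect_equal(st3$E_avg, 2 + a * 2)
  expect_equal(st3$E_avg2, 2 + a * (st3$E_avg - 2))
  expect_equal(st3$r_avg[1, 1], 1 + a)
  expect_equal(st3$r_avg2[1, 1], 1 + a * (st3$r_avg[1, 1] - 1))
  expect_error(
    update_position_and_energy_averages(st, matrix(1, 2, 3), 2, 0.001, 0.2),
    "shapes")
})

test_that("low-frequency state: cold start, identity and ramp steady state", {
  m <- 39.948; dt <- 0.001; t_L <- 0.2
  r <- matrix(c(1, 2, 3), 1, 3)
  cold <- derive_low_frequency_state(r, r, r, matrix(0, 1, 3), m, dt, t_L)
  expect_equal(cold$p_tilde, matrix(0, 1, 3))
  expect_equal(cold$F_tilde2, matrix(0, 1, 3))
  # F_tilde == (p - p_tilde)/t_L identically
  set.seed(2)
  for (i in 1:5) {
    s <- derive_low_frequency_state(matrix(rnorm(3), 1), matrix(rnorm(3), 1),
                                    matrix(rnorm(3), 1), matrix(rnorm(3), 1),
                                    m, dt, t_L)
    expect_equal(s$F_tilde, (s$p_full - s$p_tilde) / t_L)
  }
  # uniform motion: p_tilde converges to m v (discrete fixed point
  # m v (1 - dt/t_L)), contracting towards it by (1 - dt/t_L) each step
  v <- 2.5
  p_star <- m * v * (1 - dt / t_L)
  r_avg <- 0; gaps <- numeric(4000)
  for (k in 1:4000) {
    x <- v * k * dt
    r_avg <- local_average_update(r_avg, x, dt, t_L)
    pt <- m / t_L * (x - r_avg)
    gaps[k] <- p_star - pt
  }
  ratios <- gaps[3:100] / gaps[2:99]
  expect_equal(ratios, rep(1 - dt / t_L, length(ratios)), tolerance = 1e-9)
  expect_equal(pt, p_star, tolerance = 1e-7)
  expect_equal(pt, m * v, tolerance = 2 * dt / t_L)
  expect_error(derive_low_frequency_state(r, r, r, r * 0, m, 0, t_L), "dt")
})

test_that("apparent friction recovers exact proportionality and guards", {
  dt <- 0.001; t_avg <- 2
  acc <- list(FP = 0, PP = 0)
  set.seed(4)
  for (i in 1:25000) {  # > 10 t_avg of samples
    pt <- matrix(rnorm(3), 1)
    dF <- -3 * pt  # exactly proportional stream
    acc <- update_friction_estimate(acc, dF, matrix(0, 1, 3), pt, dt, t_avg)
  }
  expect_equal(acc$xi, 3, tolerance = 1e-8)
  # zero momentum: guard keeps xi at 0 with no division error
  acc0 <- list(FP = 0, PP = 0)
  acc0 <- update_friction_estimate(acc0, matrix(1, 1, 3), matrix(0, 1, 3),
                                   matrix(0, 1, 3), dt, t_avg)
  expect_identical(acc0$xi, 0)
  # white noise uncorrelated with p_tilde: xi ~ 0
  accw <- list(FP = 0, PP = 0)
  set.seed(8)
  for (i in 1:1e5) {
    accw <- update_friction_estimate(accw, matrix(rnorm(3), 1),
                                     matrix(0, 1, 3), matrix(rnorm(3), 1),
                                     dt, t_avg)
  }
  expect_lt(abs(accw$xi), 3 * sqrt(1 / (3 * t_avg / dt)) * 3)
})

test_that("guiding force combines the two guiding terms", {
  z <- matrix(0, 1, 3)
  expect_equal(guiding_force(0, 0, 5, matrix(1, 1, 3), matrix(2, 1, 3), z), z)
  expect_equal(guiding_force(1, 0, 2, matrix(c(1, 0, 0), 1), z, z),
               matrix(c(2, 0, 0), 1))
  expect_equal(guiding_force(0, -0.2, 0, z, matrix(c(5, 0, 0), 1), z),
               matrix(c(-1, 0, 0), 1))
})

test_that("eta follows the conservation formula with guarded degeneracies", {
  z <- matrix(0, 1, 3)
  expect_identical(conservation_scaling_eta(z, matrix(1, 1, 3), z, 0, 1, 0.001),
                   0)
  # arithmetic case: gamma = 0, g.p0 = 1, p0^2 = 10, exactly constructed
  # with f = -g so p0 = m v_half: eta = 2 * 1 / (2*10 - 1*dt)
  dt <- 0.001
  g2 <- matrix(c(1 / sqrt(10), 0, 0), 1)
  v2 <- matrix(c(sqrt(10), 0, 0), 1)
  eta2 <- conservation_scaling_eta(g2, v2, -g2, 0, 1, dt)
  expect_equal(eta2, 2 / (20 - 0.001), tolerance = 1e-12)
  expect_warning(
    conservation_scaling_eta(matrix(c(1, 0, 0), 1), z, z, 0, 1, dt),
    "eta guard")
})

test_that("eta cancels the guiding-force work in the velocity update", {
  # free particle, gamma = 0: one velocity update with and without eta.
  # eta solves the discrete cancellation condition, so the kinetic-energy
  # change with eta vanishes to rounding while the unscaled update gains
  # the guiding work g.v dt (+ O(dt^2)).
  m <- 10; v <- matrix(c(1.2, -0.4, 0.7), 1)
  g <- matrix(c(3, 1, -2), 1)
  ke <- function(vv) 0.5 * m * sum(vv^2)
  dke <- function(dt, use_eta) {
    eta <- if (use_eta)
      conservation_scaling_eta(g, v, matrix(0, 1, 3), 0, m, dt) else 0
    c <- eta * dt / 2
    vnew <- ((1 - c) * v + g * dt / m) / (1 + c)
    ke(vnew) - ke(v)
  }
  for (dt in c(0.002, 0.001)) {
    expect_lt(abs(dke(dt, TRUE)), 1e-12 * ke(v))
    expect_equal(dke(dt, FALSE), sum(g * v) * dt, tolerance = 1e-3)
  }
})

test_that("balanced guiding factors are mutual inverses with the printed pins", {
  expect_equal(balanced_force_factor(0), 0, tolerance = 1e-12)
  expect_equal(balanced_momentum_factor(0), 0)
  expect_equal(round(balanced_force_factor(1), 4), 0.3247)
  expect_equal(round(balanced_force_factor(-1), 4), -0.3177)
  expect_equal(round(equivalent_force_factor(1), 4), -0.3247)
  expect_equal(round(equivalent_force_factor(-1), 4), 0.3177)
  for (lam in seq(-1, 1, by = 0.125)) {
    expect_lt(abs(balanced_momentum_factor(balanced_force_factor(lam)) - lam),
              1e-10)
  }
  expect_equal(balanced_momentum_factor(balanced_force_factor(1)), 1,
               tolerance = 1e-10)
  expect_equal(balanced_momentum_factor(balanced_force_factor(-1)), -1,
               tolerance = 1e-10)
  expect_error(balanced_momentum_factor(-1), "exceed")
  expect_error(balanced_force_factor(1.95), "real-root")
})

test_that("GLE nu solves lambda = nu(2 - nu) on the lower branch", {
  expect_equal(gle_nu(0), 0)
  expect_equal(gle_nu(1), 1)
  expect_equal(gle_nu(0.75), 0.5)
  for (lam in seq(-0.5, 1, by = 0.25)) {
    nu <- gle_nu(lam)
    expect_lt(abs(nu * (2 - nu) - lam), 1e-14)
  }
  expect_error(gle_nu(1.1), "exceed 1")
})

test_that("recursive colored noise equals the explicit convolution", {
  set.seed(21)
  n <- 2000; dt <- 0.001; t_L <- 0.2; a <- dt / t_L
  lambda <- 0.8; nu <- gle_nu(lambda)
  R <- matrix(rnorm(3 * n), n, 3)
  colored <- gle_colored_noise(R, nu, dt, t_L)
  # oracle: R_n - nu [ (1-a) sum_{k>=1} a(1-a)^(k-1) R_{n-k} + (a/2) R_n ]
  for (n_at in c(1, 7, 1000, 2000)) {
    k <- seq_len(n_at - 1)
    hist_w <- if (length(k)) (1 - a) * a * (1 - a)^(k - 1) else numeric(0)
    expected <- R[n_at, ] * (1 - nu * a / 2) -
      if (length(k)) nu * colSums(hist_w * R[n_at - k, , drop = FALSE]) else 0
    expect_lt(max(abs(colored[n_at, ] - expected)), 1e-12)
  }
  # lambda = 0 leaves the white stream untouched
  expect_identical(gle_colored_noise(R, gle_nu(0), dt, t_L), R)
})
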