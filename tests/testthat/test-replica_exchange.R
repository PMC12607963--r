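test_that("frequency factors reduce correctly with and without guiding", {
  n <- 8
  set.seed(19)
  f <- matrix(rnorm(3 * n), n); p <- matrix(rnorm(3 * n), n)
  favg <- f * 0.6; pavg <- p * 0.4
  z <- matrix(0, n, 3)
  # zero guiding: both collision factors are exactly 1
  ff <- frequency_factors(f, favg, z, z, p, pavg, gamma = 10)
  expect_equal(ff$chi_lf, 1)
  expect_equal(ff$chi_hf, 1)
  # plain MD (gamma = 0, g = 0): lambda_lf is a self-projection = 1
  ff0 <- suppressWarnings(frequency_factors(f, favg, z, z, p, pavg,
                                            gamma = 0))
  expect_equal(ff0$lambda_lf, 1)
  expect_equal(ff0$lambda_hf, 1)
  # synthetic g_avg = gamma p_avg / 2 halves the low-frequency collision factor
  ffh <- frequency_factors(f, favg, 10 * p / 2, 10 * pavg / 2, p, pavg,
                           gamma = 10)
  expect_equal(ffh$chi_lf, 0.5)
  degen <- testthat::capture_warnings(
    frequency_factors(z, z, z, z, z, z, gamma = 10))
  expect_true(any(grepl("degenerate", degen)))
})

test_that("exchange coefficients follow their definitions", {
  kB <- sg_constants()$kB
  no_guide <- list(lambda_lf = 1, lambda_hf = 1, chi_lf = 1, chi_hf = 1)
  co <- exchange_coefficients(274, no_guide)
  expect_equal(co$l, 0)
  expect_equal(co$h, 1 / (kB * 274))
  co2 <- exchange_coefficients(274, list(lambda_lf = 1.2, lambda_hf = 1,
                                         chi_lf = 1, chi_hf = 1))
  expect_equal(co2$l, 0.2 / (kB * 274))
  # cancellation whenever the low- and high-frequency products agree
  co3 <- exchange_coefficients(300, list(lambda_lf = 0.8, lambda_hf = 1,
                                         chi_lf = 1.5, chi_hf = 1.2))
  expect_equal(co3$l, 0)
})

test_that("legacy exchange probability is Metropolis-symmetric", {
  kB <- sg_constants()$kB
  cm <- list(l = 0.1, h = 1 / (kB * 300))
  cn <- list(l = 0.25, h = 1 / (kB * 320))
  # identical coefficients: unit probability
  same <- exchange_probability_legacy(1, 0.5, 2, 0.7, cm, cm)
  expect_equal(same$prob, 1)
  # printed arithmetic: only the high-frequency term, exponent -0.01
  ar <- exchange_probability_legacy(0, 0, 1, 0, list(l = 0.1, h = 0.11),
                                    list(l = 0.1, h = 0.10))
  expect_equal(ar$ratio, exp(-0.01))
  expect_equal(ar$prob, 0.99005, tolerance = 1e-5)
  # detailed balance: forward and reverse raw ratios multiply to 1
  set.seed(5)
  for (i in 1:10) {
    E <- rnorm(2); Ea <- rnorm(2)
    fwd <- exchange_probability_legacy(E[1], Ea[1], E[2], Ea[2], cm, cn)
    rev <- exchange_probability_legacy(E[2], Ea[2], E[1], Ea[1], cm, cn)
    expect_equal(fwd$ratio * rev$ratio, 1, tolerance = 1e-12)
  }
})

test_that("generalized exchange probability handles balance and symmetry", {
  s300 <- list(temperature = 300, lambda = 0, mu = 0)
  s300b <- list(temperature = 300, lambda = 1, mu = balanced_force_factor(1))
  s350 <- list(temperature = 350, lambda = 0.5, mu = -0.1)
  # identical stage parameters: unit probability
  expect_equal(exchange_probability_generalized(1, 0.5, 0.2, 3, 1, 0.1,
                                                s300, s300)$prob, 1)
  # equal temperature, both stages balanced: unit probability at any energies
  set.seed(6)
  for (i in 1:5) {
    E <- rnorm(2, sd = 5); Ea <- rnorm(2); Ea2 <- rnorm(2)
    pr <- exchange_probability_generalized(E[1], Ea[1], Ea2[1],
                                           E[2], Ea[2], Ea2[2], s300, s300b)
    expect_equal(pr$prob, 1)
    expect_equal(pr$ratio, 1)
  }
  # detailed-balance products
  for (i in 1:10) {
    E <- rnorm(2); Ea <- rnorm(2); Ea2 <- rnorm(2)
    fwd <- exchange_probability_generalized(E[1], Ea[1], Ea2[1], E[2], Ea[2],
                                            Ea2[2], s300, s350)
    rev <- exchange_probability_generalized(E[2], Ea[2], Ea2[2], E[1], Ea[1],
                                            Ea2[1], s300, s350)
    expect_equal(fwd$ratio * rev$ratio, 1, tolerance = 1e-12)
  }
  # stage-term arithmetic at equal temperatures
  beta <- 1 / (sg_constants()$kB * 300)
  sA <- list(temperature = 300, lambda = 0, mu = 0.05 / beta)
  pr <- exchange_probability_generalized(0, 2, 0, 0, 0, 0, sA, s300)
  expect_equal(pr$ratio, exp(0.1))
})

test_that("Metropolis acceptance matches the computed probability", {
  # constructed pair with ratio exp(-log 2) = 0.5 at equal temperatures
  beta <- 1 / (sg_constants()$kB * 300)
  stage_m <- list(stage = 0, temperature = 300, lambda = 0, mu = 0)
  stage_n <- list(stage = 1, temperature = 300, lambda = 0,
                  mu = log(2) / (2 * beta))
  rep_i <- list(stage = stage_m, E_p = 0, E_avg = 2, E_avg2 = 0)
  rep_j <- list(stage = stage_n, E_p = 0, E_avg = 0, E_avg2 = 0)
  probe <- attempt_exchange(rep_i, rep_j)
  expect_equal(probe$prob, 0.5, tolerance = 1e-12)
  set.seed(10)
  acc <- vapply(1:10000, function(i)
    attempt_exchange(rep_i, rep_j)$accepted, logical(1))
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / 10000))
  # swapped assignments on acceptance
  hit <- attempt_exchange(rep_i, rep_j)
  if (hit$accepted) {
    expect_equal(hit$rep_i$stage$stage, 1)
    expect_equal(hit$rep_j$stage$stage, 0)
  }
  expect_warning(attempt_exchange(rep_i, rep_i), "same-stage")
})

test_that("identical-stage ladders accept everything and walk symmetrically", {
  sys <- sdw_system()
  stages <- suppressWarnings(stage_ladder(rep(300, 3), lambda = 0))
  cfg <- sg_config(n_steps = 1, temperature = 300,
                   guiding = guiding_params("SGLD", gamma = 10), seed = 2,
                   record_every = 1)
  rx <- run_rxsgld(sys, stages, cfg, n_cycles = 60, exchange_interval = 200)
  expect_equal(sum(rx$acceptance$acceptances), sum(rx$acceptance$attempts))
  # permutation conservation: every cycle's assignment is a bijection
  for (j in seq_len(ncol(rx$stage_trace)))
    expect_setequal(rx$stage_trace[, j], 0:2)
  # the base replica reaches every stage (random-walk reachability)
  expect_setequal(unique(rx$stage_trace[1, ]), 0:2)
})

test_that("exchange leaves the stage ensembles statistically intact", {
  sys <- sdw_system()
  stages <- suppressWarnings(stage_ladder(rep(300, 2), lambda = 0))
  cfg <- sg_config(n_steps = 1, temperature = 300,
                   guiding = guiding_params("SGLD", gamma = 10), seed = 8,
                   record_every = 1)
  # 1 ps between retained samples so both series are quasi-independent
  rx <- run_rxsgld(sys, stages, cfg, n_cycles = 200, exchange_interval = 1000)
  base <- rx$frames$E_p[rx$frames$stage == 0 & rx$frames$cycle > 20]
  solo <- sdw_run(0, 0, 88, n_steps = 2e5, record_every = 1000)
  ks <- suppressWarnings(stats::ks.test(base, warm_frames(solo)$E_p))
  expect_gt(ks$p.value, 0.01)
})

test_that("the stage ladder validates its base stage", {
  expect_warning(stage_ladder(300, lambda = c(0.5, 1)), "base stage")
  expect_warning(stage_ladder(c(300, 350)), "unequal stage temperatures")
  expect_error(stage_ladder(300), "at least 2")
})
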