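# Shared fixtures, built in code.  Expensive equilibrated states are cached
# for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

# small periodic argon box at the reference liquid density, LD-equilibrated
argon_fixture <- function(n_atoms = 125, t_equil = 20) {
  key <- paste0("argon_", n_atoms)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  box <- 28.53 / (500 / n_atoms)^(1 / 3)
  cutoff <- min(10, 0.95 * box / 2)
  ar <- build_argon_system(n_atoms, box = box, temperature = 100, seed = 1234,
                           params = lj_params(cutoff = cutoff))
  cfg <- sg_config(n_steps = round(t_equil / 0.001), temperature = 100,
                   guiding = guiding_params("LD", gamma = 10), seed = 4321,
                   record_every = 1000)
  eq <- run_simulation(ar$system, cfg, ar$positions, ar$velocities)
  out <- list(system = ar$system, positions = eq$positions,
              velocities = eq$velocities)
  .fixture_cache[[key]] <- out
  out
}

# one SDW production run with the reference guiding settings
sdw_run <- function(lambda, mu, seed, n_steps = 1e6, mode = NULL,
                    record_positions = FALSE, record_every = 20) {
  if (is.null(mode))
    mode <- if (lambda == 0 && mu == 0) "LD" else "SGLD"
  g <- if (mode == "LD") guiding_params("LD", gamma = 10) else
    guiding_params(mode, lambda = lambda, mu = mu, gamma = 10)
  cfg <- sg_config(n_steps = n_steps, dt = 0.001, temperature = 300,
                   guiding = g, seed = seed, record_every = record_every,
                   record_positions = record_positions)
  run_simulation(sdw_system(), cfg)
}

# post-warm-up frames of a run
warm_frames <- function(run) {
  fr <- run$frames
  fr[fr$t - fr$t[1] >= run$config$warmup, , drop = FALSE]
}

# standard error of a reweighted mean from block-wise reweighted averages
block_se_weighted <- function(values, weights, n_blocks = 50) {
  n <- length(values)
  block <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  bm <- vapply(split(seq_len(n), block),
               function(i) sum(values[i] * weights[i]) / sum(weights[i]),
               numeric(1))
  sd(bm) / sqrt(length(bm))
}

# central finite-difference forces for any energy function
fd_forces <- function(efun, positions, h = 1e-5) {
  positions <- rbind(positions)
  out <- positions * 0
  for (i in seq_len(nrow(positions))) for (d in 1:3) {
    up <- positions; up[i, d] <- up[i, d] + h
    dn <- positions; dn[i, d] <- dn[i, d] - h
    out[i, d] <- -(efun(up) - efun(dn)) / (2 * h)
  }
  out
}
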