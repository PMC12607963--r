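# Leap-frog drivers: plain MD/LD baselines, the generalized SGMD/SGLD
# algorithm, and the SGLD-GLE colored-noise variant.  The inner loop lives in
# compiled code; this file owns configuration, validation, dispatch and the
# `sg_run` result class.

.sg_modes <- c("MD", "LD", "SGMD", "SGLD", "SGLD-GLE")

#' Guiding parameters
#'
#' The knobs of a self-guided run: the local average time `t_L` (frequency
#' threshold 1/t_L; 0.2 ps filters out covalent-bond-scale vibration), the
#' long average time `t_avg` used for the apparent-friction estimate
#' (typically 10 t_L), the momentum guiding factor `lambda` (positive values
#' promote diffusion-controlled search), the force guiding factor `mu`
#' (negative values lower effective barriers), and the collision constant
#' `gamma` of the Langevin bath.
#'
#' @param mode One of "MD", "LD", "SGMD", "SGLD", "SGLD-GLE".
#' @param lambda Momentum guiding factor (SGLD-GLE requires lambda <= 1).
#' @param mu Force guiding factor (must be 0 for SGLD-GLE).
#' @param t_L Local average time (ps), > 0.
#' @param t_avg Long average time (ps), >= t_L; default 10 t_L.
#' @param gamma Collision/friction constant (1/ps).  Must be 0 for MD/SGMD
#'   and > 0 for the stochastic modes; defaults accordingly (10/ps for
#'   LD/SGLD/SGLD-GLE).
#' @return An object of class `guiding_params`.
#' @export
guiding_params <- function(mode = "LD", lambda = 0, mu = 0, t_L = 0.2,
                           t_avg = 10 * t_L, gamma = NULL) {
  mode <- match.arg(mode, .sg_modes)
  if (is.null(gamma)) gamma <- if (mode %in% c("MD", "SGMD")) 0 else 10
  stopifnot(t_L > 0, t_avg >= t_L, gamma >= 0)
  if (mode %in% c("MD", "SGMD") && gamma != 0)
    stop("gamma must be exactly 0 for ", mode)
  if (mode %in% c("LD", "SGLD", "SGLD-GLE") && gamma <= 0)
    stop("gamma must be positive for ", mode)
  if (mode == "SGLD-GLE") {
    if (mu != 0) stop("SGLD-GLE uses momentum guiding only (mu must be 0)")
    if (lambda > 1) stop("SGLD-GLE requires lambda <= 1 (nu would be complex)")
  }
  if (mode %in% c("MD", "LD") && (lambda != 0 || mu != 0))
    stop("guiding factors must be 0 in mode ", mode)
  structure(list(mode = mode, lambda = lambda, mu = mu, t_L = t_L,
                 t_avg = t_avg, gamma = gamma), class = "guiding_params")
}

#' Integrator configuration
#'
#' @param n_steps Number of leap-frog steps.
#' @param dt Timestep (ps); must not exceed the guiding `t_L`.
#' @param temperature Bath/target temperature (K).
#' @param guiding A [guiding_params()] object.
#' @param seed Optional integer seed applied at the start of the run.
#' @param record_every Steps between saved frames (>= 1).
#' @param record_positions,record_velocities Record per-frame trajectories
#'   (positions are unwrapped, so mean-square displacements stay valid under
#'   periodic boundaries).
#' @param eta Apply the energy-conservation scaling factor (SGMD/SGLD).
#'   Disabling it is only useful for demonstrating the guiding-force heating
#'   it cancels.
#' @param warmup Equilibration span (ps) excluded from ensemble summaries;
#'   default 5 t_L, when the local averages become representative.
#' @return An object of class `sg_config`.
#' @export
sg_config <- function(n_steps, dt = 0.001, temperature = 300,
                      guiding = guiding_params(), seed = NULL,
                      record_every = 10, record_positions = FALSE,
                      record_velocities = FALSE, eta = TRUE,
                      warmup = 5 * guiding$t_L) {
  stopifnot(inherits(guiding, "guiding_params"), n_steps >= 0, dt > 0,
            temperature > 0, record_every >= 1)
  if (dt > guiding$t_L)
    stop("dt must not exceed the local average time t_L")
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 temperature = temperature, guiding = guiding, seed = seed,
                 record_every = as.integer(record_every),
                 record_positions = record_positions,
                 record_velocities = record_velocities, eta = eta,
                 warmup = warmup), class = "sg_config")
}

.default_positions <- function(system) {
  if (system$potential == "sdw") {
    # start in the deeper well
    matrix(c(0, -system$params$y0, 0), 1, 3)
  } else if (system$potential == "harmonic") {
    matrix(0, system$n_atoms, 3)
  } else {
    stop("LJ systems need explicit initial positions ",
         "(see build_argon_system())")
  }
}

#' Run a (self-guided) dynamics simulation
#'
#' Integrates the equation of self-guided motion with the generalized
#' leap-frog algorithm: potential evaluation; exponential local averages of
#' energy and positions; derived low-frequency momentum and forces; the
#' on-the-fly apparent-friction estimate; the guiding force
#' g = mu (F_tilde - F_tilde2) + lambda xi p_tilde; the energy-conservation
#' scaling factor eta; then the staggered velocity and position updates.
#' Modes "MD" and "LD" run the plain baselines (to which SGMD/SGLD reduce
#' exactly at lambda = mu = 0); "SGLD-GLE" replaces the guiding force by
#' lambda gamma p_tilde and the white noise by the colored stream
#' R - nu R_tilde (nu = 1 - sqrt(1 - lambda)), with no eta scaling — that
#' variant preserves the canonical ensemble by construction.
#'
#' @param system An `sg_system` (see [sdw_system()], [lj_system()],
#'   [harmonic_system()]).
#' @param config An [sg_config()].
#' @param positions Initial positions (n x 3); defaults to the system's
#'   natural start (SDW: the deeper well; harmonic: the origin).
#' @param velocities Initial half-step velocities (n x 3); drawn from the
#'   Maxwell-Boltzmann distribution at `config$temperature` if omitted.
#' @param state Internal dynamics state from a previous run's `$state`, to
#'   continue a trajectory (local averages and friction accumulators carry
#'   over); `NULL` cold-starts the averages at the current values.
#' @return An object of class `sg_run`: `frames` (a data frame of per-frame
#'   records: time, potential energy and its two local averages, the
#'   reweighting factor `w`, kinetic and low-frequency temperatures, mean
#'   apparent friction, total energy and the frequency-separated diagnostic
#'   factors), final `positions`/`velocities`, the continuation `state`, and
#'   `pos_traj`/`vel_traj` arrays (frames x atoms x 3) when recorded.
#' @examples
#' cfg <- sg_config(n_steps = 2000, guiding = guiding_params("SGLD", lambda = 1),
#'                  seed = 1)
#' run <- run_simulation(sdw_system(), cfg)
#' summary(run)
#' @export
run_simulation <- function(system, config, positions = NULL,
                           velocities = NULL, state = NULL) {
  stopifnot(inherits(system, "sg_system"), inherits(config, "sg_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(positions)) positions <- .default_positions(system)
  positions <- .check_positions(positions, system$n_atoms)
  if (is.null(velocities))
    velocities <- maxwell_velocities(system$masses, config$temperature)
  velocities <- .check_positions(velocities, system$n_atoms)
  g <- config$guiding
  mode_code <- match(g$mode, .sg_modes) - 1L
  pot_code <- match(system$potential, c("harmonic", "sdw", "lj")) - 1L

  out <- .sg_run_cpp(positions, velocities, system$masses, pot_code,
                     system$pot_params,
                     if (is.null(system$box)) 0 else system$box,
                     mode_code, config$dt, config$n_steps,
                     config$temperature, g$gamma, g$lambda, g$mu, g$t_L,
                     g$t_avg, isTRUE(config$eta), config$record_every,
                     isTRUE(config$record_positions),
                     isTRUE(config$record_velocities), state)
  if (isTRUE(out$overlap))
    warning("overlapping atoms encountered during the run (r < 0.1 A)")
  if (out$eta_guard_hits > 0)
    warning("eta guard triggered ", out$eta_guard_hits,
            " time(s): |p0| ~ 0 with nonzero guiding force")

  frames <- as.data.frame(out$frames)
  frames$w <- conformation_weight(frames$E_avg, frames$E_avg2, g$lambda,
                                  g$mu, config$temperature,
                                  mode = g$mode)
  res <- structure(list(frames = frames, positions = out$positions,
                        velocities = out$velocities, state = out$state,
                        E_p = out$E_p, system = system, config = config,
                        eta_guard_hits = out$eta_guard_hits),
                   class = "sg_run")
  if (!is.null(out$pos_traj)) res$pos_traj <- aperm(out$pos_traj, c(3, 2, 1))
  if (!is.null(out$vel_traj)) res$vel_traj <- aperm(out$vel_traj, c(3, 2, 1))
  res
}

#' Advance a dynamics state by a single leap-frog step
#'
#' Convenience wrapper around [run_simulation()] with `n_steps = 1` and
#' every frame recorded; useful for stepwise inspection and hand-checked
#' ordering tests (velocities advance before positions).
#'
#' @inheritParams run_simulation
#' @return An `sg_run` for the single step.
#' @export
sg_leapfrog_step <- function(system, config, positions, velocities,
                             state = NULL) {
  config$n_steps <- 1L
  config$record_every <- 1L
  run_simulation(system, config, positions, velocities, state)
}

#' @export
print.sg_run <- function(x, ...) {
  g <- x$config$guiding
  cat("<sg_run> ", g$mode, " | ", x$system$potential, ", ",
      x$system$n_atoms, " atom(s)\n", sep = "")
  cat(sprintf("  %d steps of %g ps (%.4g ps), T = %g K, gamma = %g/ps\n",
              x$config$n_steps, x$config$dt,
              x$config$n_steps * x$config$dt, x$config$temperature, g$gamma))
  if (g$mode %in% c("SGMD", "SGLD", "SGLD-GLE"))
    cat(sprintf("  lambda = %g, mu = %g, t_L = %g ps, t_avg = %g ps\n",
                g$lambda, g$mu, g$t_L, g$t_avg))
  cat(sprintf("  %d frames recorded\n", nrow(x$frames)))
  invisible(x)
}

#' @export
summary.sg_run <- function(object, ...) {
  fr <- object$frames
  warm <- fr[fr$t - fr$t[1] >= object$config$warmup, , drop = FALSE]
  if (nrow(warm) == 0) warm <- fr  # run shorter than the warm-up span
  rw <- reweighted_average(warm$E_p, warm$w)
  out <- list(
    mode = object$config$guiding$mode,
    n_frames = nrow(fr), n_warm = nrow(warm),
    E_p_mean = mean(warm$E_p), E_p_se = block_se(warm$E_p),
    E_p_reweighted = rw$mean, ess = rw$effective_sample_size,
    T_kin_mean = mean(warm$T_kin), T_lf_mean = mean(warm$T_lf),
    xi_mean = mean(warm$xi),
    E_tot_drift = if (nrow(warm) > 2)
      unname(coef(lm(warm$E_tot ~ warm$t))[2]) else NA_real_)
  class(out) <- "summary.sg_run"
  out
}

#' @export
print.summary.sg_run <- function(x, ...) {
  cat("<sg_run summary> mode ", x$mode, ", ", x$n_warm, "/", x$n_frames,
      " frames after warm-up\n", sep = "")
  cat(sprintf("  <E_p>      = %.5g +/- %.3g kcal/mol\n", x$E_p_mean, x$E_p_se))
  cat(sprintf("  reweighted = %.5g kcal/mol (ESS %.1f)\n",
              x$E_p_reweighted, x$ess))
  cat(sprintf("  <T_kin>    = %.4g K   <T_lf> = %.4g K   <xi> = %.3g /ps\n",
              x$T_kin_mean, x$T_lf_mean, x$xi_mean))
  if (is.finite(x$E_tot_drift))
    cat(sprintf("  E_tot drift = %.3g kcal/mol/ps\n", x$E_tot_drift))
  invisible(x)
}

#' @export
plot.sg_run <- function(x, which = c("energy", "temperature"), ...) {
  which <- match.arg(which)
  fr <- x$frames
  if (which == "energy") {
    plot(fr$t, fr$E_p, type = "l", col = "grey50", xlab = "t (ps)",
         ylab = "E (kcal/mol)", ...)
    graphics::lines(fr$t, fr$E_avg, col = "firebrick")
    graphics::legend("topright", c("E_p", "local average"),
                     col = c("grey50", "firebrick"), lty = 1, bty = "n")
  } else {
    plot(fr$t, fr$T_kin, type = "l", col = "grey50", xlab = "t (ps)",
         ylab = "T (K)", ...)
    graphics::lines(fr$t, fr$T_lf, col = "steelblue")
    graphics::legend("topright", c("T_kin", "T_lf"),
                     col = c("grey50", "steelblue"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Gaussian random forces of the Langevin bath
#'
#' Each Cartesian component is i.i.d. Gaussian with zero mean and variance
#' 2 gamma m kB T / dt (internal force units), the discretization consistent
#' with the leap-frog friction term.
#'
#' @param gamma Friction constant (1/ps).
#' @param mass Per-atom masses (amu).
#' @param temperature Bath temperature (K).
#' @param dt Timestep (ps).
#' @param n_atoms Number of atoms (defaults to `length(mass)`).
#' @return n x 3 matrix of random forces (amu*A/ps^2); zeros when gamma = 0.
#' @export
langevin_random_force <- function(gamma, mass, temperature, dt,
                                  n_atoms = length(mass)) {
  stopifnot(gamma >= 0, temperature > 0, dt > 0)
  m <- rep_len(mass, n_atoms)
  if (gamma == 0) return(matrix(0, n_atoms, 3))
  sd <- sqrt(2 * gamma * m * .kB_int * temperature / dt)
  matrix(rnorm(3 * n_atoms), n_atoms, 3) * sd
}
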