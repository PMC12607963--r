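# The self-guiding machinery at the R surface: exponential local averages,
# low-frequency quantities derived from them, the on-the-fly apparent
# friction estimate, guiding forces, the energy-conservation scaling factor,
# and the balanced guiding-factor conversions.
#
# These functions operate in internal units (A, ps, amu; momenta amu*A/ps,
# forces amu*A/ps^2).  The compiled integrator performs the identical
# arithmetic; the R versions are the documented, testable module surface.

#' One step of the exponential local average
#'
#' The local average of a signal P with time constant `t_L` is the
#' exponentially weighted running mean
#' \deqn{\tilde P_t = (1 - \delta t/t_L)\,\tilde P_{t-\delta t} +
#'       (\delta t/t_L)\, P_t,}
#' a first-order low-pass filter with frequency threshold 1/t_L.
#'
#' @param prev_avg Previous average (scalar, vector or matrix).
#' @param current_value Current signal value, same shape.
#' @param dt Timestep (ps); must satisfy 0 < dt <= t_L.
#' @param t_L Local average time (ps).
#' @return The updated average, same shape as the inputs.
#' @export
local_average_update <- function(prev_avg, current_value, dt, t_L) {
  if (!(dt > 0) || !(t_L > 0)) stop("dt and t_L must be positive")
  if (dt > t_L) stop("dt must not exceed t_L (filter ill-defined)")
  if (length(prev_avg) != length(current_value))
    stop("prev_avg and current_value must have the same shape")
  (1 - dt / t_L) * prev_avg + (dt / t_L) * current_value
}

#' Advance the position and energy local averages one step
#'
#' Updates the four stored local averages: the potential energy averages
#' (E_avg, then E_avg2 averaging the just-updated E_avg) and the position
#' averages (r_avg, then r_avg2 averaging the just-updated r_avg), in that
#' order.
#'
#' @param state List with `r_avg`, `r_avg2` (n x 3), `E_avg`, `E_avg2`.
#' @param positions Current positions (n x 3).
#' @param E_p Current potential energy.
#' @param dt,t_L Timestep and local average time (ps).
#' @return The updated state list.
#' @export
update_position_and_energy_averages <- function(state, positions, E_p, dt, t_L) {
  positions <- rbind(positions)
  if (!identical(dim(rbind(state$r_avg)), dim(positions)))
    stop("state and positions shapes disagree")
  state$E_avg <- local_average_update(state$E_avg, E_p, dt, t_L)
  state$E_avg2 <- local_average_update(state$E_avg2, state$E_avg, dt, t_L)
  state$r_avg <- local_average_update(state$r_avg, positions, dt, t_L)
  state$r_avg2 <- local_average_update(state$r_avg2, state$r_avg, dt, t_L)
  state
}

#' Low-frequency momentum and forces from the stored position averages
#'
#' Only the local-average positions need be stored during a run; the
#' low-frequency momentum and force components follow from them:
#' p_tilde = (m/t_L)(r - r_avg); the full-step momentum
#' p = p_tilde_prev + (t_L/dt)(p_tilde - p_tilde_prev); the local-average
#' force F_tilde = p/t_L - (m/t_L^2)(r - r_avg) = (p - p_tilde)/t_L; and its
#' local average F_tilde2 = (m/t_L^2)(r - 2 r_avg + r_avg2).
#'
#' @param positions Current positions (n x 3).
#' @param r_avg,r_avg2 Current-step local-average positions (already updated).
#' @param p_avg_prev Previous-step p_tilde (n x 3; zeros at cold start).
#' @param mass Per-atom masses (amu).
#' @param dt,t_L Timestep and local average time (ps).
#' @return List with `p_tilde`, `p_full`, `F_tilde`, `F_tilde2`
#'   (all n x 3, internal units).
#' @export
derive_low_frequency_state <- function(positions, r_avg, r_avg2, p_avg_prev,
                                       mass, dt, t_L) {
  if (dt == 0) stop("dt must be nonzero")
  positions <- rbind(positions); r_avg <- rbind(r_avg); r_avg2 <- rbind(r_avg2)
  p_avg_prev <- rbind(p_avg_prev)
  m <- rep_len(mass, nrow(positions))
  p_tilde <- m / t_L * (positions - r_avg)
  p_full <- p_avg_prev + t_L / dt * (p_tilde - p_avg_prev)
  F_tilde <- (p_full - p_tilde) / t_L
  F_tilde2 <- m / t_L^2 * (positions - 2 * r_avg + r_avg2)
  list(p_tilde = p_tilde, p_full = p_full, F_tilde = F_tilde,
       F_tilde2 = F_tilde2)
}

#' Advance the apparent-friction accumulators one step
#'
#' The apparent friction constant xi converts local-average momentum into
#' local-average force deviation: xi = -<(F_tilde - F_tilde2) . p_tilde> /
#' <p_tilde . p_tilde>, with the ensemble averages replaced by long-time
#' exponential averages (time constant `t_avg`, typically 10 t_L) stored in
#' the per-atom scalars FP and PP.  The ratio is guarded: until PP exceeds
#' 1e-12 (internal units), xi = 0.
#'
#' @param acc List with per-atom `FP`, `PP` (zeros at cold start).
#' @param F_tilde,F_tilde2,p_tilde Current low-frequency state (n x 3).
#' @param dt,t_avg Timestep and long average time (ps).
#' @return The updated accumulator list, with per-atom `xi` (1/ps) attached.
#' @export
update_friction_estimate <- function(acc, F_tilde, F_tilde2, p_tilde, dt,
                                     t_avg) {
  F_tilde <- rbind(F_tilde); F_tilde2 <- rbind(F_tilde2)
  p_tilde <- rbind(p_tilde)
  fp <- rowSums((F_tilde - F_tilde2) * p_tilde)
  pp <- rowSums(p_tilde * p_tilde)
  acc$FP <- local_average_update(acc$FP, fp, dt, t_avg)
  acc$PP <- local_average_update(acc$PP, pp, dt, t_avg)
  acc$xi <- ifelse(acc$PP > 1e-12, -acc$FP / acc$PP, 0)
  acc
}

#' The guiding force
#'
#' g = mu (F_tilde - F_tilde2) + lambda xi p_tilde, in internal force units
#' (amu*A/ps^2; divide by 418.4 for kcal/mol/A).
#'
#' @param lambda Momentum guiding factor.
#' @param mu Force guiding factor.
#' @param xi Per-atom apparent friction constant (1/ps).
#' @param p_tilde,F_tilde,F_tilde2 Low-frequency state (n x 3).
#' @return The guiding force (n x 3).
#' @export
guiding_force <- function(lambda, mu, xi, p_tilde, F_tilde, F_tilde2) {
  stopifnot(all(is.finite(xi)))
  mu * (rbind(F_tilde) - rbind(F_tilde2)) + lambda * xi * rbind(p_tilde)
}

#' Energy-conservation scaling factor
#'
#' The guiding force does work on the system; the per-atom velocity-scaling
#' rate eta cancels that work so that SGMD conserves total energy.  With the
#' free-move momentum p0 = m v(t - dt/2) + (f + g - gamma m v(t - dt/2)) dt/2,
#' \deqn{\eta = (2 + \gamma\,\delta t)\,(g \cdot p_0) /
#'       (2\,p_0^2 - (g \cdot p_0)\,\delta t).}
#' eta is exactly zero when g . p0 = 0, and is zeroed (with a warning) when
#' the denominator degenerates (p0 ~ 0).
#'
#' @param g Guiding force (n x 3, internal units).
#' @param v_half Velocities at t - dt/2 (n x 3, A/ps).
#' @param f Total force other than guiding (n x 3, internal units; includes
#'   the random force in Langevin dynamics).
#' @param gamma Friction constant (1/ps); 0 for SGMD.
#' @param mass Per-atom masses (amu).
#' @param dt Timestep (ps).
#' @return Per-atom eta (1/ps).
#' @export
conservation_scaling_eta <- function(g, v_half, f, gamma, mass, dt) {
  stopifnot(all(mass > 0), dt > 0)
  g <- rbind(g); v_half <- rbind(v_half); f <- rbind(f)
  m <- rep_len(mass, nrow(g))
  p0 <- m * v_half + (f + g - gamma * m * v_half) * dt / 2
  gp0 <- rowSums(g * p0)
  p0sq <- rowSums(p0 * p0)
  den <- 2 * p0sq - gp0 * dt
  eta <- numeric(nrow(g))
  live <- gp0 != 0
  degenerate <- live & abs(den) <= 1e-30
  if (any(degenerate))
    warning("eta guard: |p0| ~ 0 with a nonzero guiding force; eta set to 0")
  ok <- live & !degenerate
  eta[ok] <- (2 + gamma * dt) * gp0[ok] / den[ok]
  eta
}

# ---------------------------------------------------------------------------
# balanced guiding factors and the GLE noise parameter
# ---------------------------------------------------------------------------

#' Balanced momentum guiding factor of mu
#'
#' The momentum guiding factor whose conformational bias exactly cancels
#' that of the force guiding factor `mu`:
#' \deqn{\lambda_\mu = (1+\mu)^2 - 1/(1+\mu).}
#' Inverse of [balanced_force_factor()].
#'
#' @param mu Force guiding factor, > -1.
#' @return The balanced momentum guiding factor.
#' @export
balanced_momentum_factor <- function(mu) {
  if (any(mu <= -1)) stop("mu must exceed -1")
  (1 + mu)^2 - 1 / (1 + mu)
}

#' Balanced force guiding factor of lambda
#'
#' Solves the balance relation lambda = (1+mu)^2 - 1/(1+mu) for mu, i.e.
#' finds the unique positive real root u = 1 + mu of the cubic
#' u^3 - lambda u - 1 = 0.  The root is unique for lambda below
#' (27/4)^(1/3) ~ 1.8899; beyond that the balance relation has no single
#' real branch and the input is rejected.  At the reference points,
#' mu_lambda(1) = 0.324718 and mu_lambda(-1) = -0.317672 (the printed
#' guiding-factor correspondence |mu| = 0.3247, 0.3177 carries the opposite
#' sign because it maps equivalent *enhancement*, not cancellation; see
#' [equivalent_force_factor()]).
#'
#' @param lambda Momentum guiding factor, <= (27/4)^(1/3).
#' @return The balanced force guiding factor mu_lambda.
#' @seealso [balanced_momentum_factor()], [equivalent_force_factor()]
#' @export
balanced_force_factor <- function(lambda) {
  vapply(lambda, function(l) {
    if (!is.finite(l) || 81 - 12 * l^3 < 0)
      stop("lambda outside the real-root regime (lambda <= (27/4)^(1/3))")
    h <- function(u) u^3 - l * u - 1
    hi <- 2 + abs(l)
    u <- uniroot(h, c(1e-12, hi), tol = 1e-14)$root
    for (i in 1:3) u <- u - h(u) / (3 * u^2 - l)  # Newton polish
    u - 1
  }, numeric(1))
}

#' Force guiding factor with enhancement equivalent to lambda
#'
#' Applying the momentum guiding factor `lambda` alone biases the
#' conformational distribution exactly as the force guiding factor
#' -mu_lambda would: a positive lambda and a negative mu both promote
#' low-frequency motion.  This is the correspondence quoted for the usable
#' range lambda = -1..1 <-> mu = 0.3177..-0.3247.
#'
#' @param lambda Momentum guiding factor.
#' @return -[balanced_force_factor()]`(lambda)`.
#' @export
equivalent_force_factor <- function(lambda) -balanced_force_factor(lambda)

#' GLE noise parameter nu from lambda
#'
#' The colored-noise parameter of SGLD-GLE satisfies lambda = nu (2 - nu);
#' the branch nu = 1 - sqrt(1 - lambda) is used.
#'
#' @param lambda Momentum guiding factor, <= 1.
#' @return nu in `[0, 1]` for lambda in `[0, 1]`.
#' @export
gle_nu <- function(lambda) {
  if (any(lambda > 1)) stop("lambda must not exceed 1 for SGLD-GLE")
  1 - sqrt(1 - lambda)
}

#' Colored noise stream R - nu * R_tilde
#'
#' Applies the SGLD-GLE noise construction to a white-noise history: each row
#' of `R` is one step; `R_tilde` is the exponential local average of the rows
#' (time constant `t_L`, cold-started at zero) and the returned stream is
#' R - nu * R_tilde row by row — the same recursion the integrator uses.
#' The current-step impulse straddles the averaging-window boundary and
#' enters `R_tilde` with half weight (the delta-function convention of the
#' memory-kernel derivation); full weight would leave an O(dt/t_L) cold bias
#' in the sampled temperature.
#'
#' @param R Matrix (steps x components) of white noise draws.
#' @param nu Noise parameter from [gle_nu()].
#' @param dt,t_L Timestep and local average time (ps).
#' @return Matrix of the colored noise, same shape as `R`.
#' @export
gle_colored_noise <- function(R, nu, dt, t_L) {
  R <- rbind(R)
  a <- dt / t_L
  if (a <= 0 || a > 1) stop("require 0 < dt <= t_L")
  out <- R
  avg <- numeric(ncol(R))
  for (i in seq_len(nrow(R))) {
    out[i, ] <- R[i, ] - nu * ((1 - a) * avg + 0.5 * a * R[i, ])
    avg <- (1 - a) * avg + a * R[i, ]
  }
  out
}
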