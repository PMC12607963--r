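# Self-guided ensemble weights and canonical-average recovery, plus the
# low-frequency / self-guiding temperature diagnostics.

#' Conformation weight of a self-guided frame
#'
#' A self-guided run with guiding factors (lambda, mu) samples the SG
#' ensemble, whose bias relative to the canonical ensemble lives entirely on
#' the low-frequency energy surface (E_avg - E_avg2).  The per-frame weight
#' that recovers canonical averages is
#' \deqn{w = \exp(+\beta\,(\mu - \mu_\lambda)(\tilde E_p - \tilde{\tilde E}_p)),}
#' the importance ratio between the canonical ensemble and the self-guided
#' ensemble with bias surface (mu - mu_lambda)(E_avg - E_avg2),
#' with mu_lambda the balanced force guiding factor of lambda.  At balanced
#' guiding (mu = mu_lambda) — in particular at lambda = mu = 0 — every weight
#' is 1 and the run is already canonical.  Exponents are clipped at +/- 700
#' (with a warning) to avoid overflow.
#'
#' @param E_avg,E_avg2 Per-frame local-average energies (kcal/mol).
#' @param lambda,mu Guiding factors of the run.
#' @param temperature Temperature (K) defining beta; the thermostat target.
#' @param mode Simulation mode; for "MD", "LD" and the canonical-by-
#'   construction "SGLD-GLE" the weight is identically 1.
#' @return Per-frame weights.
#' @export
conformation_weight <- function(E_avg, E_avg2, lambda, mu, temperature,
                                mode = "SGLD") {
  stopifnot(temperature > 0)
  if (mode %in% c("MD", "LD", "SGLD-GLE"))
    return(rep(1, length(E_avg)))
  beta <- 1 / (.kB * temperature)
  expo <- beta * (mu - balanced_force_factor(lambda)) * (E_avg - E_avg2)
  if (any(abs(expo) > 700)) {
    warning("weight exponent clipped at |700|; weights are degenerate")
    expo <- pmin(pmax(expo, -700), 700)
  }
  exp(expo)
}

#' Weighted (reweighted) ensemble average
#'
#' mean = sum(w P) / sum(w), with the effective sample size
#' (sum w)^2 / sum(w^2) reported so weight degeneracy is visible.
#'
#' @param values Per-frame property values.
#' @param weights Per-frame weights, >= 0 with a positive sum.
#' @return List with `mean`, `weights_sum` and `effective_sample_size`.
#' @export
reweighted_average <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sum(weights)
  if (sw == 0) stop("all weights vanished (sum of weights is zero)")
  list(mean = sum(weights * values) / sw, weights_sum = sw,
       effective_sample_size = sw^2 / sum(weights^2))
}

#' Low-frequency temperature
#'
#' The kinetic temperature carried by the local-average momenta:
#' T_lf = (1 / (NDF kB)) sum_i p_tilde_i^2 / m_i.  Because the local average
#' filters out high-frequency kinetic content, T_lf is well below T even
#' without guiding; its zero-guiding value T_lf0 is the calibration point
#' for the self-guiding temperature.
#'
#' @param p_tilde n x 3 matrix of local-average momenta (amu*A/ps).
#' @param masses Per-atom masses (amu).
#' @param ndf Degrees of freedom (> 0); 3n for unconstrained atoms.
#' @return Temperature in K.
#' @export
low_frequency_temperature <- function(p_tilde, masses, ndf) {
  stopifnot(ndf > 0)
  p_tilde <- rbind(p_tilde)
  m <- rep_len(masses, nrow(p_tilde))
  sum(rowSums(p_tilde^2) / m) / (ndf * .kB_int)
}

#' Self-guiding temperature
#'
#' Quantifies the conformational-search power of a self-guided stage:
#' \deqn{T_{SG} = \frac{\tilde T (T - \tilde T_0)}{\tilde T_0 (T - \tilde T)} T.}
#' With no guiding (T_lf = T_lf0) this is exactly T; positive momentum
#' guiding raises T_lf and hence T_SG above T.
#'
#' @param temperature Thermostat temperature T (K).
#' @param T_lf Measured low-frequency temperature (K), in (0, T).
#' @param T_lf0 Zero-guiding low-frequency temperature (K), in (0, T);
#'   see [calibrate_low_frequency_temperature()].
#' @return T_SG in K.
#' @export
self_guiding_temperature <- function(temperature, T_lf, T_lf0) {
  stopifnot(T_lf0 > 0, T_lf0 < temperature)
  if (any(T_lf >= temperature) || any(T_lf <= 0))
    stop("T_lf must lie strictly between 0 and T ",
         "(T_lf >= T indicates a mis-set t_L or dt)")
  T_lf * (temperature - T_lf0) / (T_lf0 * (temperature - T_lf)) * temperature
}

.tlf0_cache <- new.env(parent = emptyenv())

#' Calibrate the zero-guiding low-frequency temperature
#'
#' T_lf0 is defined as the low-frequency temperature with no guiding forces;
#' it is obtained here from a companion run of the same system, temperature,
#' friction and t_L with lambda = mu = 0, and cached per configuration
#' signature.
#'
#' @param system An `sg_system`.
#' @param config An [sg_config()]; its guiding mode is replaced by the
#'   zero-guiding baseline ("LD" when gamma > 0, else "MD").
#' @param positions,velocities Optional initial conditions.
#' @param n_steps Length of the calibration run (defaults to the config's).
#' @return Mean T_lf (K) over the post-warm-up frames.
#' @export
calibrate_low_frequency_temperature <- function(system, config,
                                                positions = NULL,
                                                velocities = NULL,
                                                n_steps = config$n_steps) {
  g <- config$guiding
  key <- paste(system$potential, system$n_atoms,
               paste(signif(system$pot_params, 10), collapse = ","),
               config$temperature, g$gamma, g$t_L, config$dt, n_steps,
               config$seed, sep = "|")
  if (!is.null(.tlf0_cache[[key]])) return(.tlf0_cache[[key]])
  base_mode <- if (g$gamma > 0) "LD" else "MD"
  cfg0 <- sg_config(n_steps = n_steps, dt = config$dt,
                    temperature = config$temperature,
                    guiding = guiding_params(base_mode, t_L = g$t_L,
                                             t_avg = g$t_avg,
                                             gamma = g$gamma),
                    seed = config$seed, record_every = config$record_every,
                    warmup = config$warmup)
  run <- run_simulation(system, cfg0, positions, velocities)
  fr <- run$frames
  warm <- fr[fr$t - fr$t[1] >= config$warmup, , drop = FALSE]
  val <- mean(warm$T_lf)
  .tlf0_cache[[key]] <- val
  val
}

#' Standard error from block averages
#'
#' Correlation-aware standard error of the mean of a stationary series:
#' the series is cut into `n_blocks` contiguous blocks and the SE of the
#' block means is returned.  Blocks longer than the autocorrelation time
#' make the estimate unbiased.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 50).
#' @return Standard error of `mean(x)`.
#' @export
block_se <- function(x, n_blocks = 50) {
  n <- length(x)
  if (n < 2 * n_blocks) n_blocks <- max(2, n %/% 2)
  block <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  bm <- tapply(x, block, mean)
  sd(bm) / sqrt(length(bm))
}
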