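# Replica-exchanging self-guided Langevin dynamics (RXSGLD) and its
# temperature-ladder counterpart (TRXLD): stage ladders, the
# frequency-separated diagnostic factors, the legacy and generalized
# exchange probabilities, Metropolis swaps and bookkeeping.

#' Define a replica-exchange stage ladder
#'
#' Each stage is a simulation condition (T, lambda, mu).  Stage 1 (index 0)
#' is the base stage with the condition of interest; the recommended ladder
#' keeps all temperatures equal and increases the guiding factors, so that
#' conformational distributions overlap strongly between neighbours.
#'
#' @param temperature Per-stage temperatures (K), recycled.
#' @param lambda,mu Per-stage guiding factors, recycled.
#' @return A data frame of class `sg_stages` with columns `stage`,
#'   `temperature`, `lambda`, `mu`.
#' @export
stage_ladder <- function(temperature, lambda = 0, mu = 0) {
  k <- max(length(temperature), length(lambda), length(mu))
  if (k < 2) stop("a ladder needs at least 2 stages")
  out <- data.frame(stage = seq_len(k) - 1L,
                    temperature = rep_len(temperature, k),
                    lambda = rep_len(lambda, k), mu = rep_len(mu, k))
  if (out$lambda[1] != 0 || out$mu[1] != 0)
    warning("base stage (index 0) normally has lambda = mu = 0")
  if (length(unique(out$temperature)) > 1)
    warning("unequal stage temperatures: the legacy exchange probability ",
            "is only approximate, and swapped momenta are not rescaled")
  class(out) <- c("sg_stages", "data.frame")
  out
}

#' Frequency-separated energy and collision factors
#'
#' The diagnostic factors of the legacy SGLD partition function.  The energy
#' factors are average projections of the total force on the interaction
#' force, split into low- and high-frequency parts:
#' lambda_lf = sum((f_avg + g_avg - gamma p_avg) . f_avg) / sum(f_avg . f_avg),
#' and analogously for the high-frequency components (f - f_avg etc.).  The
#' collision factors project the guiding force on the friction force:
#' chi_lf = 1 - sum(g_avg . gamma p_avg) / sum(gamma^2 p_avg . p_avg), and
#' chi_hf likewise from the high-frequency components, whose numerator and
#' denominator should be long-time averages (pass them via `chf_num`/
#' `chf_den` when accumulated over a run).  With zero guiding both chi
#' factors are exactly 1.  Degenerate (cold-start) denominators return 1
#' with a warning.
#'
#' @param f,f_avg Interaction force and its local average (n x 3).
#' @param g,g_avg Guiding force and its local average (n x 3).
#' @param p,p_avg Momentum and local-average momentum (n x 3).
#' @param gamma Friction constant, scalar or per-atom (1/ps).
#' @param chf_num,chf_den Optional long-time-averaged numerator/denominator
#'   for chi_hf; instantaneous sums are used when omitted.
#' @return List with `lambda_lf`, `lambda_hf`, `chi_lf`, `chi_hf`.
#' @export
frequency_factors <- function(f, f_avg, g, g_avg, p, p_avg, gamma,
                              chf_num = NULL, chf_den = NULL) {
  f <- rbind(f); f_avg <- rbind(f_avg); g <- rbind(g); g_avg <- rbind(g_avg)
  p <- rbind(p); p_avg <- rbind(p_avg)
  gam <- rep_len(gamma, nrow(f))
  ratio1 <- function(num, den, what, fallback) {
    if (abs(den) < 1e-30) {
      warning("degenerate denominator for ", what, "; factor defaults to 1")
      return(fallback)
    }
    num / den
  }
  fh <- f - f_avg; gh <- g - g_avg; ph <- p - p_avg
  lambda_lf <- ratio1(sum((f_avg + g_avg - gam * p_avg) * f_avg),
                      sum(f_avg^2), "lambda_lf", 1)
  lambda_hf <- ratio1(sum((fh + gh - gam * ph) * fh), sum(fh^2),
                      "lambda_hf", 1)
  # for the chi factors a degenerate denominator must leave the factor at 1
  chi_lf <- 1 - ratio1(sum(g_avg * gam * p_avg), sum(gam^2 * p_avg^2),
                       "chi_lf", 0)
  if (is.null(chf_num)) chf_num <- sum(gam * gh * ph)
  if (is.null(chf_den)) chf_den <- sum(gam^2 * ph^2)
  chi_hf <- 1 - ratio1(chf_num, chf_den, "chi_hf", 0)
  list(lambda_lf = lambda_lf, lambda_hf = lambda_hf, chi_lf = chi_lf,
       chi_hf = chi_hf)
}

#' Stage exchange coefficients (legacy criterion)
#'
#' l_m = (lambda_lf chi_lf - lambda_hf chi_hf) / (kB T_m) and
#' h_m = lambda_hf chi_hf / (kB T_m), the low- and high-frequency exchange
#' coefficients entering the legacy exchange probability.  With no guiding
#' (all factors 1), l_m = 0 and h_m = beta_m.
#'
#' @param temperature Stage temperature (K).
#' @param factors A list as returned by [frequency_factors()].
#' @return List with `l` and `h` (mol/kcal).
#' @export
exchange_coefficients <- function(temperature, factors) {
  stopifnot(temperature > 0)
  kT <- .kB * temperature
  lf <- factors$lambda_lf * factors$chi_lf
  hf <- factors$lambda_hf * factors$chi_hf
  list(l = (lf - hf) / kT, h = hf / kT)
}

#' Legacy replica-exchange probability
#'
#' Exchange probability between replica i on stage m and replica j on stage
#' n from the legacy partition function, using the equal-temperature
#' approximation that a conformation's low-frequency energy is
#' stage-independent:
#' ratio = exp(-(l_m - l_n)(E_avg_j - E_avg_i) - (h_m - h_n)(E_p_j - E_p_i)).
#'
#' @param E_i,E_avg_i Potential energy and its local average for replica i
#'   (on stage m), kcal/mol.
#' @param E_j,E_avg_j Same for replica j (on stage n).
#' @param coef_m,coef_n Stage coefficients from [exchange_coefficients()].
#' @return List with `prob` = min(1, ratio) and the raw `ratio` (whose
#'   product with the reverse move's ratio is exactly 1).
#' @export
exchange_probability_legacy <- function(E_i, E_avg_i, E_j, E_avg_j,
                                        coef_m, coef_n) {
  expo <- -(coef_m$l - coef_n$l) * (E_avg_j - E_avg_i) -
    (coef_m$h - coef_n$h) * (E_j - E_i)
  ratio <- exp(expo)
  list(prob = min(1, ratio), ratio = ratio)
}

#' Generalized replica-exchange probability
#'
#' The exchange criterion of the generalized SG ensemble, which needs only
#' the per-frame energies and the stage parameters (no frequency factors):
#' \deqn{ratio = \exp\{(\beta_m - \beta_n)(E_i - E_j) +
#'   [\beta_m(\mu_m - \hat\mu_m) - \beta_n(\mu_n - \hat\mu_n)]
#'   [(\tilde E_i - \tilde{\tilde E}_i) - (\tilde E_j - \tilde{\tilde E}_j)]\}}
#' with hat-mu the balanced force factor of each stage's lambda.  Equal-T
#' ladders of balanced stages accept every attempt.
#'
#' @param E_i,E_avg_i,E_avg2_i Energies of replica i (on stage m), kcal/mol.
#' @param E_j,E_avg_j,E_avg2_j Energies of replica j (on stage n).
#' @param stage_m,stage_n Lists/rows with `temperature`, `lambda`, `mu`.
#' @return List with `prob` and raw `ratio`.
#' @export
exchange_probability_generalized <- function(E_i, E_avg_i, E_avg2_i,
                                             E_j, E_avg_j, E_avg2_j,
                                             stage_m, stage_n) {
  beta_m <- 1 / (.kB * stage_m$temperature)
  beta_n <- 1 / (.kB * stage_n$temperature)
  am <- beta_m * (stage_m$mu - balanced_force_factor(stage_m$lambda))
  an <- beta_n * (stage_n$mu - balanced_force_factor(stage_n$lambda))
  expo <- (beta_m - beta_n) * (E_i - E_j) +
    (am - an) * ((E_avg_i - E_avg2_i) - (E_avg_j - E_avg2_j))
  ratio <- exp(expo)
  list(prob = min(1, ratio), ratio = ratio)
}

#' Attempt a Metropolis stage exchange between two replicas
#'
#' Computes the exchange probability in the requested mode and accepts with
#' Metropolis probability min(1, ratio); on acceptance the two replicas swap
#' their stage assignments (their momenta are kept — equal-temperature
#' ladders need no rescaling).  A same-stage pair is rejected with a
#' warning.
#'
#' @param rep_i,rep_j Replica records: lists with `stage` (a stage row or
#'   list with `stage`, `temperature`, `lambda`, `mu`), `E_p`, `E_avg`,
#'   `E_avg2`, and for legacy mode `coef` from [exchange_coefficients()].
#' @param mode "generalized" (default) or "legacy".
#' @return List with `accepted`, `prob`, `ratio`, and the (possibly swapped)
#'   `rep_i`, `rep_j`.
#' @export
attempt_exchange <- function(rep_i, rep_j,
                             mode = c("generalized", "legacy")) {
  mode <- match.arg(mode)
  if (identical(rep_i$stage$stage, rep_j$stage$stage)) {
    warning("same-stage pair: exchange attempt rejected")
    return(list(accepted = FALSE, prob = 0, ratio = NA_real_,
                rep_i = rep_i, rep_j = rep_j))
  }
  pr <- if (mode == "legacy") {
    exchange_probability_legacy(rep_i$E_p, rep_i$E_avg, rep_j$E_p,
                                rep_j$E_avg, rep_i$coef, rep_j$coef)
  } else {
    exchange_probability_generalized(rep_i$E_p, rep_i$E_avg, rep_i$E_avg2,
                                     rep_j$E_p, rep_j$E_avg, rep_j$E_avg2,
                                     rep_i$stage, rep_j$stage)
  }
  accepted <- runif(1) < pr$prob
  if (accepted) {
    tmp <- rep_i$stage; rep_i$stage <- rep_j$stage; rep_j$stage <- tmp
    if (mode == "legacy") {
      tmp <- rep_i$coef; rep_i$coef <- rep_j$coef; rep_j$coef <- tmp
    }
  }
  list(accepted = accepted, prob = pr$prob, ratio = pr$ratio,
       rep_i = rep_i, rep_j = rep_j)
}

#' Run a replica-exchanging self-guided simulation
#'
#' Interleaves dynamics segments with Metropolis stage exchanges.  Each
#' replica carries its own dynamics state (local averages and friction
#' accumulators continue across swaps); a swap exchanges only the stage
#' assignment — guiding factors and thermostat target — of the two
#' replicas.  Exchange partners follow the alternating even/odd
#' adjacent-stage schedule standard in replica-exchange practice (random
#' adjacent pairing is available as an option).
#'
#' @param system An `sg_system`.
#' @param stages A [stage_ladder()].
#' @param config An [sg_config()]; its `n_steps` is ignored in favour of
#'   `n_cycles * exchange_interval`, and its guiding mode is used for every
#'   stage (stage rows override lambda, mu and temperature).
#' @param n_cycles Number of dynamics/exchange cycles.
#' @param exchange_interval Steps of dynamics between exchange attempts.
#' @param replicas_per_stage Replicas initially on each stage.
#' @param prob_mode "generalized" (default) or "legacy" (which derives each
#'   stage's coefficients from the run's frequency-factor diagnostics).
#' @param pairing "deterministic" (alternating even/odd) or "random"
#'   (one random adjacent stage pair per cycle).
#' @param positions,velocities Optional shared initial conditions.
#' @return An object of class `rxsgld`: `acceptance` (per stage pair:
#'   attempts, acceptances, ratio), `stage_trace` (replicas x cycles stage
#'   assignments over time), `frames` (per-replica per-cycle records with
#'   stage labels; base-stage rows are canonical-ensemble material) and the
#'   final `replicas`.
#' @export
run_rxsgld <- function(system, stages, config, n_cycles, exchange_interval,
                       replicas_per_stage = 1,
                       prob_mode = c("generalized", "legacy"),
                       pairing = c("deterministic", "random"),
                       positions = NULL, velocities = NULL) {
  prob_mode <- match.arg(prob_mode)
  pairing <- match.arg(pairing)
  stopifnot(inherits(stages, "sg_stages"), n_cycles >= 1,
            exchange_interval >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- nrow(stages)
  n_rep <- k * replicas_per_stage
  if (is.null(positions)) positions <- .default_positions(system)

  replicas <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    st <- stages[((i - 1L) %% k) + 1L, ]
    v0 <- if (is.null(velocities))
      maxwell_velocities(system$masses, st$temperature) else velocities
    replicas[[i]] <- list(id = i, stage = st, positions = positions,
                          velocities = v0, state = NULL,
                          E_p = NA, E_avg = NA, E_avg2 = NA, coef = NULL)
  }

  pair_counts <- new.env(parent = emptyenv())
  bump <- function(s1, s2, acc) {
    key <- paste(sort(c(s1, s2)), collapse = "-")
    cur <- pair_counts[[key]]
    if (is.null(cur)) cur <- c(0L, 0L)
    pair_counts[[key]] <- cur + c(1L, as.integer(acc))
  }

  stage_trace <- matrix(NA_integer_, n_rep, n_cycles + 1L)
  stage_trace[, 1] <- vapply(replicas, function(r) r$stage$stage, integer(1))
  frames_list <- vector("list", n_cycles)

  cfg_seg <- config
  cfg_seg$seed <- NULL # RNG stream continues across segments
  cfg_seg$n_steps <- as.integer(exchange_interval)
  cfg_seg$record_every <- as.integer(exchange_interval)

  for (cycle in seq_len(n_cycles)) {
    recs <- vector("list", n_rep)
    for (i in seq_len(n_rep)) {
      rep_i <- replicas[[i]]
      st <- rep_i$stage
      cfg_seg$temperature <- st$temperature
      g <- config$guiding
      cfg_seg$guiding <- guiding_params(g$mode, lambda = st$lambda,
                                        mu = st$mu, t_L = g$t_L,
                                        t_avg = g$t_avg, gamma = g$gamma)
      seg <- run_simulation(system, cfg_seg, rep_i$positions,
                            rep_i$velocities, rep_i$state)
      last <- seg$frames[nrow(seg$frames), ]
      rep_i$positions <- seg$positions
      rep_i$velocities <- seg$velocities
      rep_i$state <- seg$state
      rep_i$E_p <- last$E_p; rep_i$E_avg <- last$E_avg
      rep_i$E_avg2 <- last$E_avg2
      if (prob_mode == "legacy")
        rep_i$coef <- exchange_coefficients(
          st$temperature,
          list(lambda_lf = last$lambda_lf, lambda_hf = last$lambda_hf,
               chi_lf = last$chi_lf, chi_hf = last$chi_hf))
      replicas[[i]] <- rep_i
      recs[[i]] <- data.frame(cycle = cycle, replica = i,
                              stage = st$stage, t = last$t, E_p = last$E_p,
                              E_avg = last$E_avg, E_avg2 = last$E_avg2,
                              T_kin = last$T_kin, T_lf = last$T_lf)
    }
    frames_list[[cycle]] <- do.call(rbind, recs)

    # exchange attempts between adjacent stages
    cur_stage <- vapply(replicas, function(r) r$stage$stage, integer(1))
    pairs <- if (pairing == "deterministic") {
      lo <- if (cycle %% 2 == 1 || k == 2) seq(0, k - 2, by = 2) else
        seq(1, k - 2, by = 2)
      lapply(lo[lo <= k - 2], function(s) c(s, s + 1))
    } else {
      s <- sample(0:(k - 2), 1)
      list(c(s, s + 1))
    }
    for (p in pairs) {
      cand_i <- which(cur_stage == p[1])
      cand_j <- which(cur_stage == p[2])
      if (!length(cand_i) || !length(cand_j)) next
      i <- if (length(cand_i) > 1) sample(cand_i, 1) else cand_i
      j <- if (length(cand_j) > 1) sample(cand_j, 1) else cand_j
      res <- attempt_exchange(replicas[[i]], replicas[[j]], prob_mode)
      replicas[[i]] <- res$rep_i
      replicas[[j]] <- res$rep_j
      bump(p[1], p[2], res$accepted)
      cur_stage <- vapply(replicas, function(r) r$stage$stage, integer(1))
    }
    stage_trace[, cycle + 1L] <- cur_stage
  }

  keys <- ls(pair_counts)
  acceptance <- do.call(rbind, lapply(keys, function(kk) {
    ct <- pair_counts[[kk]]
    ss <- as.integer(strsplit(kk, "-")[[1]])
    data.frame(stage_lo = ss[1], stage_hi = ss[2], attempts = ct[1],
               acceptances = ct[2], ratio = ct[2] / ct[1])
  }))
  acceptance <- acceptance[order(acceptance$stage_lo), , drop = FALSE]

  structure(list(acceptance = acceptance, stage_trace = stage_trace,
                 frames = do.call(rbind, frames_list), replicas = replicas,
                 stages = stages, config = config,
                 exchange_interval = exchange_interval),
            class = "rxsgld")
}

#' @export
print.rxsgld <- function(x, ...) {
  cat("<rxsgld> ", nrow(x$stage_trace), " replicas on ", nrow(x$stages),
      " stages, ", ncol(x$stage_trace) - 1L, " cycles of ",
      x$exchange_interval, " steps\n", sep = "")
  cat("  acceptance by stage pair:\n")
  print(x$acceptance, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rxsgld <- function(object, ...) {
  base <- object$frames[object$frames$stage == 0, , drop = FALSE]
  list(mean_acceptance = sum(object$acceptance$acceptances) /
         sum(object$acceptance$attempts),
       acceptance = object$acceptance,
       base_E_p_mean = mean(base$E_p),
       stages_visited_by_replica =
         apply(object$stage_trace, 1, function(z) length(unique(z))))
}
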