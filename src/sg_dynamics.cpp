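// Core leap-frog integrators for self-guided molecular / Langevin dynamics.
//
// Internal unit system: Angstrom, picosecond, amu.  Energies inside the
// integrator are amu A^2/ps^2 (1 kcal/mol = 418.4 of these); potential
// energies are reported to R in kcal/mol.  All random numbers come from R's
// RNG (norm_rand), drawn in a fixed per-step, per-atom, per-component order
// so trajectories are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const double FCONV = 418.4;           // kcal/mol -> amu A^2/ps^2
static const double KB = 0.0019872041;       // kcal/mol/K
static const double KB_INT = KB * FCONV;     // amu A^2/ps^2/K
static const double PP_GUARD = 1e-12;        // PP below this -> xi = 0
static const double DEN_GUARD = 1e-30;       // p0 ~ 0 guard for eta

enum Mode { MODE_MD = 0, MODE_LD = 1, MODE_SGMD = 2, MODE_SGLD = 3, MODE_GLE = 4 };
enum Pot { POT_HARMONIC = 0, POT_SDW = 1, POT_LJ = 2 };

// ---------------------------------------------------------------------------
// potentials: positions in A, energy in kcal/mol, forces in kcal/mol/A
// ---------------------------------------------------------------------------

static double harmonic_ef(const std::vector<double>& r, int n, double k,
                          std::vector<double>& f) {
  double e = 0.0;
  for (int i = 0; i < 3 * n; ++i) {
    e += 0.5 * k * r[i] * r[i];
    f[i] = -k * r[i];
  }
  return e;
}

static double sdw_ef(const std::vector<double>& r, int n, double a, double b,
                     double c, double y0, std::vector<double>& f) {
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = r[3 * i], y = r[3 * i + 1], z = r[3 * i + 2];
    double y2 = y * y;
    e += a * y2 * (y2 - 2.0 * y0 * y0) + b * (y + y0) * (y + y0) +
         c * (x * x + z * z);
    f[3 * i]     = -2.0 * c * x;
    f[3 * i + 1] = -(4.0 * a * y * (y2 - y0 * y0) + 2.0 * b * (y + y0));
    f[3 * i + 2] = -2.0 * c * z;
  }
  return e;
}

// truncated, energy-shifted Lennard-Jones with minimum-image convention
static double lj_ef(const std::vector<double>& r, int n, double eps,
                    double sigma, double rcut, double box,
                    std::vector<double>& f, bool* overlap) {
  double e = 0.0;
  const double rc2 = rcut * rcut;
  const double sr6c = std::pow(sigma * sigma / rc2, 3.0);
  const double eshift = 4.0 * eps * (sr6c * sr6c - sr6c); // value at cutoff
  std::fill(f.begin(), f.end(), 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = r[3 * i] - r[3 * j];
      double dy = r[3 * i + 1] - r[3 * j + 1];
      double dz = r[3 * i + 2] - r[3 * j + 2];
      dx -= box * std::nearbyint(dx / box);
      dy -= box * std::nearbyint(dy / box);
      dz -= box * std::nearbyint(dz / box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (r2 < 0.01) *overlap = true;
      double sr2 = sigma * sigma / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      e += 4.0 * eps * (sr12 - sr6) - eshift;
      double fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2; // (1/r)(dU/dr) * -1
      f[3 * i] += fr * dx;  f[3 * j] -= fr * dx;
      f[3 * i + 1] += fr * dy;  f[3 * j + 1] -= fr * dy;
      f[3 * i + 2] += fr * dz;  f[3 * j + 2] -= fr * dz;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".potential_ef_cpp")]]
List potential_ef_cpp(NumericMatrix pos, int potential, NumericVector pot_params,
                      double box) {
  int n = pos.nrow();
  std::vector<double> r(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) r[3 * i + d] = pos(i, d);
  bool overlap = false;
  double e;
  if (potential == POT_HARMONIC) {
    e = harmonic_ef(r, n, pot_params[0], f);
  } else if (potential == POT_SDW) {
    e = sdw_ef(r, n, pot_params[0], pot_params[1], pot_params[2], pot_params[3], f);
  } else {
    e = lj_ef(r, n, pot_params[0], pot_params[1], pot_params[2], box, f, &overlap);
  }
  NumericMatrix fo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fo(i, d) = f[3 * i + d];
  return List::create(_["energy"] = e, _["forces"] = fo,
                      _["overlap"] = overlap);
}

// ---------------------------------------------------------------------------
// the generalized self-guided leap-frog driver
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sg_run_cpp")]]
List sg_run_cpp(NumericMatrix r0, NumericMatrix v0, NumericVector mass,
                int potential, NumericVector pot_params, double box,
                int mode, double dt, int n_steps, double temperature,
                double gamma, double lambda, double mu, double tL,
                double tavg, bool use_eta, int record_every,
                bool record_positions, bool record_velocities,
                Nullable<List> init_state) {
  const int n = r0.nrow();
  const int nc = 3 * n;
  std::vector<double> r(nc), v(nc), m(n);
  for (int i = 0; i < n; ++i) {
    m[i] = mass[i];
    for (int d = 0; d < 3; ++d) {
      r[3 * i + d] = r0(i, d);
      v[3 * i + d] = v0(i, d);
    }
  }

  const double a_L = dt / tL;       // local-average weight
  const double a_A = dt / tavg;     // long-average weight
  const bool stochastic = (mode == MODE_LD || mode == MODE_SGLD || mode == MODE_GLE);
  const bool self_guided = (mode == MODE_SGMD || mode == MODE_SGLD || mode == MODE_GLE);
  const double nu = (mode == MODE_GLE) ? 1.0 - std::sqrt(1.0 - lambda) : 0.0;
  const double kT_int = KB_INT * temperature;

  // state arrays (internal units)
  std::vector<double> r_avg(nc), r_avg2(nc), p_avg_prev(nc, 0.0), R_avg(nc, 0.0);
  std::vector<double> f_avg(nc, 0.0), g_avg(nc, 0.0);
  std::vector<double> FP(n, 0.0), PP(n, 0.0);
  double E_avg, E_avg2, t0 = 0.0;
  // long-time accumulators for frequency-separated factors
  double llf_num = 0.0, llf_den = 0.0, lhf_num = 0.0, lhf_den = 0.0;
  double clf_num = 0.0, clf_den = 0.0, chf_num = 0.0, chf_den = 0.0;
  int eta_guard_hits = 0;

  // work arrays
  std::vector<double> f_int(nc), f(nc), Rv(nc, 0.0), g(nc, 0.0);
  std::vector<double> ptil(nc), pfull(nc), Ftil(nc), Ftil2(nc);

  bool overlap = false;
  double E_p; // kcal/mol

  auto eval_pot = [&](void) -> double {
    if (potential == POT_HARMONIC) return harmonic_ef(r, n, pot_params[0], f_int);
    if (potential == POT_SDW)
      return sdw_ef(r, n, pot_params[0], pot_params[1], pot_params[2],
                    pot_params[3], f_int);
    return lj_ef(r, n, pot_params[0], pot_params[1], pot_params[2], box,
                 f_int, &overlap);
  };

  E_p = eval_pot();
  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector ra = st["r_avg"], ra2 = st["r_avg2"], pp = st["p_avg_prev"];
    NumericVector Ra = st["R_avg"], fa = st["f_avg"], ga = st["g_avg"];
    NumericVector fp = st["FP"], ppv = st["PP"];
    for (int i = 0; i < nc; ++i) {
      r_avg[i] = ra[i]; r_avg2[i] = ra2[i]; p_avg_prev[i] = pp[i];
      R_avg[i] = Ra[i]; f_avg[i] = fa[i]; g_avg[i] = ga[i];
    }
    for (int i = 0; i < n; ++i) { FP[i] = fp[i]; PP[i] = ppv[i]; }
    E_avg = as<double>(st["E_avg"]);
    E_avg2 = as<double>(st["E_avg2"]);
    t0 = as<double>(st["t"]);
    NumericVector acc = st["factor_acc"];
    llf_num = acc[0]; llf_den = acc[1]; lhf_num = acc[2]; lhf_den = acc[3];
    clf_num = acc[4]; clf_den = acc[5]; chf_num = acc[6]; chf_den = acc[7];
  } else {
    // cold start: local averages equal current values, accumulators zero
    for (int i = 0; i < nc; ++i) { r_avg[i] = r[i]; r_avg2[i] = r[i]; }
    E_avg = E_p; E_avg2 = E_p;
  }

  // recording layout
  const int n_frames = 1 + (record_every > 0 ? n_steps / record_every : 0);
  const int NCOL = 12;
  NumericMatrix frames(n_frames, NCOL);
  NumericVector pos_traj(record_positions ? (R_xlen_t)n_frames * nc : 0);
  NumericVector vel_traj(record_velocities ? (R_xlen_t)n_frames * nc : 0);
  int frame_i = 0;

  const double noise_sd_base = std::sqrt(2.0 * gamma * kT_int / dt);

  auto record_frame = [&](double tnow, double KE_int, double Tlf_num) {
    double Tkin = (nc > 0) ? 2.0 * KE_int / (nc * KB_INT) : 0.0;
    double Tlf = Tlf_num / (nc * KB_INT);
    double xi_mean = 0.0;
    for (int i = 0; i < n; ++i)
      xi_mean += (PP[i] > PP_GUARD) ? -FP[i] / PP[i] : 0.0;
    xi_mean /= n;
    double llf = (llf_den > DEN_GUARD) ? llf_num / llf_den : 1.0;
    double lhf = (lhf_den > DEN_GUARD) ? lhf_num / lhf_den : 1.0;
    double clf = (clf_den > DEN_GUARD) ? 1.0 - clf_num / clf_den : 1.0;
    double chf = (chf_den > DEN_GUARD) ? 1.0 - chf_num / chf_den : 1.0;
    frames(frame_i, 0) = tnow;
    frames(frame_i, 1) = E_p;
    frames(frame_i, 2) = E_avg;
    frames(frame_i, 3) = E_avg2;
    frames(frame_i, 4) = Tkin;
    frames(frame_i, 5) = Tlf;
    frames(frame_i, 6) = xi_mean;
    frames(frame_i, 7) = E_p + KE_int / FCONV; // total energy, kcal/mol
    frames(frame_i, 8) = llf;
    frames(frame_i, 9) = lhf;
    frames(frame_i, 10) = clf;
    frames(frame_i, 11) = chf;
    if (record_positions)
      for (int i = 0; i < nc; ++i) pos_traj[(R_xlen_t)frame_i * nc + i] = r[i];
    if (record_velocities)
      for (int i = 0; i < nc; ++i) vel_traj[(R_xlen_t)frame_i * nc + i] = v[i];
    ++frame_i;
  };

  // initial frame (KE from the incoming half-step velocities; p~ from state)
  {
    double KE = 0.0, Tlf_num = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        double vv = v[3 * i + d];
        KE += 0.5 * m[i] * vv * vv;
        double pt = m[i] / tL * (r[3 * i + d] - r_avg[3 * i + d]);
        Tlf_num += pt * pt / m[i];
      }
    }
    record_frame(t0, KE, Tlf_num);
  }

  RNGScope rng_scope;

  for (int step = 0; step < n_steps; ++step) {
    // (1) energy and interaction forces at r(t); convert to internal units
    E_p = eval_pot();
    for (int i = 0; i < nc; ++i) f[i] = f_int[i] * FCONV;
    if (!std::isfinite(E_p))
      stop("non-finite potential energy at t = %g ps", t0 + step * dt);

    // random forces (LD / SGLD / SGLD-GLE); fixed draw order
    if (stochastic && gamma > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sd = noise_sd_base * std::sqrt(m[i]);
        for (int d = 0; d < 3; ++d) Rv[3 * i + d] = sd * norm_rand();
      }
      if (mode == MODE_GLE) {
        // colored noise R - nu*R~.  R~ is the exponential local average of
        // the white stream; the current impulse straddles the window
        // boundary and enters with half weight (the delta convention of the
        // memory-kernel derivation), which removes the O(dt/t_L) sampling
        // bias of a full-weight boundary sample.
        for (int i = 0; i < nc; ++i) {
          double r_half = (1.0 - a_L) * R_avg[i] + 0.5 * a_L * Rv[i];
          f[i] += Rv[i] - nu * r_half;
          R_avg[i] = (1.0 - a_L) * R_avg[i] + a_L * Rv[i];
        }
      } else {
        for (int i = 0; i < nc; ++i) f[i] += Rv[i];
      }
    }

    // (2) local averages of energy and positions
    E_avg = (1.0 - a_L) * E_avg + a_L * E_p;
    E_avg2 = (1.0 - a_L) * E_avg2 + a_L * E_avg;
    for (int i = 0; i < nc; ++i) {
      r_avg[i] = (1.0 - a_L) * r_avg[i] + a_L * r[i];
      r_avg2[i] = (1.0 - a_L) * r_avg2[i] + a_L * r_avg[i];
    }
    // derived low-frequency quantities
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        int k = 3 * i + d;
        double pt = m[i] / tL * (r[k] - r_avg[k]);
        ptil[k] = pt;
        pfull[k] = p_avg_prev[k] + tL / dt * (pt - p_avg_prev[k]);
        Ftil[k] = (pfull[k] - pt) / tL;
        Ftil2[k] = m[i] / (tL * tL) * (r[k] - 2.0 * r_avg[k] + r_avg2[k]);
      }
    }

    // (3) apparent friction constants (long-time averages FP, PP)
    if (self_guided) {
      for (int i = 0; i < n; ++i) {
        double fp = 0.0, pp = 0.0;
        for (int d = 0; d < 3; ++d) {
          int k = 3 * i + d;
          fp += (Ftil[k] - Ftil2[k]) * ptil[k];
          pp += ptil[k] * ptil[k];
        }
        FP[i] = (1.0 - a_A) * FP[i] + a_A * fp;
        PP[i] = (1.0 - a_A) * PP[i] + a_A * pp;
      }
    }

    // (4) guiding force
    if (mode == MODE_GLE) {
      for (int i = 0; i < nc; ++i) g[i] = lambda * gamma * ptil[i];
    } else if (self_guided) {
      for (int i = 0; i < n; ++i) {
        double xi = (PP[i] > PP_GUARD) ? -FP[i] / PP[i] : 0.0;
        for (int d = 0; d < 3; ++d) {
          int k = 3 * i + d;
          g[k] = mu * (Ftil[k] - Ftil2[k]) + lambda * xi * ptil[k];
        }
      }
    } else {
      std::fill(g.begin(), g.end(), 0.0);
    }

    // frequency-separated factor accumulators (diagnostics / legacy exchange)
    if (self_guided) {
      double s_llf_n = 0.0, s_llf_d = 0.0, s_lhf_n = 0.0, s_lhf_d = 0.0;
      double s_clf_n = 0.0, s_clf_d = 0.0, s_chf_n = 0.0, s_chf_d = 0.0;
      for (int i = 0; i < nc; ++i) {
        f_avg[i] = (1.0 - a_L) * f_avg[i] + a_L * f[i];
        g_avg[i] = (1.0 - a_L) * g_avg[i] + a_L * g[i];
        double fl = f_avg[i], gl = g_avg[i], pl = ptil[i];
        double fh = f[i] - fl, gh = g[i] - gl, ph = pfull[i] - pl;
        s_llf_n += (fl + gl - gamma * pl) * fl;
        s_llf_d += fl * fl;
        s_lhf_n += (fh + gh - gamma * ph) * fh;
        s_lhf_d += fh * fh;
        s_clf_n += gl * gamma * pl;
        s_clf_d += gamma * gamma * pl * pl;
        s_chf_n += gamma * gh * ph;
        s_chf_d += gamma * gamma * ph * ph;
      }
      llf_num = (1.0 - a_A) * llf_num + a_A * s_llf_n;
      llf_den = (1.0 - a_A) * llf_den + a_A * s_llf_d;
      lhf_num = (1.0 - a_A) * lhf_num + a_A * s_lhf_n;
      lhf_den = (1.0 - a_A) * lhf_den + a_A * s_lhf_d;
      clf_num = (1.0 - a_A) * clf_num + a_A * s_clf_n;
      clf_den = (1.0 - a_A) * clf_den + a_A * s_clf_d;
      chf_num = (1.0 - a_A) * chf_num + a_A * s_chf_n;
      chf_den = (1.0 - a_A) * chf_den + a_A * s_chf_d;
    }

    // (5)-(7) eta, velocity and position updates
    double KE = 0.0, Tlf_num = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      if (use_eta && self_guided && mode != MODE_GLE) {
        double gp0 = 0.0, p0sq = 0.0;
        for (int d = 0; d < 3; ++d) {
          int k = 3 * i + d;
          double p0 = m[i] * v[k] + (f[k] + g[k] - gamma * m[i] * v[k]) * dt / 2.0;
          gp0 += g[k] * p0;
          p0sq += p0 * p0;
        }
        if (gp0 != 0.0) {
          double den = 2.0 * p0sq - gp0 * dt;
          if (std::fabs(den) > DEN_GUARD) {
            eta = (2.0 + gamma * dt) * gp0 / den;
          } else {
            ++eta_guard_hits;
          }
        }
      }
      double c = (gamma + eta) * dt / 2.0;
      for (int d = 0; d < 3; ++d) {
        int k = 3 * i + d;
        double v_old = v[k];
        v[k] = ((1.0 - c) * v_old + (f[k] + g[k]) * dt / m[i]) / (1.0 + c);
        r[k] += v[k] * dt;
        KE += 0.25 * m[i] * (v_old * v_old + v[k] * v[k]);
        Tlf_num += ptil[k] * ptil[k] / m[i];
        p_avg_prev[k] = ptil[k];
      }
    }

    if ((step + 1) % record_every == 0 && frame_i < n_frames)
      record_frame(t0 + (step + 1) * dt, KE, Tlf_num);
  }

  // final potential energy at the final positions (also refreshes f_int)
  double E_final = eval_pot();

  NumericMatrix r_out(n, 3), v_out(n, 3);
  NumericVector ra(nc), ra2(nc), pp(nc), Ra(nc), fa(nc), ga(nc);
  NumericVector FPo(n), PPo(n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      r_out(i, d) = r[3 * i + d];
      v_out(i, d) = v[3 * i + d];
    }
  for (int i = 0; i < nc; ++i) {
    ra[i] = r_avg[i]; ra2[i] = r_avg2[i]; pp[i] = p_avg_prev[i];
    Ra[i] = R_avg[i]; fa[i] = f_avg[i]; ga[i] = g_avg[i];
  }
  for (int i = 0; i < n; ++i) { FPo[i] = FP[i]; PPo[i] = PP[i]; }

  List state = List::create(
      _["r_avg"] = ra, _["r_avg2"] = ra2, _["p_avg_prev"] = pp,
      _["R_avg"] = Ra, _["f_avg"] = fa, _["g_avg"] = ga,
      _["FP"] = FPo, _["PP"] = PPo, _["E_avg"] = E_avg, _["E_avg2"] = E_avg2,
      _["t"] = t0 + n_steps * dt,
      _["factor_acc"] = NumericVector::create(llf_num, llf_den, lhf_num,
                                              lhf_den, clf_num, clf_den,
                                              chf_num, chf_den));

  colnames(frames) = CharacterVector::create(
      "t", "E_p", "E_avg", "E_avg2", "T_kin", "T_lf", "xi", "E_tot",
      "lambda_lf", "lambda_hf", "chi_lf", "chi_hf");

  List out = List::create(
      _["frames"] = frames, _["positions"] = r_out, _["velocities"] = v_out,
      _["state"] = state, _["E_p"] = E_final,
      _["eta_guard_hits"] = eta_guard_hits, _["overlap"] = overlap);
  if (record_positions) {
    pos_traj.attr("dim") = IntegerVector::create(3, n, n_frames);
    out["pos_traj"] = pos_traj;
  }
  if (record_velocities) {
    vel_traj.attr("dim") = IntegerVector::create(3, n, n_frames);
    out["vel_traj"] = vel_traj;
  }
  return out;
}
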