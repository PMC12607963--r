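---
title: "Self-guided dynamics: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-guided dynamics: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgld)
```

## The model

Self-guided dynamics rests on one primitive: the exponential local average.
For any trajectory property $P(t)$,

$$\tilde P_t = (1 - \delta t/t_L)\,\tilde P_{t-\delta t}
             + (\delta t/t_L)\,P_t ,$$

a first-order low-pass filter whose time constant $t_L$ sets a frequency
threshold $1/t_L$: motion faster than that is filtered away, slower motion
passes through. The equation of self-guided motion adds two low-frequency
feedback terms to the ordinary (Langevin) force:

$$\dot{\mathbf p} = \mathbf F
  + \lambda\,\xi\,\tilde{\mathbf p}
  + \mu\,(\tilde{\mathbf F} - \tilde{\tilde{\mathbf F}}).$$

The momentum guiding force $\lambda\xi\tilde{\mathbf p}$ pushes each atom
along its own low-frequency drift, countering the friction the environment
exerts on slow motion; $\lambda > 0$ enhances diffusion-controlled search.
The force guiding term $\mu(\tilde F - \tilde{\tilde F})$ acts like a
smoothed energy surface; $\mu < 0$ effectively lowers barriers. The
apparent friction constant $\xi$ is the conversion factor between the two
kinds of guiding, estimated per atom during the run as
$\xi = -\langle(\tilde F - \tilde{\tilde F})\cdot\tilde p\rangle /
\langle\tilde p\cdot\tilde p\rangle$ with the ensemble averages replaced by
long-time exponential averages (time constant $t_\mathrm{avg}$).

Everything low-frequency is derived from two stored arrays — the
local-average positions $\tilde r$ and their local averages
$\tilde{\tilde r}$:
$\tilde p = (m/t_L)(r - \tilde r)$;
$p = \tilde p_{t-\delta t} + (t_L/\delta t)(\tilde p - \tilde p_{t-\delta t})$;
$\tilde F = (p - \tilde p)/t_L$;
$\tilde{\tilde F} = (m/t_L^2)(r - 2\tilde r + \tilde{\tilde r})$.
Each atom updates independently, so the overhead per step is a handful of
array operations.

### Ensemble theory and reweighting

The bias the guiding forces exert on the conformational distribution lives
entirely on the low-frequency energy surface
$\Delta = \tilde E_p - \tilde{\tilde E}_p$. The momentum guiding force at
factor $\lambda$ biases exactly as a force guiding factor $-\mu_\lambda$
would, where $\mu_\lambda$ solves the balance relation

$$\lambda = (1+\mu)^2 - \frac{1}{1+\mu},$$

i.e. $u = 1 + \mu_\lambda$ is the unique positive real root of
$u^3 - \lambda u - 1 = 0$ (real for
$\lambda \le (27/4)^{1/3} \approx 1.89$). The two reference points are
$\mu_\lambda(1) = +0.3247$ and $\mu_\lambda(-1) = -0.3177$; the usable
working range $\lambda = -1\ldots1$ corresponds, in *equivalent
enhancement*, to $\mu = +0.3177\ldots-0.3247$ (the opposite sign, exposed
as `equivalent_force_factor()`). A guided run samples
$\propto \exp[-\beta(E_p + (\mu-\mu_\lambda)\Delta)]$, so the per-frame
weight

$$w = \exp\!\big[+\beta\,(\mu - \mu_\lambda)\,\Delta\big]$$

recovers canonical averages, and at balanced guiding ($\mu = \mu_\lambda$)
the run is canonical outright with $w \equiv 1$. Two empirical checks pin
this sign convention down, both run routinely in the test suite: (i) SDW
runs at $(\lambda = \pm 1, \mu_\lambda)$ give unweighted $\langle E_p\rangle$
within one standard error of plain LD, and (ii) reweighting a
$(\lambda = 1, \mu = 0)$ run moves its (raised) mean energy back onto the
LD value — with the opposite sign it moves it further away. The weight
exponent is clipped at $|700|$ with a warning; clipping indicates weight
degeneracy, which the reported effective sample size
$(\sum w)^2/\sum w^2$ makes visible.

A subtlety worth recording: with the on-the-fly $\xi$ (which fluctuates
around its long-time mean), the realized bias surface is only approximately
the ideal $(\mu-\mu_\lambda)\Delta$. At high precision (five seeds × 4 ns
on the double well) the ideal-surface weight overcorrects the guiding bias
by roughly 40% of its own small magnitude (~0.01–0.02 kcal/mol). This is
well inside the statistical tolerances of every check here, but users
pushing reweighting hard should watch the effective sample size and compare
against a baseline run.

### The leap-frog algorithm

One step at time $t$: (1) evaluate $E_p$ and forces (plus the Langevin
random force for stochastic modes); (2) update the four local averages
($\tilde E_p$, $\tilde{\tilde E}_p$, $\tilde r$, $\tilde{\tilde r}$, in
that order) and derive $\tilde p, p, \tilde F, \tilde{\tilde F}$;
(3) advance the friction accumulators FP and PP and form
$\xi = -\mathrm{FP}/\mathrm{PP}$; (4) assemble the guiding force
$g = \mu(\tilde F - \tilde{\tilde F}) + \lambda\xi\tilde p$;
(5) compute the energy-conservation scaling factor per atom,

$$\eta = \frac{(2+\gamma\,\delta t)\,(g\cdot p_0)}
              {2p_0^2 - (g\cdot p_0)\,\delta t},
\qquad
p_0 = m v_{t-\delta t/2} + (f + g - \gamma m v_{t-\delta t/2})\,
      \frac{\delta t}{2};$$

(6) update velocities
$v_{t+\delta t/2} = \frac{1-(\gamma+\eta)\delta t/2}
{1+(\gamma+\eta)\delta t/2} v_{t-\delta t/2}
+ \frac{(f+g)\,\delta t/m}{1+(\gamma+\eta)\delta t/2}$;
(7) advance positions $r_{t+\delta t} = r_t + v_{t+\delta t/2}\delta t$.
$\eta$ is the exact solution of the discrete work-cancellation condition:
on a free particle the kinetic-energy change of the $\eta$-scaled update is
zero to rounding. SGMD is this algorithm with $\gamma = 0$ and no random
force; plain MD/LD are the $\lambda = \mu = 0$ limits, to which the guided
modes reduce bitwise (the guiding force is then exactly zero, hence
$\eta = 0$, hence identical arithmetic and identical RNG consumption).

### SGLD-GLE

Choosing an exponential memory kernel in the generalized Langevin equation
yields an equation of motion
$\dot p = f - \gamma p + \lambda\gamma\tilde p + R - \nu\tilde R$ with
$\lambda = \nu(2-\nu)$ (we use $\nu = 1 - \sqrt{1-\lambda}$, hence
$\lambda \le 1$). Note the guiding coefficient is $\gamma$, not $\xi$, and
there is no $\eta$: the colored noise and the modified friction satisfy the
fluctuation–dissipation theorem together, so the canonical ensemble is
preserved exactly. $\tilde R$ is the same exponential local average applied
to the white stream, with one discretization choice that matters: the
current-step impulse straddles the averaging-window boundary and enters
$\tilde R$ with half weight (the delta-function convention of the
kernel derivation). The full-weight variant leaves an $O(\delta t/t_L)$
cold bias — measured at $-3.7\%$ in $\langle x^2\rangle$ at
$\delta t = 2$ fs on a harmonic oscillator, and within noise ($\lesssim 1\%$)
at the standard 1 fs with the half-weight form.

### Replica exchange

RXSGLD places replicas on a ladder of *guiding* stages
$(T, \lambda_i, \mu_i)$ — all at the same temperature — and swaps stage
assignments by Metropolis. Because guiding perturbs only the small
low-frequency share of thermal motion, neighbouring stages overlap far more
than temperature neighbours of equal search power, which is the method's
advantage for large systems. The generalized criterion needs only per-frame
energies and stage parameters:

$$\pi = \min\!\Big(1, \exp\big[(\beta_m-\beta_n)(E_i - E_j)
+ (\beta_m(\mu_m - \hat\mu_m) - \beta_n(\mu_n - \hat\mu_n))
  (\Delta_i - \Delta_j)\big]\Big),$$

with $\hat\mu = \mu_\lambda$ per stage. The legacy criterion (from the
older partition function) is retained for diagnostics; it needs the
frequency-separated energy/collision factors
$\lambda_{lf}, \lambda_{hf}, \chi_{lf}, \chi_{hf}$, which the integrator
accumulates with $t_\mathrm{avg}$ averaging, and it is exact only for
equal-temperature ladders (the package warns otherwise). Exchange partners
follow the alternating even/odd adjacent-pair schedule standard in
replica-exchange practice (random pairing is available); momenta are kept
on swap, which equal-temperature ladders make exact. A stage's search power
is summarized by the self-guiding temperature
$T_{SG} = \tilde T(T - \tilde T_0)\,T / [\tilde T_0 (T - \tilde T)]$,
where $\tilde T$ is the kinetic temperature of the local-average momenta
and $\tilde T_0$ its zero-guiding value. $\tilde T_0$ has no closed-form
estimator, so the package calibrates it from a companion zero-guiding run
with the same $T$, $\gamma$, $t_L$ (cached per configuration signature).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `t_L` | 0.2 ps | local average time; $1/t_L$ is the enhancement frequency threshold. 0.2 ps filters covalent-vibration scales; larger values target slower motion |
| `t_avg` | 10 `t_L` | long-average time for $\xi$ and the frequency factors |
| `lambda` | 0 | momentum guiding factor; working range $-1\ldots1$ |
| `mu` | 0 | force guiding factor; negative enhances, $\mu_\lambda$ cancels $\lambda$ |
| `gamma` | 10/ps (LD modes) | Langevin collision frequency; must be 0 for MD/SGMD |
| `dt` | 1 fs | leap-frog timestep; must not exceed `t_L` |
| `warmup` | 5 `t_L` | span excluded from ensemble summaries while the local averages become representative |

Units are Å, ps, amu and kcal/mol throughout, with
$k_B = 0.0019872041$ kcal/mol/K and 1 kcal/mol = 418.4 amu Å²/ps²; the
conversion's correctness is pinned by the equipartition tests rather than
asserted.

## The toy systems

**Skewed double well.** One argon-mass particle on
$\varepsilon(x,y,z) = a y^2(y^2 - 2y_0^2) + b(y+y_0)^2 + c(x^2+z^2)$ with
$a = 1$, $b = 0.25$, $c = 1000$ kcal/mol, $y_0 = 1$ Å: wells at
$y = -1$ and $y \approx 0.854$, barrier top at $y \approx 0.146$
(1.29 kcal/mol above the deep well), and stiff transverse restraints that
make $x, z$ purely high-frequency. The particle's mass is taken as
39.948 amu. Barrier crossings are counted with a hysteresis band of
$\pm 0.5\,y_0$ about the numerically located barrier top, so recrossing
noise inside the band is not counted.

**Lennard-Jones argon.** $\varepsilon = 119.8$ K ($0.2381$ kcal/mol),
$\sigma = 3.405$ Å, 500 atoms in a 28.53 Å cube at the reference liquid
density. The long-range treatment here is cutoff truncation with the pair
energy shifted to zero at the cutoff — chosen because it conserves energy
exactly, which the $\eta$ tests require; it is not the isotropic periodic
sum the original argon studies used, so absolute energies and pressures
differ from theirs while all *comparative* statements (spectral shifts,
ensemble overlap, diffusion trends) are unaffected. Pair interactions use
an $O(N^2)$ minimum-image loop — fine at these sizes — and initial
configurations are a simple-cubic lattice with Maxwell–Boltzmann
velocities, centre-of-mass momentum removed.

## Scaled-down study conditions

The validation suite runs desk-scale versions of the reference experiments;
the physics settings (T = 300 K/100 K, $\gamma$ = 10/ps, $t_L$ = 0.2 ps,
dt = 1 fs) are kept, the run lengths and system sizes are reduced:

- Canonical baselines: 1-D-per-component harmonic oscillator
  ($k = 2$ kcal/mol/Å², $m = 20$ amu), $10^6$ steps, block-averaged
  standard errors (50 blocks) with 3-SE tolerances.
- Balanced-pair and reweighting checks: SDW, 1 ns per run.
- Barrier-crossing trends: SDW, 4 ns per run, five seeds — sized so the
  ~25% enhancement at $\lambda = 1$ stands well clear of the Poisson noise
  of the counts.
- Spectra, ensemble-overlap and diffusion: 125 argon atoms in a 17.97 Å box
  (the 500-atom density), cutoff reduced to 8.5 Å to respect the
  minimum-image bound, 20 ps LD equilibration from the lattice, 100 ps
  production, velocities every 0.05 ps, VACF to 4 ps lag with a Hann
  window and 4× zero padding.
- Replica exchange: four-stage SDW ladders, 4000 exchange cycles of 200
  steps — the single-particle acceptance contrast between a guiding ladder
  and a comparable temperature ladder is only ~1 percentage point, so it
  takes several thousand attempts to resolve.

What these toy systems do *not* emulate: biomolecular force fields, bonded
terms, electrostatics, solvent, or constrained bonds. Passing tests show
the machinery is faithful to its equations and that the enhancement and
ensemble claims hold where they are checkable cheaply; they do not predict
enhancement factors for macromolecules.

## Numerical choices and degenerate inputs

- $\xi$ guard: $\xi = 0$ until PP exceeds $10^{-12}$ (internal units), so a
  cold start (PP = 0) never divides by zero; likewise $\eta = 0$ exactly
  when $g\cdot p_0 = 0$ and when $|p_0| \approx 0$ (with a warning).
- Cold start: $\tilde r = \tilde{\tilde r} = r(0)$,
  $\tilde E = \tilde{\tilde E} = E_p(0)$, $\tilde p_{prev} = 0$,
  FP = PP = 0 — guiding forces grow in smoothly from zero.
- The discrete filter's fixed point on a uniform ramp is
  $m v (1 - \delta t/t_L)$, not $m v$; all filter tests assert the discrete
  value and the per-step contraction factor $(1 - \delta t/t_L)$.
- Kinetic energy and temperature are reported from the mean of squared
  velocities at the two adjacent half-steps (the standard leap-frog
  estimator); the full-step momentum $p$ of the derivation enters only
  $\tilde F$.
- In LD-family modes the random force is part of $f$ everywhere $f$
  appears, including $p_0$.
- RNG: one master seed; draws are made per step, per atom, per component in
  a fixed order, so trajectories are bit-reproducible; replica-exchange
  runs consume the same global stream sequentially over replicas.
- Trajectory positions are unwrapped (minimum image is applied to
  coordinate *differences* in the force loop), so mean-square displacements
  need no unwrapping step; `diffusion_constant()` still detects and warns
  on wrapped input.

## Known limitations

- With the guiding strengths these equations prescribe, liquid argon
  develops an apparent friction $\xi \approx 2.4$/ps (the package's
  estimate matches an independent spectral evaluation from the measured
  VACF to <1%). At $\gamma = 10$/ps this makes the SGLD momentum guiding
  force ($\lambda\xi\tilde p$) substantially weaker than SGLD-GLE's
  ($\lambda\gamma\tilde p$), so at equal $\lambda$ SGLD-GLE shows the
  larger zero-frequency spectral gain here — the opposite ordering of the
  enhancement magnitudes sometimes quoted for these methods. The relative
  ordering depends on $\xi/\gamma$ and is system- and bath-dependent.
- The reweighting overcorrection noted above (~40% of an already small
  bias) reflects the long-time-average approximation in $\xi$; it is
  invisible at 3-SE tolerances but measurable with multi-seed precision.
- Replica exchange is sequential in-process; no distributed execution.
- No constraints (SHAKE), no barostat (NVT/NVE only), no biomolecular force
  fields; the legacy exchange criterion is approximate off the
  equal-temperature ladder.
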