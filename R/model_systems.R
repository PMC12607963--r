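# Toy model systems: the skewed double well (SDW), Lennard-Jones argon and
# harmonic oscillators.  Positions are n x 3 matrices in Angstrom; energies
# kcal/mol; forces kcal/mol/A.

.check_positions <- function(positions, n_atoms = NULL) {
  positions <- rbind(positions) # promote a bare 3-vector to 1 x 3
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix (Angstrom)")
  if (!all(is.finite(positions)))
    stop("non-finite input coordinates")
  if (!is.null(n_atoms) && nrow(positions) != n_atoms)
    stop("positions have ", nrow(positions), " rows but the system has ",
         n_atoms, " atoms")
  positions
}

#' Skewed double-well parameters
#'
#' The one-particle test surface
#' \deqn{\epsilon(x,y,z) = a y^2 (y^2 - 2 y_0^2) + b (y + y_0)^2 + c (x^2 + z^2)}
#' has two wells near \eqn{y = \pm y_0} separated by a static barrier; `a`
#' sets the well depth, `b` skews the two wells apart in energy and the large
#' `c` confines x and z so tightly that motion in those directions is purely
#' high-frequency.
#'
#' @param a Well-depth parameter (kcal/mol), > 0.
#' @param b Skew parameter (kcal/mol), >= 0.
#' @param c Restraint stiffness in x and z (kcal/mol/A^2), > 0.
#' @param y0 Half-separation of the wells (A), > 0.
#' @return An object of class `sdw_params`.
#' @examples
#' p <- sdw_params()
#' sdw_energy_forces(c(0, -1, 0), p)$energy  # lower well, -1 kcal/mol
#' @export
sdw_params <- function(a = 1, b = 0.25, c = 1000, y0 = 1) {
  stopifnot(a > 0, b >= 0, c > 0, y0 > 0)
  structure(list(a = a, b = b, c = c, y0 = y0), class = "sdw_params")
}

#' Lennard-Jones parameters
#'
#' 6-12 pair potential, truncated at `cutoff` and shifted so the pair energy
#' is zero at the cutoff (which keeps the dynamics strictly energy
#' conserving).  The argon defaults are epsilon = 119.8 K (converted to
#' kcal/mol) and sigma = 3.405 A.
#'
#' @param epsilon Well depth in kcal/mol.
#' @param sigma LJ diameter (A).
#' @param cutoff Truncation radius (A), must exceed `sigma`.
#' @return An object of class `lj_params`.
#' @export
lj_params <- function(epsilon = 119.8 * .kB, sigma = 3.405, cutoff = 10) {
  stopifnot(epsilon > 0, sigma > 0, cutoff > sigma)
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff),
            class = "lj_params")
}

#' SDW potential energy and forces
#'
#' @param positions A 3-vector or n x 3 matrix (A).
#' @param params An [sdw_params()] object.
#' @return List with `energy` (kcal/mol) and `forces` (n x 3, kcal/mol/A),
#'   the exact negative gradient.
#' @export
sdw_energy_forces <- function(positions, params = sdw_params()) {
  positions <- .check_positions(positions)
  out <- .potential_ef_cpp(positions, 1L,
                           c(params$a, params$b, params$c, params$y0), 0)
  list(energy = out$energy, forces = out$forces)
}

#' Lennard-Jones energy and forces under periodic boundaries
#'
#' Minimum-image convention in a cubic box; pair interactions are truncated
#' at the cutoff with the pair energy shifted to zero there.  Overlapping
#' atoms (r < 0.1 A) are reported with a warning rather than silently
#' continued.
#'
#' @param positions n x 3 matrix (A).
#' @param box Cubic box edge (A); must exceed twice the cutoff.
#' @param params An [lj_params()] object.
#' @return List with `energy` (kcal/mol) and `forces` (n x 3, kcal/mol/A).
#' @export
lj_energy_forces <- function(positions, box, params = lj_params()) {
  positions <- .check_positions(positions)
  if (box < 2 * params$cutoff)
    stop("box edge (", box, " A) must exceed twice the cutoff (",
         2 * params$cutoff, " A)")
  out <- .potential_ef_cpp(positions, 2L,
                           c(params$epsilon, params$sigma, params$cutoff), box)
  if (isTRUE(out$overlap))
    warning("overlapping atoms detected (pair distance < 0.1 A)")
  list(energy = out$energy, forces = out$forces)
}

#' Harmonic test potential
#'
#' Each atom feels an independent isotropic spring about the origin:
#' energy 0.5 * k * |r|^2, force -k * r.  Used as an analytic reference
#' system for integrator and thermostat checks.
#'
#' @param positions 3-vector or n x 3 matrix (A).
#' @param k_spring Spring constant (kcal/mol/A^2), > 0.
#' @return List with `energy` and `forces`.
#' @export
harmonic_energy_forces <- function(positions, k_spring) {
  stopifnot(k_spring > 0)
  positions <- .check_positions(positions)
  out <- .potential_ef_cpp(positions, 0L, k_spring, 0)
  list(energy = out$energy, forces = out$forces)
}

# ---------------------------------------------------------------------------
# system builders
# ---------------------------------------------------------------------------

.new_system <- function(potential, n_atoms, masses, pot_params, box = NULL,
                        extra = list()) {
  stopifnot(all(masses > 0))
  structure(c(list(potential = potential, n_atoms = n_atoms,
                   masses = rep_len(masses, n_atoms),
                   pot_params = pot_params, box = box), extra),
            class = "sg_system")
}

#' @export
print.sg_system <- function(x, ...) {
  cat("<sg_system> ", x$potential, ", ", x$n_atoms, " atom(s)",
      if (!is.null(x$box)) paste0(", periodic box ", signif(x$box, 6), " A"),
      "\n", sep = "")
  invisible(x)
}

#' Single-particle skewed double-well system
#'
#' One particle (an argon atom by default) on the SDW surface.
#'
#' @param params [sdw_params()].
#' @param mass Particle mass (amu).
#' @return An `sg_system`.
#' @export
sdw_system <- function(params = sdw_params(), mass = 39.948) {
  .new_system("sdw", 1L, mass, c(params$a, params$b, params$c, params$y0),
              extra = list(params = params))
}

#' Harmonic oscillator system
#'
#' @param k_spring Spring constant (kcal/mol/A^2).
#' @param mass Atom mass (amu).
#' @param n_atoms Number of independent oscillators.
#' @return An `sg_system`.
#' @export
harmonic_system <- function(k_spring, mass = 39.948, n_atoms = 1L) {
  stopifnot(k_spring > 0, n_atoms >= 1)
  .new_system("harmonic", as.integer(n_atoms), mass, k_spring,
              extra = list(k_spring = k_spring))
}

#' Periodic Lennard-Jones system
#'
#' @param n_atoms Number of atoms.
#' @param box Cubic box edge (A); must exceed twice the LJ cutoff.
#' @param params [lj_params()].
#' @param mass Atom mass (amu); argon by default.
#' @return An `sg_system`.
#' @export
lj_system <- function(n_atoms, box, params = lj_params(), mass = 39.948) {
  if (box <= 2 * params$cutoff)
    stop("box edge must exceed twice the LJ cutoff (", 2 * params$cutoff, " A)")
  .new_system("lj", as.integer(n_atoms), mass,
              c(params$epsilon, params$sigma, params$cutoff), box = box,
              extra = list(params = params))
}

#' Maxwell-Boltzmann velocities with the centre of mass at rest
#'
#' @param masses Per-atom masses (amu).
#' @param temperature Temperature (K).
#' @return n x 3 matrix of velocities (A/ps) whose total momentum is zero.
#' @export
maxwell_velocities <- function(masses, temperature) {
  stopifnot(temperature > 0, all(masses > 0))
  n <- length(masses)
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(.kB_int * temperature / masses)
  if (n > 1) {
    p_com <- colSums(v * masses) / sum(masses)
    v <- sweep(v, 2, p_com)
  }
  v
}

#' Build a periodic argon system on a simple-cubic lattice
#'
#' Places `n_atoms` on a uniform simple-cubic lattice filling the box and
#' draws Maxwell-Boltzmann velocities at `temperature` with the centre-of-mass
#' momentum removed.  Deterministic for a fixed RNG state (call [set.seed()]
#' or pass `seed`).
#'
#' @param n_atoms Number of atoms (500 fills the reference box at liquid
#'   density).
#' @param box Cubic box edge (A).
#' @param temperature Temperature for the initial velocities (K).
#' @param seed Optional integer seed.
#' @param params [lj_params()].
#' @param mass Atom mass (amu).
#' @return A list with `system` (an `sg_system`), `positions` and
#'   `velocities` (both n x 3).
#' @examples
#' ar <- build_argon_system(8, box = 22, temperature = 100, seed = 1,
#'                          params = lj_params(cutoff = 8))
#' colSums(ar$velocities * ar$system$masses)  # ~ zero total momentum
#' @export
build_argon_system <- function(n_atoms = 500, box = 28.53, temperature = 100,
                               seed = NULL, params = lj_params(),
                               mass = 39.948) {
  if (!is.null(seed)) set.seed(seed)
  sys <- lj_system(n_atoms, box, params, mass)
  nside <- ceiling(n_atoms^(1 / 3) - 1e-9)
  spacing <- box / nside
  if (spacing < 0.5 * params$sigma)
    stop("lattice cannot fit ", n_atoms, " atoms in a ", box,
         " A box without overlap")
  idx <- seq_len(n_atoms) - 1L
  positions <- cbind(idx %% nside,
                     (idx %/% nside) %% nside,
                     idx %/% (nside * nside)) * spacing + spacing / 2
  velocities <- maxwell_velocities(sys$masses, temperature)
  list(system = sys, positions = positions, velocities = velocities)
}

# internal: evaluate a system's potential at given positions
.system_energy_forces <- function(system, positions) {
  code <- match(system$potential, c("harmonic", "sdw", "lj")) - 1L
  .potential_ef_cpp(rbind(positions), code, system$pot_params,
                    if (is.null(system$box)) 0 else system$box)
}

#' Locate the SDW barrier top and well minima
#'
#' Scans the potential profile along y at x = z = 0 on a fine grid and
#' refines the two minima and the interior maximum.
#'
#' @param params [sdw_params()].
#' @param grid Grid spacing for the scan (A).
#' @return List with `y_barrier`, `y_wells` (length 2), `E_barrier` and
#'   `E_wells` (kcal/mol).
#' @export
sdw_barrier <- function(params = sdw_params(), grid = 1e-3) {
  yy <- seq(-2 * params$y0, 2 * params$y0, by = grid)
  prof <- function(y) params$a * y^2 * (y^2 - 2 * params$y0^2) +
    params$b * (y + params$y0)^2
  e <- prof(yy)
  i_min <- which(diff(sign(diff(e))) == 2) + 1L
  if (length(i_min) != 2)
    stop("expected two wells in the scanned range; found ", length(i_min))
  lo <- optimize(prof, c(yy[i_min[1]] - grid, yy[i_min[1]] + grid),
                 tol = 1e-10)
  hi <- optimize(prof, c(yy[i_min[2]] - grid, yy[i_min[2]] + grid),
                 tol = 1e-10)
  top <- optimize(prof, c(lo$minimum, hi$minimum), maximum = TRUE,
                  tol = 1e-10)
  list(y_barrier = top$maximum, y_wells = c(lo$minimum, hi$minimum),
       E_barrier = top$objective, E_wells = c(lo$objective, hi$objective))
}
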