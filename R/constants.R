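# Unit system: Angstrom, picosecond, amu.  The internal energy unit is
# amu*A^2/ps^2; 1 kcal/mol = 418.4 amu*A^2/ps^2 (4184 J/mol divided by
# 10 J/mol per internal unit).  Forces cross the boundary as kcal/mol/A
# at the user surface and amu*A/ps^2 inside the integrator.

.kB <- 0.0019872041     # Boltzmann constant, kcal/mol/K
.FCONV <- 418.4         # kcal/mol -> amu*A^2/ps^2
.kB_int <- .kB * .FCONV # amu*A^2/ps^2/K

#' Physical constants and unit conversions
#'
#' The package works internally in Angstrom / picosecond / amu, so the
#' internal energy unit is amu*A^2/ps^2.  User-facing energies are kcal/mol.
#'
#' @return A list with `kB` (Boltzmann constant, kcal/mol/K),
#'   `kcal_per_internal` (kcal/mol per amu*A^2/ps^2) and `f_conv`
#'   (amu*A^2/ps^2 per kcal/mol, i.e. 418.4).
#' @examples
#' sg_constants()$kB * 119.8  # argon LJ well depth in kcal/mol
#' @export
sg_constants <- function() {
  list(kB = .kB, kcal_per_internal = 1 / .FCONV, f_conv = .FCONV)
}
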