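#' @useDynLib thzbind, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# MD unit system: length nm, time ps, mass u, charge e, energy kJ/mol.
# 1 u nm^2 ps^-2 = 1 kJ/mol exactly, so kinetic energy needs no conversion.

#' Physical constants in MD units
#'
#' Constants used throughout the package: lengths in nm, times in ps, masses
#' in atomic mass units (u), charges in elementary charge (e), energies in
#' kJ/mol. In this system 1 u nm^2/ps^2 = 1 kJ/mol, so no hidden conversion
#' factors appear in the dynamics.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/mol/K.}
#'   \item{coulomb}{Coulomb prefactor \eqn{1/(4\pi\epsilon_0)},
#'     kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.}
#'   \item{eV_to_kJmol}{1 e·V in kJ/mol (Faraday constant / 1000).}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#' }
#' @export
md_constants <- list(
  kB          = 0.0083144621,
  coulomb     = 138.935458,
  eV_to_kJmol = 96.4853,
  avogadro    = 6.02214076e23
)

#' Convert a field amplitude acting on a charge to an MD force
#'
#' An electric field of amplitude \code{A} V/nm acting on a partial charge
#' \code{q} e exerts a force \code{q * A * 96.4853} kJ/mol/nm (1 e·V =
#' 96.4853 kJ/mol).
#'
#' @param A field amplitude, V/nm.
#' @param q charge, e.
#' @return Force magnitude in kJ/mol/nm (signed by \code{q}).
#' @examples
#' field_to_force_units(0.5, 1)   # 48.243
#' @export
field_to_force_units <- function(A, q) {
  q * A * md_constants$eV_to_kJmol
}
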