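#' @name units
#' @title Unit conventions and physical constants
#'
#' @description
#' All user-facing geometry is in Angstrom and all charges in units of the
#' elementary charge e.  Electrostatics is computed internally in Hartree
#' atomic units (Bohr, e, Hartree/e), so electrostatic potentials are always
#' in atomic units.  Polarizabilities are supplied in Angstrom^3 and converted
#' to Bohr^3 internally.  Molecular dipole moments are reported in Debye.
#'
#' Conversion constants used throughout (documented to full precision):
#' * 1 Angstrom = 1.889726124565062 Bohr
#' * 1 e.Angstrom = 4.803204 Debye
#' @keywords internal
NULL

## 1 Angstrom in Bohr
ANG_TO_BOHR <- 1.889726124565062

## 1 e.Angstrom in Debye
EA_TO_DEBYE <- 4.803204

## base R has no erf(); relation to the normal CDF is exact
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
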