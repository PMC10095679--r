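#' @useDynLib gamdkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm var integrate sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Package-wide unit system: lengths in Angstrom, time in ps, energy in
# kcal/mol, mass in amu, temperature in K.  1 kcal/mol = 418.4 amu A^2/ps^2
# (the square of Amber's 20.455 time conversion factor).
.KCAL_PER_AMU_A2_PS2 <- 418.4

#' Boltzmann constant in kcal/mol/K
#'
#' @export
GAMD_KB <- 0.0019872041

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in Kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT(300) # ~0.596 kcal/mol
#' @export
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAMD_KB * temperature
}
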