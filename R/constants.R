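# Unit conventions: energies in cm^-1, magnetic fields in Gauss, frequencies
# in GHz. These constants fix every conversion in the package.

# Bohr magneton over hc, cm^-1 per Gauss
MU_B_CM1_PER_G <- 4.668645e-5

# GHz -> cm^-1 (divide by c in cm GHz)
GHZ_PER_CM1 <- 29.9792458

# hartree -> cm^-1
CM1_PER_HARTREE <- 219474.63

# Boltzmann constant, cm^-1 per Kelvin
KB_CM1_PER_K <- 0.69503480

#' Convert a microwave frequency in GHz to a photon energy in cm^-1
#'
#' X-band spectrometers are conventionally quoted in GHz while spin-Hamiltonian
#' parameters are quoted in cm^-1; this is the single conversion used
#' throughout the package (division by the speed of light, 29.9792458 cm GHz).
#'
#' @param ghz Frequency in GHz.
#' @return Energy in cm^-1.
#' @export
#' @examples
#' ghz_to_cm1(9.50)
ghz_to_cm1 <- function(ghz) ghz / GHZ_PER_CM1

#' Convert an energy in hartree to cm^-1
#'
#' Quantum-chemical total energies are reported in hartree; the exchange-fit
#' stage works in cm^-1. Fixed at 219474.63 cm^-1 per hartree.
#'
#' @param hartree Energy in hartree.
#' @return Energy in cm^-1.
#' @export
hartree_to_cm1 <- function(hartree) hartree * CM1_PER_HARTREE

#' Resonance field of an isotropic spin at a given frequency
#'
#' Inverts the resonance condition h nu = g muB B.
#'
#' @param g Dimensionless g value.
#' @param freq_ghz Microwave frequency in GHz.
#' @return Field in Gauss.
#' @export
#' @examples
#' resonance_field(2, 9.50)
resonance_field <- function(g, freq_ghz) {
  ghz_to_cm1(freq_ghz) / (g * MU_B_CM1_PER_G)
}
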