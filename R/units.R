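#' @title Internal unit system and physical constants
#' @description
#' All quantities in the package use a single fixed unit system:
#' length in Angstrom, time in femtoseconds, temperature in Kelvin,
#' mass in atomic mass units (amu) and energy in kcal/mol.
#' Velocities are Angstrom/fs and forces kcal/mol/Angstrom.
#' @name nr-units
#' @keywords internal
NULL

#' Boltzmann constant in kcal/(mol K)
#' @export
NR_KB <- 0.0019872041

# 1 (kcal/mol/A) / amu expressed in A/fs^2: 4184 J/mol per (g/mol) per A
# = 4.184e6 m^2 s^-2 A^-1 = 4.184e-4 A/fs^2.
NR_ACC <- 4.184e-4

# amu -> gram
NR_AMU_G <- 1.66053906892e-24

#' Standard atomic weights used throughout (amu)
#'
#' C, H, N and O are the supported chemistry; a few extras are included so
#' that imported configurations do not fail on sight.
#' @export
NR_ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  He = 4.0026, F = 18.998, S = 32.06
)

#' Look up atomic masses for a vector of element symbols
#'
#' @param species character vector of element symbols.
#' @param masses named numeric table of atomic weights (amu); defaults to
#'   [NR_ATOMIC_MASSES].
#' @return numeric vector of masses (amu).
#' @export
atomic_masses <- function(species, masses = NR_ATOMIC_MASSES) {
  m <- masses[species]
  if (anyNA(m)) {
    bad <- unique(species[is.na(m)])
    stop("no atomic mass for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
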