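#' Physical constants and unit conversions
#'
#' Unit conventions throughout the package: molecule coordinates in
#' Angstrom, grid points in Bohr, potentials in Hartree/e, charges in
#' elementary charge e, energies in kJ/mol, volumes in nm^3, box dipoles
#' in e*nm, temperatures in K.
#'
#' @name resp2kit-constants
#' @keywords internal
NULL

# CODATA-style values; ANGSTROM_PER_BOHR fixed to the quantum-chemistry
# convention used for all grid file I/O.
ANGSTROM_PER_BOHR <- 0.52917721067
BOHR_PER_ANGSTROM <- 1 / ANGSTROM_PER_BOHR
DEBYE_PER_E_ANGSTROM <- 4.80321
GAS_CONSTANT_KJ <- 0.0083145      # kJ/(mol K)
AVOGADRO <- 6.02214076e23         # 1/mol
ELEMENTARY_CHARGE_C <- 1.602176634e-19  # C
BOLTZMANN_J <- 1.380649e-23       # J/K
VACUUM_PERMITTIVITY <- 8.8541878128e-12 # F/m

#' Bondi van der Waals radii
#'
#' Standard Bondi van der Waals radii in Angstrom, used to scale the
#' Merz-Singh-Kollman shells. Lookup of an element absent from the table
#' is an error.
#'
#' @param elements character vector of element symbols.
#' @return named numeric vector of radii (Angstrom).
#' @examples
#' bondi_radii(c("O", "H"))
#' @export
bondi_radii <- function(elements) {
  table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
             F = 1.47, S = 1.80, Cl = 1.75)
  missing <- setdiff(unique(elements), names(table))
  if (length(missing) > 0L) {
    stop("no van der Waals radius tabulated for element(s): ",
         paste(missing, collapse = ", "))
  }
  table[elements]
}

# Atomic numbers for the elements the package knows about.
ATOMIC_NUMBERS <- c(H = 1L, C = 6L, N = 7L, O = 8L,
                    F = 9L, S = 16L, Cl = 17L)

# Single-bond covalent radii (Angstrom) for the heuristic bond-perception
# fallback only.
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66,
                    F = 0.57, S = 1.05, Cl = 1.02)
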