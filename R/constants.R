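# Physical constants (CODATA 2018) and element data.
# Every unit conversion in the package goes through this table; tests
# reference these objects rather than redefining their own copies.

#' Physical constants used throughout the package
#'
#' A named list of CODATA 2018 physical constants and conversion factors.
#' All thermochemistry is done internally in SI and converted once, here:
#' energies in Hartree at ingestion, kcal/mol for every reported quantity,
#' entropies in cal/(mol K).
#'
#' @format Named list with elements
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{c_cm}{speed of light, cm/s}
#'   \item{NA_avogadro}{Avogadro number, 1/mol}
#'   \item{R_J}{gas constant, J/(mol K)}
#'   \item{R_kcal}{gas constant, kcal/(mol K)}
#'   \item{amu}{atomic mass unit, kg}
#'   \item{atm_Pa}{1 atm in Pa}
#'   \item{hartree_kcal}{1 Hartree in kcal/mol}
#'   \item{J_per_kcal}{thermochemical calorie convention, J per kcal}
#'   \item{grimme_Bav}{average molecular moment of inertia used by the
#'     damped free-rotor entropy, kg m^2}
#' }
#' @export
qc_constants <- list(
  h            = 6.62607015e-34,
  kB           = 1.380649e-23,
  c_cm         = 2.99792458e10,
  NA_avogadro  = 6.02214076e23,
  R_J          = 8.31446261815324,
  R_kcal       = 8.31446261815324 / 4184,
  amu          = 1.66053906660e-27,
  atm_Pa       = 101325,
  hartree_kcal = 627.5094740631,
  J_per_kcal   = 4184,
  grimme_Bav   = 1e-44
)

# Element tables. Masses are standard atomic weights; vdW radii are the
# Bondi set (C = 1.70 A, so a C...C contact sum is 3.40 A); covalent
# radii are the Cordero single-bond values used for bond perception.
.element_data <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Si", "P", "S", "Cl", "K", "Br", "I"),
  mass   = c(1.008, 4.003, 10.811, 12.011, 14.007, 15.999, 18.998, 20.180,
             22.990, 24.305, 28.085, 30.974, 32.06, 35.45, 39.098,
             79.904, 126.904),
  vdw    = c(1.20, 1.40, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
             2.27, 1.73, 2.10, 1.80, 1.80, 1.75, 2.75, 1.85, 1.98),
  covalent = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
               1.66, 1.41, 1.11, 1.07, 1.05, 1.02, 2.03, 1.20, 1.39),
  stringsAsFactors = FALSE
)

.lookup_element <- function(symbols, what, context = "element table") {
  i <- match(symbols, .element_data$symbol)
  if (anyNA(i)) {
    stop(sprintf("element(s) not in %s: %s", context,
                 paste(unique(symbols[is.na(i)]), collapse = ", ")),
         call. = FALSE)
  }
  .element_data[[what]][i]
}

#' Atomic masses (amu) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of standard atomic weights
#' @export
atomic_mass <- function(symbols) .lookup_element(symbols, "mass", "mass table")

#' Bondi van der Waals radii (Angstrom) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of radii
#' @export
vdw_radius <- function(symbols) .lookup_element(symbols, "vdw", "vdW table")

#' Covalent radii (Angstrom) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of radii
#' @export
covalent_radius <- function(symbols)
  .lookup_element(symbols, "covalent", "covalent-radius table")
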