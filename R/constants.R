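#' Physical constants and unit conversions
#'
#' Single source of truth for every unit conversion used in the package.
#' Quantum-chemical quantities are handled in atomic units internally and
#' converted at module boundaries; molecular-mechanics quantities are in
#' kcal/mol, Angstrom, amu and femtoseconds (the AMBER-style unit system).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_per_angstrom}{1 Angstrom in bohr, 1/0.52917721092.}
#'   \item{angstrom_per_bohr}{0.52917721092.}
#'   \item{kcalmol_per_hartree}{627.509474.}
#'   \item{ev_per_hartree}{27.211386.}
#'   \item{evnm}{eV times nm product for photon energy/wavelength, 1239.841984.}
#'   \item{coulomb_kcal}{Electrostatic conversion, kcal/mol * Angstrom / e^2:
#'     332.0637128.}
#'   \item{kB_kcalmol}{Boltzmann constant, kcal/(mol K).}
#'   \item{akma_accel}{Acceleration conversion: multiply a force in
#'     kcal/(mol Angstrom) by this and divide by mass in amu to obtain an
#'     acceleration in Angstrom/fs^2; 4.184e-4.}
#' }
#' @export
qmmd_constants <- list(
  bohr_per_angstrom  = 1 / 0.52917721092,
  angstrom_per_bohr  = 0.52917721092,
  kcalmol_per_hartree = 627.509474,
  ev_per_hartree     = 27.211386,
  evnm               = 1239.841984,
  coulomb_kcal       = 332.0637128,
  kB_kcalmol         = 0.0019872041,
  akma_accel         = 4.184e-4
)

# standard atomic data used by geometry readers and velocity setup
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  number = 1:18,
  mass = c(1.00794, 4.002602, 6.941, 9.012182, 10.811, 12.0107, 14.0067,
           15.9994, 18.9984032, 20.1797, 22.98976928, 24.305, 26.9815386,
           28.0855, 30.973762, 32.065, 35.453, 39.948),
  stringsAsFactors = FALSE
)

#' Look up atomic number and mass for element symbols
#'
#' @param symbols character vector of element symbols (case-insensitive).
#' @return data.frame with columns \code{symbol}, \code{number}, \code{mass}.
#' @export
element_info <- function(symbols) {
  key <- paste0(toupper(substr(symbols, 1, 1)),
                tolower(substr(symbols, 2, nchar(symbols))))
  idx <- match(key, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  data.frame(symbol = .element_table$symbol[idx],
             number = .element_table$number[idx],
             mass = .element_table$mass[idx],
             stringsAsFactors = FALSE)
}
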