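#' Molecular geometry container
#'
#' A geometry is a set of atoms with element symbols, atomic numbers,
#' Cartesian coordinates in Angstrom and masses in amu. It is the basic
#' structural object passed to the integral engine, the MM engine and the
#' dynamics driver.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param masses optional numeric vector of masses (amu); defaults to the
#'   standard atomic weights.
#' @return An object of class \code{qmmd_geometry}: a list with
#'   \code{elements}, \code{numbers}, \code{coords} (n x 3, Angstrom) and
#'   \code{masses}.
#' @export
geometry <- function(elements, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (length(elements) == 0L) stop("geometry needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix matching length(elements)")
  }
  info <- element_info(elements)
  if (is.null(masses)) masses <- info$mass
  stopifnot(all(masses > 0), all(info$number >= 1))
  structure(list(elements = info$symbol,
                 numbers = info$number,
                 coords = unname(coords),
                 masses = masses),
            class = "qmmd_geometry")
}

#' @export
print.qmmd_geometry <- function(x, ...) {
  cat(sprintf("<qmmd_geometry: %d atoms (%s)>\n", length(x$elements),
              paste(utils::head(x$elements, 8), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a \code{qmmd_geometry}.
#' @return integer atom count.
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Point-charge set for electrostatic embedding
#'
#' MM point charges fixed at atomic centres, entering the one-electron QM
#' Hamiltonian. Positions in Angstrom, charges in elementary charge units.
#'
#' @param positions numeric matrix n x 3 (Angstrom); may have zero rows.
#' @param charges numeric vector of length n.
#' @return An object of class \code{qmmd_charges}.
#' @export
point_charges <- function(positions, charges) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  charges <- as.numeric(charges)
  if (nrow(positions) != length(charges)) {
    stop("positions and charges must have the same length")
  }
  structure(list(positions = unname(positions), charges = charges),
            class = "qmmd_charges")
}

#' Empty point-charge set
#' @return A \code{qmmd_charges} with zero charges.
#' @export
no_charges <- function() point_charges(matrix(numeric(0), ncol = 3), numeric(0))

#' @export
print.qmmd_charges <- function(x, ...) {
  cat(sprintf("<qmmd_charges: %d charges, total %+.6f e>\n",
              length(x$charges), sum(x$charges)))
  invisible(x)
}

#' Nuclear repulsion energy
#'
#' Coulomb repulsion between the nuclei of a geometry, in hartree.
#'
#' @param geom a \code{qmmd_geometry}.
#' @return energy in hartree.
#' @export
nuclear_repulsion <- function(geom) {
  n <- n_atoms(geom)
  if (n < 2L) return(0)
  xb <- geom$coords * qmmd_constants$bohr_per_angstrom
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- sqrt(sum((xb[i, ] - xb[j, ])^2))
      e <- e + geom$numbers[i] * geom$numbers[j] / r
    }
  }
  e
}

#' Interaction energy of nuclei with external point charges
#'
#' The charge-nucleus half of the electrostatic embedding energy, in hartree.
#'
#' @param geom a \code{qmmd_geometry}.
#' @param charges a \code{qmmd_charges}.
#' @return energy in hartree.
#' @export
nuclear_charge_interaction <- function(geom, charges) {
  if (length(charges$charges) == 0L) return(0)
  xb <- geom$coords * qmmd_constants$bohr_per_angstrom
  cb <- charges$positions * qmmd_constants$bohr_per_angstrom
  e <- 0
  for (a in seq_len(n_atoms(geom))) {
    d <- sqrt(rowSums((cb - matrix(xb[a, ], nrow(cb), 3, byrow = TRUE))^2))
    e <- e + geom$numbers[a] * sum(charges$charges / d)
  }
  e
}
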