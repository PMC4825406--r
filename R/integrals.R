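#' @useDynLib qmmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# flattened shell arrays with centre coordinates taken from the *current*
# geometry (basis sets are reusable across frames of a trajectory)
.flat_shells <- function(geom, basis) {
  f <- basis$flat
  xb <- geom$coords * qmmd_constants$bohr_per_angstrom
  f$sx <- xb[f$centers, 1]
  f$sy <- xb[f$centers, 2]
  f$sz <- xb[f$centers, 3]
  f
}

.check_basis <- function(basis) {
  if (!inherits(basis, "qmmd_basis") || basis$n_basis < 1L) {
    stop("no basis functions")
  }
}

#' Overlap matrix
#'
#' @param geom a \code{qmmd_geometry}.
#' @param basis a \code{qmmd_basis} built on that geometry.
#' @return symmetric n_basis x n_basis matrix; unit diagonal for normalized
#'   functions.
#' @export
overlap_matrix <- function(geom, basis) {
  .check_basis(basis)
  f <- .flat_shells(geom, basis)
  st <- cpp_overlap_kinetic(f$sl, f$sx, f$sy, f$sz, f$nprim, f$exps, f$coefs)
  st$S * outer(basis$norm, basis$norm)
}

#' Kinetic-energy matrix
#'
#' One-electron kinetic integrals \eqn{-\frac12 \langle i|\nabla^2|j\rangle}
#' in hartree.
#'
#' @inheritParams overlap_matrix
#' @return symmetric matrix, hartree.
#' @export
kinetic_matrix <- function(geom, basis) {
  .check_basis(basis)
  f <- .flat_shells(geom, basis)
  st <- cpp_overlap_kinetic(f$sl, f$sx, f$sy, f$sz, f$nprim, f$exps, f$coefs)
  st$T * outer(basis$norm, basis$norm)
}

#' Point-charge attraction matrix
#'
#' Electron--point-charge interaction integrals
#' \eqn{-\sum_c q_c \langle i | 1/|r-R_c| | j\rangle} (hartree). The charges
#' may be nuclei, external embedding charges, or their union; the matrix is
#' linear in the charge values. A charge coincident with a basis-function
#' centre is legal (Boys-function limit).
#'
#' @inheritParams overlap_matrix
#' @param charges a \code{qmmd_charges} (positions in Angstrom, charges in e).
#' @return symmetric matrix, hartree; zero matrix for an empty charge set.
#' @export
attraction_matrix <- function(geom, basis, charges) {
  .check_basis(basis)
  f <- .flat_shells(geom, basis)
  if (length(charges$charges) == 0L) {
    return(matrix(0, basis$n_basis, basis$n_basis))
  }
  cpos <- charges$positions * qmmd_constants$bohr_per_angstrom
  V <- cpp_attraction(f$sl, f$sx, f$sy, f$sz, f$nprim, f$exps, f$coefs,
                      cpos, charges$charges)
  V <- -V * outer(basis$norm, basis$norm)
  if (anyNA(V)) stop("NaN in attraction integrals")
  V
}

#' Attraction matrix of the nuclei of a geometry
#'
#' Convenience wrapper building the nuclear-attraction part of the core
#' Hamiltonian from the geometry's own nuclei.
#'
#' @inheritParams overlap_matrix
#' @return symmetric matrix, hartree.
#' @export
nuclear_attraction_matrix <- function(geom, basis) {
  attraction_matrix(geom, basis,
                    point_charges(geom$coords, geom$numbers))
}

#' Two-electron repulsion integrals
#'
#' Chemist-notation tensor \eqn{(ij|kl)} in hartree, with the full 8-fold
#' permutational symmetry. \code{mode = "stored"} returns the dense 4-index
#' array; \code{mode = "generator"} returns a function
#' \code{f(i, j, k, l)} evaluating integrals on demand (per shell quartet
#' internally), for the direct-SCF path.
#'
#' @inheritParams overlap_matrix
#' @param mode \code{"stored"} or \code{"generator"}.
#' @return 4-d array, or a generator closure.
#' @export
eri_tensor <- function(geom, basis, mode = c("stored", "generator")) {
  .check_basis(basis)
  mode <- match.arg(mode)
  f <- .flat_shells(geom, basis)
  nrm <- basis$norm
  if (mode == "stored") {
    eri <- cpp_eri_tensor(f$sl, f$sx, f$sy, f$sz, f$nprim, f$exps, f$coefs)
    n <- basis$n_basis
    nn <- outer(nrm, nrm)
    eri <- eri * as.vector(outer(nn, nn))   # N_i N_j N_k N_l scaling
    return(eri)
  }
  # generator: map basis index -> (shell, component), evaluate quartet
  sl <- f$sl
  ncomp <- (sl + 1L) * (sl + 2L) / 2L
  shell_of <- rep(seq_along(sl), ncomp)
  comp_of <- unlist(lapply(ncomp, seq_len))
  function(i, j, k, l) {
    blk <- cpp_eri_quartet(f$sl, f$sx, f$sy, f$sz, f$nprim, f$exps, f$coefs,
                           shell_of[i] - 1L, shell_of[j] - 1L,
                           shell_of[k] - 1L, shell_of[l] - 1L)
    # block is laid out with the last shell's component fastest
    blk[comp_of[l], comp_of[k], comp_of[j], comp_of[i]] *
      nrm[i] * nrm[j] * nrm[k] * nrm[l]
  }
}

# direct-SCF Coulomb/exchange build (never stores the tensor): takes the
# spinless half-density P, returns list(J, K)
.jk_direct <- function(geom, basis, P) {
  f <- .flat_shells(geom, basis)
  nn <- outer(basis$norm, basis$norm)
  jk <- cpp_jk_direct(f$sl, f$sx, f$sy, f$sz, f$nprim, f$exps, f$coefs,
                      P * nn)
  list(J = jk$J * nn, K = jk$K * nn)
}
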