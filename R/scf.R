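#' SCF configuration
#'
#' Settings for the restricted Hartree-Fock driver. Defaults: energy
#' tolerance 1e-8 hartree, density RMSD tolerance 1e-6, at most 128
#' iterations, DIIS depth 8, core-Hamiltonian initial guess. With
#' \code{diis_depth = 0} the solver falls back to damped Roothaan iteration
#' (density damping factor \code{damping}), whose energy decreases
#' monotonically.
#'
#' @param max_iterations maximum SCF cycles.
#' @param energy_tolerance convergence threshold on the energy change,
#'   hartree.
#' @param density_rmsd_tolerance convergence threshold on the density RMSD.
#' @param diis_depth number of Fock/error pairs kept for DIIS; 0 disables.
#' @param mode \code{"stored"} (precomputed ERI tensor) or \code{"direct"}
#'   (Fock rebuilt from shell-quartet integrals every iteration).
#' @param charge total molecular charge (e).
#' @param damping density damping factor for the non-DIIS path.
#' @param orthogonalizer \code{"symmetric"} (S^-1/2) or \code{"cholesky"}.
#' @param verbose print the iteration log.
#' @return list of class \code{qmmd_scf_config}.
#' @export
scf_config <- function(max_iterations = 128L, energy_tolerance = 1e-8,
                       density_rmsd_tolerance = 1e-6, diis_depth = 8L,
                       mode = c("stored", "direct"), charge = 0L,
                       damping = 0.3,
                       orthogonalizer = c("symmetric", "cholesky"),
                       verbose = FALSE) {
  stopifnot(energy_tolerance > 0, density_rmsd_tolerance > 0,
            diis_depth >= 0, max_iterations >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 energy_tolerance = energy_tolerance,
                 density_rmsd_tolerance = density_rmsd_tolerance,
                 diis_depth = as.integer(diis_depth),
                 mode = match.arg(mode), charge = as.integer(charge),
                 damping = damping,
                 orthogonalizer = match.arg(orthogonalizer),
                 verbose = isTRUE(verbose)),
            class = "qmmd_scf_config")
}

#' Orthogonalizing transformation of an overlap matrix
#'
#' Returns X with \eqn{X^T S X = I}. The symmetric back-end uses
#' \eqn{S^{-1/2}}; the Cholesky back-end uses the inverse transpose of the
#' Cholesky factor. The two differ by an orbital rotation only, so SCF
#' energies are identical.
#'
#' @param S overlap matrix (positive definite).
#' @param method \code{"symmetric"} or \code{"cholesky"}.
#' @param lindep_threshold smallest admissible overlap eigenvalue.
#' @return transformation matrix X.
#' @export
orthogonalizer <- function(S, method = c("symmetric", "cholesky"),
                           lindep_threshold = 1e-8) {
  method <- match.arg(method)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < lindep_threshold) {
    stop(sprintf(
      "overlap matrix (near-)linear dependence: smallest eigenvalue %.3e",
      min(ev$values)))
  }
  if (method == "symmetric") {
    ev$vectors %*% diag(1 / sqrt(ev$values), length(ev$values)) %*%
      t(ev$vectors)
  } else {
    L <- t(chol(S))           # S = L L^T
    t(solve(L))               # X = L^-T
  }
}

#' Fock matrix from a density
#'
#' \eqn{F = h + 2J(P) - K(P)} with the spinless half-density
#' \eqn{P = C_{occ} C_{occ}^T}.
#'
#' @param density half-density matrix P.
#' @param core_hamiltonian one-electron matrix h (kinetic + all attraction
#'   terms).
#' @param eri_source either a stored 4-index ERI array, or a list
#'   \code{list(geom = , basis = )} for the direct path.
#' @return the Fock matrix.
#' @export
build_fock <- function(density, core_hamiltonian, eri_source) {
  n <- nrow(core_hamiltonian)
  if (!all(dim(density) == c(n, n))) stop("density dimension mismatch")
  jk <- coulomb_exchange(density, eri_source)
  core_hamiltonian + 2 * jk$J - jk$K
}

#' Coulomb and exchange matrices from a density
#'
#' @inheritParams build_fock
#' @return list with matrices \code{J} and \code{K}.
#' @export
coulomb_exchange <- function(density, eri_source) {
  n <- nrow(density)
  if (is.array(eri_source) && length(dim(eri_source)) == 4L) {
    eri <- matrix(eri_source, n * n, n * n)
    J <- matrix(eri %*% as.vector(density), n, n)
    # K_ij = sum_kl (ik|jl) P_kl
    Kt <- matrix(aperm(array(eri_source, c(n, n, n, n)), c(1, 3, 2, 4)),
                 n * n, n * n)
    K <- matrix(Kt %*% as.vector(density), n, n)
    list(J = J, K = K)
  } else if (is.list(eri_source) && !is.null(eri_source$basis)) {
    .jk_direct(eri_source$geom, eri_source$basis, density)
  } else {
    stop("eri_source must be a 4-index array or list(geom=, basis=)")
  }
}

#' DIIS extrapolation of the Fock matrix
#'
#' Pulay's direct inversion in the iterative subspace: minimizes the norm of
#' the extrapolated error vector subject to the coefficients summing to 1.
#' A singular DIIS system falls back to the most recent Fock matrix with a
#' warning.
#'
#' @param fock_history list of Fock matrices (oldest first).
#' @param error_history list of error matrices (same length).
#' @return extrapolated Fock matrix; attribute \code{"coefficients"} carries
#'   the mixing weights.
#' @export
diis_extrapolate <- function(fock_history, error_history) {
  m <- length(fock_history)
  if (m == 0L || length(error_history) != m) {
    stop("histories must be non-empty and of equal length")
  }
  if (m == 1L) {
    out <- fock_history[[1L]]
    attr(out, "coefficients") <- 1
    return(out)
  }
  # drop oldest entries until the (scaled) error-overlap matrix is
  # well-conditioned: near-linear dependence is structural for very small
  # basis sets and not an error condition
  B0 <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B0[i, j] <- sum(error_history[[i]] * error_history[[j]])
  }
  first <- 1L
  while (m - first >= 1L) {
    sub <- B0[first:m, first:m, drop = FALSE]
    sc <- sqrt(diag(sub))
    sc[sc == 0] <- 1
    cond <- tryCatch(rcond(sub / outer(sc, sc)), error = function(e) 0)
    if (cond > 1e-12) break
    first <- first + 1L
  }
  keep <- first:m
  if (length(keep) == 1L) {
    out <- fock_history[[m]]
    attr(out, "coefficients") <- c(rep(0, m - 1L), 1)
    return(out)
  }
  fock_history <- fock_history[keep]
  error_history <- error_history[keep]
  m <- length(keep)
  Bm <- matrix(0, m + 1L, m + 1L)
  Bm[seq_len(m), seq_len(m)] <- B0[keep, keep]
  Bm[m + 1L, seq_len(m)] <- -1
  Bm[seq_len(m), m + 1L] <- -1
  rhs <- c(rep(0, m), -1)
  co <- tryCatch(solve(Bm, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(co) || anyNA(co)) {
    # a singular system with already-tiny error vectors is the normal
    # end-game of small problems; only warn when the errors are sizeable
    if (max(abs(error_history[[m]])) > 1e-7) {
      warning("singular DIIS system; falling back to latest Fock matrix")
    }
    out <- fock_history[[m]]
    attr(out, "coefficients") <- c(rep(0, m - 1L), 1)
    return(out)
  }
  out <- Reduce(`+`, Map(`*`, fock_history, co))
  attr(out, "coefficients") <- co
  out
}

#' Restricted Hartree-Fock with optional point-charge embedding
#'
#' Solves the closed-shell Roothaan equations, optionally in the field of
#' fixed external point charges (electrostatic embedding: the charges enter
#' the one-electron Hamiltonian and polarize the wavefunction). The
#' embedding energy is bookkept as separate charge-electron and
#' charge-nucleus terms; their sum is the electrostatic QM/MM interaction
#' energy.
#'
#' @param geom a \code{qmmd_geometry}.
#' @param basis a \code{qmmd_basis}.
#' @param charges external \code{qmmd_charges} (may be empty).
#' @param config a \code{\link{scf_config}}.
#' @return object of class \code{qmmd_scf} with elements
#'   \code{mo_coefficients}, \code{orbital_energies} (hartree),
#'   \code{density} (half density P), \code{electronic_energy},
#'   \code{nuclear_repulsion}, \code{embedding_energy_terms} (list:
#'   \code{charge_nucleus}, \code{charge_electron}), \code{total_energy},
#'   \code{converged}, \code{iterations}, \code{n_occ}, plus the matrices
#'   \code{overlap}, \code{core_hamiltonian} and the iteration \code{log}.
#' @export
run_rhf <- function(geom, basis, charges = no_charges(),
                    config = scf_config()) {
  n <- basis$n_basis
  nelec <- sum(geom$numbers) - config$charge
  if (nelec %% 2L != 0L) {
    stop("RHF requires an even electron count; got ", nelec)
  }
  nocc <- nelec %/% 2L
  if (nocc > n) stop("more occupied orbitals than basis functions")

  S <- overlap_matrix(geom, basis)
  T <- kinetic_matrix(geom, basis)
  Vnuc <- nuclear_attraction_matrix(geom, basis)
  Vext <- attraction_matrix(geom, basis, charges)
  h <- T + Vnuc + Vext
  enn <- nuclear_repulsion(geom)
  eqn <- nuclear_charge_interaction(geom, charges)

  eri_source <- if (config$mode == "stored") {
    eri_tensor(geom, basis)
  } else {
    list(geom = geom, basis = basis)
  }
  X <- orthogonalizer(S, config$orthogonalizer)

  solve_orbitals <- function(F) {
    Fp <- t(X) %*% F %*% X
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    list(C = C, eps = ev$values[ord])
  }

  # core guess
  orb <- solve_orbitals(h)
  P <- if (nocc > 0) tcrossprod(orb$C[, seq_len(nocc), drop = FALSE]) else
    matrix(0, n, n)
  e_old <- Inf
  fock_hist <- list(); err_hist <- list()
  log <- data.frame(iteration = integer(0), energy = numeric(0),
                    delta_e = numeric(0), diis_error = numeric(0))
  converged <- FALSE
  iter <- 0L
  diagnostic <- NULL
  for (iter in seq_len(config$max_iterations)) {
    F <- build_fock(P, h, eri_source)
    e_elec <- sum(P * (h + F))
    err <- F %*% P %*% S - S %*% P %*% F
    diis_err <- max(abs(err))
    if (config$diis_depth > 0L && diis_err > 1e-11) {
      fock_hist <- c(fock_hist, list(F))
      err_hist <- c(err_hist, list(err))
      if (length(fock_hist) > config$diis_depth) {
        fock_hist <- fock_hist[-1L]; err_hist <- err_hist[-1L]
      }
      F_use <- diis_extrapolate(fock_hist, err_hist)
    } else {
      F_use <- F
    }
    orb <- solve_orbitals(F_use)
    P_new <- if (nocc > 0) tcrossprod(orb$C[, seq_len(nocc), drop = FALSE])
             else matrix(0, n, n)
    if (config$diis_depth == 0L && config$damping > 0 && iter > 1L) {
      P_new <- (1 - config$damping) * P_new + config$damping * P
    }
    drmsd <- sqrt(mean((P_new - P)^2))
    de <- e_elec - e_old
    log <- rbind(log, data.frame(iteration = iter, energy = e_elec,
                                 delta_e = de, diis_error = diis_err))
    if (config$verbose) {
      message(sprintf("SCF %3d  E = %.10f  dE = %.3e  err = %.3e",
                      iter, e_elec, de, diis_err))
    }
    if (abs(de) < config$energy_tolerance &&
        drmsd < config$density_rmsd_tolerance) {
      converged <- TRUE
      P <- P_new
      break
    }
    P <- P_new
    e_old <- e_elec
  }
  F <- build_fock(P, h, eri_source)
  e_elec <- sum(P * (h + F))
  if (!converged) {
    diagnostic <- sprintf(
      "SCF not converged in %d iterations (last dE %.3e, DIIS error %.3e)",
      iter, log$delta_e[nrow(log)], log$diis_error[nrow(log)])
    warning(diagnostic)
  }
  chg_elec <- 2 * sum(P * Vext)
  structure(list(
    mo_coefficients = orb$C,
    orbital_energies = orb$eps,
    density = P,
    electronic_energy = e_elec,
    nuclear_repulsion = enn,
    embedding_energy_terms = list(charge_nucleus = eqn,
                                  charge_electron = chg_elec),
    total_energy = e_elec + enn + eqn,
    converged = converged,
    iterations = iter,
    n_occ = nocc,
    overlap = S,
    core_hamiltonian = h,
    external_potential = Vext,
    fock = F,
    log = log,
    diagnostic = diagnostic,
    geom = geom, basis = basis, charges = charges, config = config
  ), class = "qmmd_scf")
}

#' @export
print.qmmd_scf <- function(x, ...) {
  cat(sprintf(
    "<qmmd_scf: E_total = %.10f hartree, %s in %d iterations>\n",
    x$total_energy, if (x$converged) "converged" else "NOT CONVERGED",
    x$iterations))
  invisible(x)
}

#' Electrostatic embedding energy of a converged SCF result
#'
#' Charge-electron plus charge-nucleus interaction with the external point
#' charges, in hartree.
#'
#' @param scf a \code{qmmd_scf}.
#' @return energy in hartree.
#' @export
embedding_energy <- function(scf) {
  scf$embedding_energy_terms$charge_nucleus +
    scf$embedding_energy_terms$charge_electron
}
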