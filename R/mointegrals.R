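#' AO to MO integral transformation
#'
#' Transforms the one-electron core Hamiltonian and the two-electron
#' repulsion tensor into the molecular-orbital basis of a converged SCF
#' result, as four successive quarter transformations. The transformed
#' tensor keeps chemist notation \eqn{(pq|rs)} and the full permutational
#' symmetry.
#'
#' @param scf a \code{qmmd_scf}.
#' @param n_core number of lowest doubly occupied orbitals frozen out of the
#'   window (their mean-field contribution is folded into the effective
#'   one-electron integrals and \code{frozen_core_energy}).
#' @param n_active number of orbitals in the window, starting right after
#'   the core; \code{NULL} means all remaining orbitals.
#' @param eri optional pre-computed AO ERI tensor (recomputed when absent).
#' @return list of class \code{qmmd_mo_integrals}: \code{one_electron}
#'   (effective h in the window, hartree), \code{two_electron} (4-index MO
#'   tensor over the window), \code{frozen_core_energy} (hartree, including
#'   nuclear repulsion and charge-nucleus terms), \code{n_orb},
#'   \code{window} (orbital indices), \code{mo_coefficients} of the window.
#' @export
transform_integrals <- function(scf, n_core = 0L, n_active = NULL,
                                eri = NULL) {
  n <- nrow(scf$mo_coefficients)
  n_core <- as.integer(n_core)
  if (is.null(n_active)) n_active <- n - n_core
  if (n_core < 0L || n_active < 1L || n_core + n_active > n) {
    stop("orbital window exceeds basis dimension")
  }
  if (is.null(eri)) eri <- eri_tensor(scf$geom, scf$basis)
  window <- (n_core + 1L):(n_core + n_active)
  Call <- scf$mo_coefficients[, seq_len(n_core + n_active), drop = FALSE]
  # four quarter transformations over the core+active window
  m <- ncol(Call)
  g <- eri
  for (pass in 1:4) {
    dim(g) <- c(dim(g)[1], prod(dim(g)[-1]))
    g <- crossprod(Call, g)                 # contract leading AO index
    dim(g) <- c(m, rep(n, 4L - pass), rep(m, pass - 1L))
    # cycle so the next untransformed index leads
    g <- aperm(g, c(2:4, 1))
  }
  h_mo <- crossprod(Call, scf$core_hamiltonian %*% Call)

  core <- seq_len(n_core)
  e_frozen <- scf$nuclear_repulsion +
    scf$embedding_energy_terms$charge_nucleus
  h_eff <- h_mo[window, window, drop = FALSE]
  if (n_core > 0L) {
    e_frozen <- e_frozen + 2 * sum(diag(h_mo)[core])
    for (i in core) for (j in core) {
      e_frozen <- e_frozen + 2 * g[i, i, j, j] - g[i, j, j, i]
    }
    for (i in core) {
      h_eff <- h_eff + 2 * g[window, window, i, i] -
        g[window, i, i, window]
    }
  }
  structure(list(one_electron = h_eff,
                 two_electron = g[window, window, window, window,
                                  drop = FALSE],
                 frozen_core_energy = e_frozen,
                 n_orb = n_active,
                 window = window,
                 mo_coefficients = scf$mo_coefficients[, window,
                                                       drop = FALSE]),
            class = "qmmd_mo_integrals")
}

#' Second-order Moller-Plesset correlation energy
#'
#' Closed-shell MP2 correction from MO integrals over the full orbital
#' space (no frozen core inside the window).
#'
#' @param mo a \code{qmmd_mo_integrals} spanning occupied and virtual
#'   orbitals.
#' @param orbital_energies orbital energies matching the window, hartree.
#' @param n_occ number of doubly occupied orbitals inside the window.
#' @return MP2 correlation energy, hartree (non-positive for a ground-state
#'   RHF reference).
#' @export
mp2_energy <- function(mo, orbital_energies, n_occ) {
  n <- mo$n_orb
  if (n_occ >= n) return(0)
  occ <- seq_len(n_occ)
  virt <- (n_occ + 1L):n
  g <- mo$two_electron
  eps <- orbital_energies
  e2 <- 0
  for (i in occ) for (j in occ) for (a in virt) for (b in virt) {
    denom <- eps[i] + eps[j] - eps[a] - eps[b]
    if (abs(denom) < 1e-12) {
      stop(sprintf("zero MP2 denominator for orbitals (%d,%d)->(%d,%d)",
                   i, j, a, b))
    }
    e2 <- e2 + g[i, a, j, b] * (2 * g[i, a, j, b] - g[i, b, j, a]) / denom
  }
  e2
}

#' Configuration interaction singles (singlet block)
#'
#' Builds and diagonalizes the spin-adapted singlet singles Hamiltonian
#' \eqn{A_{ia,jb} = \delta_{ij}\delta_{ab}(\epsilon_a-\epsilon_i) +
#' 2(ia|jb) - (ij|ab)}; the triplet block is excluded by construction, so
#' the dimension is \code{n_occ * n_virt}.
#'
#' @param mo a \code{qmmd_mo_integrals} over occupied + virtual orbitals.
#' @param orbital_energies orbital energies for the window, hartree.
#' @param n_occ doubly occupied orbital count in the window.
#' @param n_states number of excited states requested.
#' @param reference_energy energy added to the excitation energies to form
#'   total state energies (typically the RHF total energy), hartree.
#' @return list of class \code{qmmd_ci}: \code{state_energies} (total,
#'   ascending), \code{excitation_energies}, \code{ci_vectors}
#'   (columns, orthonormal, over the \code{ia} product space with occupied
#'   index fastest), \code{n_determinants} (singles-space dimension).
#' @export
cis_states <- function(mo, orbital_energies, n_occ, n_states,
                       reference_energy = 0) {
  n <- mo$n_orb
  n_virt <- n - n_occ
  ndim <- n_occ * n_virt
  if (ndim < 1L) stop("CIS needs at least one occupied-virtual pair")
  if (n_states > ndim) {
    stop(sprintf("n_states (%d) exceeds singles dimension (%d)",
                 n_states, ndim))
  }
  occ <- seq_len(n_occ); virt <- (n_occ + 1L):n
  eps <- orbital_energies
  g <- mo$two_electron
  A <- matrix(0, ndim, ndim)
  idx <- function(i, a) (a - n_occ - 1L) * n_occ + i
  for (i in occ) for (a in virt) for (j in occ) for (b in virt) {
    v <- 2 * g[i, a, j, b] - g[i, j, a, b]
    if (i == j && a == b) v <- v + eps[a] - eps[i]
    A[idx(i, a), idx(j, b)] <- v
  }
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  sel <- ord[seq_len(n_states)]
  structure(list(state_energies = reference_energy + ev$values[sel],
                 excitation_energies = ev$values[sel],
                 ci_vectors = ev$vectors[, sel, drop = FALSE],
                 n_determinants = ndim,
                 n_occ = n_occ, n_virt = n_virt),
            class = "qmmd_ci")
}
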