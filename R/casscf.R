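# full-space MO integrals for a given coefficient matrix
.mo_full <- function(C, h_ao, eri_ao) {
  n <- ncol(C)
  g <- eri_ao
  nb <- nrow(C)
  for (pass in 1:4) {
    dim(g) <- c(dim(g)[1], prod(dim(g)[-1]))
    g <- crossprod(C, g)
    dim(g) <- c(n, rep(nb, 4L - pass), rep(n, pass - 1L))
    g <- aperm(g, c(2:4, 1))
  }
  list(h = crossprod(C, h_ao %*% C), g = g)
}

# state-averaged generalized Fock and orbital gradient.
# core: indices 1..nc; active: nc+1..nc+na; virtual: rest.
.orbital_gradient <- function(h, g, nc, na, rdm1, rdm2) {
  n <- nrow(h)
  core <- seq_len(nc)
  act <- nc + seq_len(na)
  # inactive Fock
  Fi <- h
  for (i in core) {
    Fi <- Fi + 2 * g[, , i, i] - g[, i, i, ]
  }
  # active Fock
  Fa <- matrix(0, n, n)
  for (v in seq_len(na)) for (w in seq_len(na)) {
    Fa <- Fa + rdm1[v, w] *
      (g[, , act[v], act[w]] - 0.5 * g[, act[v], act[w], ])
  }
  Fgen <- matrix(0, n, n)
  if (nc > 0L) Fgen[core, ] <- 2 * (Fi + Fa)[core, ]
  if (na > 0L) {
    for (v in seq_len(na)) {
      row <- rdm1[v, ] %*% Fi[act, , drop = FALSE]  # sum_w gamma_vw Fi_wn
      Q <- numeric(n)
      for (w in seq_len(na)) for (x in seq_len(na)) for (y in seq_len(na)) {
        Q <- Q + rdm2[v, w, x, y] * g[, act[w], act[x], act[y]]
      }
      Fgen[act[v], ] <- as.vector(row) + Q
    }
  }
  # with the rotation convention C' = C exp(kappa):
  # dE/dkappa_mn = 2 (F_nm - F_mn)
  grad <- 2 * (t(Fgen) - Fgen)
  # redundant rotations carry no information: zero the within-space blocks
  grad[core, core] <- 0
  grad[act, act] <- 0
  virt <- setdiff(seq_len(n), c(core, act))
  grad[virt, virt] <- 0
  list(gradient = grad, Fi = Fi, Fa = Fa)
}

.expm_antisym <- function(K) {
  # exp of an antisymmetric matrix via the eigendecomposition of iK
  # (real orthogonal result); Pade via Matrix::expm is equally fine
  as.matrix(Matrix::expm(Matrix::Matrix(K)))
}

#' State-averaged CASSCF
#'
#' Two-step optimizer: a CASCI solve over the current orbitals alternates
#' with an orbital-rotation update driven by the state-averaged generalized
#' Fock matrix built from the SA one- and two-particle density matrices.
#' One single set of molecular orbitals is optimized for the weighted state
#' average, so all states share orbitals (the protocol used for
#' excited-state dynamics here). A backtracking line search keeps the SA
#' energy monotonically non-increasing.
#'
#' @param geom a \code{qmmd_geometry}.
#' @param basis a \code{qmmd_basis}.
#' @param charges external \code{qmmd_charges} (electrostatic embedding).
#' @param cas a \code{\link{cas_space}}.
#' @param n_states states entering the average.
#' @param weights averaging weights, sum to 1 (default equal).
#' @param energy_tolerance convergence on the SA energy change, hartree.
#' @param gradient_tolerance convergence on the orbital-gradient max-norm.
#' @param max_macro_iterations macro-iteration cap; exceeding it with an
#'   oscillating energy is an error carrying the energy history.
#' @param scf optional converged \code{qmmd_scf} to start from.
#' @param solver CI eigensolver passed to \code{\link{casci}}.
#' @return list of class \code{qmmd_casscf}: \code{ci} (final
#'   \code{qmmd_casci}), \code{mo_coefficients}, \code{state_energies},
#'   \code{sa_energy}, \code{gradient_norm}, \code{energy_history},
#'   \code{converged}, \code{iterations}, and the underlying \code{scf}.
#' @export
sa_casscf <- function(geom, basis, charges = no_charges(), cas,
                      n_states = 1L, weights = NULL,
                      energy_tolerance = 1e-8, gradient_tolerance = 1e-5,
                      max_macro_iterations = 100L, scf = NULL,
                      solver = "davidson") {
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  if (abs(sum(weights) - 1) > 1e-10) stop("weights must sum to 1")
  if (is.null(scf)) scf <- run_rhf(geom, basis, charges)
  eri_ao <- eri_tensor(geom, basis)
  C <- scf$mo_coefficients
  n <- ncol(C)
  nc <- (2L * scf$n_occ - cas$n_active_electrons) / 2
  if (nc != round(nc) || nc < 0) stop("inconsistent active electron count")
  nc <- as.integer(nc)
  na <- cas$n_active_orbitals

  scf_at <- function(C) { s <- scf; s$mo_coefficients <- C; s }
  hist_e <- numeric(0)
  ci <- NULL
  grad_norm <- Inf
  converged <- FALSE
  e_prev <- Inf
  for (it in seq_len(max_macro_iterations)) {
    ci <- casci(scf_at(C), cas, n_states = n_states, weights = weights,
                solver = solver, eri = eri_ao)
    e_sa <- sum(weights * ci$state_energies)
    hist_e <- c(hist_e, e_sa)
    full <- .mo_full(C, scf$core_hamiltonian, eri_ao)
    og <- .orbital_gradient(full$h, full$g, nc, na, ci$sa_rdm1, ci$sa_rdm2)
    grad_norm <- max(abs(og$gradient))
    if (grad_norm < gradient_tolerance &&
        abs(e_prev - e_sa) < energy_tolerance) {
      converged <- TRUE
      break
    }
    e_prev <- e_sa
    # preconditioned steepest-descent step with backtracking
    denom <- outer(diag(og$Fi + og$Fa), diag(og$Fi + og$Fa),
                   function(a, b) 4 * abs(b - a))
    denom[denom < 0.5] <- 0.5
    K0 <- -og$gradient / denom
    e_try <- function(step) {
      Ctry <- C %*% .expm_antisym(step * K0)
      citry <- tryCatch(
        casci(scf_at(Ctry), cas, n_states = n_states, weights = weights,
              solver = solver, eri = eri_ao),
        error = function(e) NULL)
      if (is.null(citry)) return(list(e = Inf, C = Ctry))
      list(e = sum(weights * citry$state_energies), C = Ctry)
    }
    step <- 1
    improved <- FALSE
    for (ls in 1:12) {
      tr <- e_try(step)
      if (tr$e <= e_sa + 1e-12) {
        # greedy expansion: CASCI solves are cheap at desk scale, so
        # keep doubling while the energy still drops
        for (gr in 1:6) {
          tr2 <- e_try(2 * step)
          if (tr2$e < tr$e) { step <- 2 * step; tr <- tr2 } else break
        }
        C <- tr$C
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      # gradient direction yields no decrease at machine resolution:
      # treat as stationary if the gradient is at least small-ish
      if (grad_norm < 50 * gradient_tolerance) { converged <- TRUE; break }
      stop(sprintf(
        paste0("SA-CASSCF oscillation: no descent step found at ",
               "iteration %d; energy history: %s"),
        it, paste(sprintf("%.10f", hist_e), collapse = ", ")))
    }
  }
  if (!converged) {
    stop(sprintf(
      "SA-CASSCF did not converge in %d macro-iterations; history: %s",
      max_macro_iterations,
      paste(sprintf("%.10f", utils::tail(hist_e, 8)), collapse = ", ")))
  }
  structure(list(ci = ci, mo_coefficients = C,
                 state_energies = ci$state_energies,
                 sa_energy = sum(weights * ci$state_energies),
                 gradient_norm = grad_norm,
                 energy_history = hist_e,
                 converged = converged, iterations = length(hist_e),
                 weights = weights, cas = cas, scf = scf),
            class = "qmmd_casscf")
}

#' @export
print.qmmd_casscf <- function(x, ...) {
  cat(sprintf(
    "<qmmd_casscf: SA energy %.10f hartree, |g| = %.2e, %d macro-iter>\n",
    x$sa_energy, x$gradient_norm, x$iterations))
  for (i in seq_along(x$state_energies)) {
    cat(sprintf("  state %d: %.10f hartree\n", i - 1L, x$state_energies[i]))
  }
  invisible(x)
}
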