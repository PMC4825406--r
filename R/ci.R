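#' Complete-active-space definition
#'
#' @param n_active_electrons electrons in the active space.
#' @param n_active_orbitals spatial orbitals in the active space.
#' @param n_core_orbitals doubly occupied orbitals below the active space
#'   (folded into the effective integrals).
#' @param spin_projection Ms, half-integer; alpha and beta electron counts
#'   are \code{nel/2 +- Ms}.
#' @return list of class \code{qmmd_cas}.
#' @export
cas_space <- function(n_active_electrons, n_active_orbitals,
                      n_core_orbitals = 0L, spin_projection = 0) {
  ne <- as.integer(n_active_electrons)
  no <- as.integer(n_active_orbitals)
  if (ne < 0L || ne > 2L * no) {
    stop("need 0 <= n_active_electrons <= 2 * n_active_orbitals")
  }
  na <- ne / 2 + spin_projection
  nb <- ne / 2 - spin_projection
  if (na != round(na) || nb != round(nb) || na < 0 || nb < 0 ||
      na > no || nb > no) {
    stop("spin projection incompatible with electron and orbital counts")
  }
  structure(list(n_active_electrons = ne, n_active_orbitals = no,
                 n_core_orbitals = as.integer(n_core_orbitals),
                 spin_projection = spin_projection,
                 n_alpha = as.integer(na), n_beta = as.integer(nb)),
            class = "qmmd_cas")
}

# all length-k subsets of 1..n in lexicographic order, as a list
.strings <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  cols <- utils::combn(n, k)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

.string_key <- function(occ) paste(occ, collapse = ",")

# single-excitation operator tables: for each orbital pair (p,q) a sparse
# matrix E with E[I', I] = <I'| a_p^dagger a_q |I>
.excitation_tables <- function(strings, norb) {
  nstr <- length(strings)
  keyidx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nstr)) assign(.string_key(strings[[i]]), i, keyidx)
  tabs <- vector("list", norb * norb)
  trip <- lapply(seq_len(norb * norb), function(k) list(i = integer(0),
                                                        j = integer(0),
                                                        x = numeric(0)))
  for (I in seq_len(nstr)) {
    occ <- strings[[I]]
    for (qi in seq_along(occ)) {
      q <- occ[qi]
      sign_q <- if (qi %% 2L == 1L) 1 else -1   # (-1)^(position-1)
      rest <- occ[-qi]
      for (p in seq_len(norb)) {
        if (p != q && p %in% rest) next
        newocc <- sort(c(rest, p))
        sign_p <- if (sum(rest < p) %% 2L == 0L) 1 else -1
        J <- get(.string_key(newocc), keyidx)
        k <- (q - 1L) * norb + p            # column-major (p,q) slot
        trip[[k]]$i <- c(trip[[k]]$i, J)
        trip[[k]]$j <- c(trip[[k]]$j, I)
        trip[[k]]$x <- c(trip[[k]]$x, sign_q * sign_p)
      }
    }
  }
  for (k in seq_len(norb * norb)) {
    tabs[[k]] <- Matrix::sparseMatrix(i = trip[[k]]$i, j = trip[[k]]$j,
                                      x = trip[[k]]$x,
                                      dims = c(nstr, nstr))
  }
  tabs
}

#' Enumerate the determinant basis of a CAS space
#'
#' Alpha and beta strings are enumerated lexicographically; the determinant
#' index runs with the alpha string fastest. The count is
#' \eqn{C(n_{orb}, n_\alpha) \cdot C(n_{orb}, n_\beta)}.
#'
#' @param cas a \code{\link{cas_space}}.
#' @return list of class \code{qmmd_detspace}: \code{alpha_strings},
#'   \code{beta_strings} (lists of occupied-orbital vectors),
#'   \code{n_determinants}, \code{alpha_index}/\code{beta_index} per
#'   determinant, and cached excitation tables.
#' @export
enumerate_determinants <- function(cas) {
  no <- cas$n_active_orbitals
  astr <- .strings(no, cas$n_alpha)
  bstr <- .strings(no, cas$n_beta)
  na <- length(astr); nb <- length(bstr)
  structure(list(alpha_strings = astr, beta_strings = bstr,
                 n_alpha_strings = na, n_beta_strings = nb,
                 n_determinants = na * nb,
                 alpha_index = rep(seq_len(na), times = nb),
                 beta_index = rep(seq_len(nb), each = na),
                 norb = no,
                 Ea = .excitation_tables(astr, no),
                 Eb = .excitation_tables(bstr, no),
                 cas = cas),
            class = "qmmd_detspace")
}

# apply E_pq = E^alpha_pq + E^beta_pq to a CI matrix C (nstra x nstrb)
.apply_Epq <- function(det, p, q, C) {
  k <- (q - 1L) * det$norb + p
  as.matrix(det$Ea[[k]] %*% C) + as.matrix(C %*% Matrix::t(det$Eb[[k]]))
}

#' Direct-CI sigma vector
#'
#' Computes \eqn{\sigma = H c} for the active-space Hamiltonian without ever
#' materializing the CI matrix, using the alpha/beta string factorization:
#' \eqn{\sigma = \sum_{pq} h'_{pq} E_{pq} c + \tfrac12 \sum_{pq} E_{pq}
#' \sum_{rs}(pq|rs) E_{rs} c} with
#' \eqn{h'_{pq} = h_{pq} - \tfrac12\sum_r (pr|rq)}.
#'
#' @param ci_vector coefficient vector over the determinant basis.
#' @param mo active-space integrals: list with \code{one_electron} (matrix)
#'   and \code{two_electron} (4-index array), both over active orbitals.
#' @param det a \code{qmmd_detspace} (see
#'   \code{\link{enumerate_determinants}}).
#' @return numeric vector \eqn{H c}.
#' @export
sigma_vector <- function(ci_vector, mo, det) {
  no <- det$norb
  na <- det$n_alpha_strings; nb <- det$n_beta_strings
  if (length(ci_vector) != na * nb) stop("CI vector dimension mismatch")
  C <- matrix(ci_vector, na, nb)
  g <- mo$two_electron
  h <- mo$one_electron
  hp <- h - 0.5 * apply(g, c(1, 4), function(m) sum(diag(m)))
  # G[, pq] = E_pq c
  G <- matrix(0, na * nb, no * no)
  for (q in seq_len(no)) for (p in seq_len(no)) {
    k <- (q - 1L) * no + p
    G[, k] <- .apply_Epq(det, p, q, C)
  }
  sig <- G %*% as.vector(hp)
  W <- matrix(aperm(g, c(3, 4, 1, 2)), no * no, no * no)  # W[rs, pq]
  Tm <- G %*% W
  for (q in seq_len(no)) for (p in seq_len(no)) {
    k <- (q - 1L) * no + p
    sig <- sig + 0.5 * as.vector(.apply_Epq(det, p, q,
                                            matrix(Tm[, k], na, nb)))
  }
  as.vector(sig)
}

# ---------------------------------------------------------------------------
# independent dense route: Slater-Condon rules over spin-orbitals
# (alpha orbital k -> 2k-1, beta orbital k -> 2k); determinants keep the
# alpha block first, matching the phase convention of the string tables

.so_list <- function(aocc, bocc) c(2L * aocc - 1L, 2L * bocc)

# antisymmetrized physicist integral <mn||pq> over spin-orbitals
.so_anti <- function(g, m, n, p, q) {
  sp <- function(s) (s + 1L) %/% 2L
  ss <- function(s) s %% 2L
  d <- 0
  if (ss(m) == ss(p) && ss(n) == ss(q)) {
    d <- d + g[sp(m), sp(p), sp(n), sp(q)]
  }
  if (ss(m) == ss(q) && ss(n) == ss(p)) {
    d <- d - g[sp(m), sp(q), sp(n), sp(p)]
  }
  d
}

.slater_element <- function(D1, D2, h, g) {
  sp <- function(s) (s + 1L) %/% 2L
  ss <- function(s) s %% 2L
  diff1 <- setdiff(D1, D2); diff2 <- setdiff(D2, D1)
  nd <- length(diff1)
  if (nd > 2L) return(0)
  common <- intersect(D1, D2)
  if (nd == 0L) {
    e <- sum(vapply(D1, function(m) h[sp(m), sp(m)], numeric(1)))
    for (i in seq_along(D1)) for (j in seq_along(D1)) {
      if (i < j) e <- e + .so_anti(g, D1[i], D1[j], D1[i], D1[j])
    }
    return(e)
  }
  sgn <- (-1)^(sum(match(diff1, D1)) + sum(match(diff2, D2)))
  if (nd == 1L) {
    m <- diff1[1L]; p <- diff2[1L]
    if (ss(m) != ss(p)) return(0)
    e <- h[sp(m), sp(p)]
    for (n in common) e <- e + .so_anti(g, m, n, p, n)
    return(sgn * e)
  }
  m <- diff1[1L]; n <- diff1[2L]; p <- diff2[1L]; q <- diff2[2L]
  sgn * .so_anti(g, m, n, p, q)
}

#' Dense active-space CI Hamiltonian (oracle route)
#'
#' Builds the full determinant Hamiltonian by Slater-Condon rules over
#' spin-orbitals. Independent of the string-driven sigma build; intended for
#' small spaces and cross-validation.
#'
#' @inheritParams sigma_vector
#' @return dense symmetric matrix of dimension \code{n_determinants}.
#' @export
ci_hamiltonian_dense <- function(mo, det) {
  nd <- det$n_determinants
  dets <- lapply(seq_len(nd), function(d) {
    .so_list(det$alpha_strings[[det$alpha_index[d]]],
             det$beta_strings[[det$beta_index[d]]])
  })
  H <- matrix(0, nd, nd)
  for (i in seq_len(nd)) for (j in i:nd) {
    H[i, j] <- H[j, i] <- .slater_element(dets[[i]], dets[[j]],
                                          mo$one_electron, mo$two_electron)
  }
  H
}

# diagonal of the CI Hamiltonian (Davidson/LOBPCG preconditioner)
.ci_diagonal <- function(mo, det) {
  nd <- det$n_determinants
  vapply(seq_len(nd), function(d) {
    D <- .so_list(det$alpha_strings[[det$alpha_index[d]]],
                  det$beta_strings[[det$beta_index[d]]])
    .slater_element(D, D, mo$one_electron, mo$two_electron)
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# iterative eigensolvers (operator interface)

.orthonormalize <- function(V, against = NULL, tol = 1e-10) {
  if (!is.null(against)) V <- V - against %*% crossprod(against, V)
  keep <- NULL
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    if (!is.null(keep)) v <- v - keep %*% crossprod(keep, v)
    nv <- sqrt(sum(v^2))
    if (nv > tol) keep <- cbind(keep, v / nv)
  }
  keep
}

#' Iterative lowest-eigenpair solver (Davidson or LOBPCG)
#'
#' Finds the lowest \code{n_states} eigenpairs of a symmetric operator given
#' only its action on vectors and its diagonal (used as preconditioner).
#' Both back-ends converge each state to a residual norm below \code{tol}.
#'
#' @param op function taking a matrix of column vectors and returning the
#'   operator applied to each column.
#' @param diagonal the operator diagonal (length n).
#' @param n_states number of lowest eigenpairs.
#' @param solver \code{"davidson"} or \code{"lobpcg"}.
#' @param tol residual-norm convergence threshold.
#' @param max_iterations iteration cap; exceeding it is an error carrying
#'   the best residual norms.
#' @return list with \code{values} (ascending), \code{vectors}
#'   (orthonormal columns), \code{residual_norms}, \code{iterations}.
#' @export
solve_ci <- function(op, diagonal, n_states,
                     solver = c("davidson", "lobpcg"), tol = 1e-6,
                     max_iterations = 200L) {
  solver <- match.arg(solver)
  n <- length(diagonal)
  if (n_states < 1L || n_states > n) stop("invalid n_states")
  # initial guesses: unit vectors at the smallest diagonal entries
  init <- function(k) {
    V <- matrix(0, n, k)
    ord <- order(diagonal)[seq_len(k)]
    V[cbind(ord, seq_len(k))] <- 1
    V
  }
  if (n <= max(3L * n_states, 12L)) {
    # space too small for a subspace method: diagonalize via op columns
    H <- op(diag(1, n))
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    sel <- order(ev$values)[seq_len(n_states)]
    return(list(values = ev$values[sel],
                vectors = ev$vectors[, sel, drop = FALSE],
                residual_norms = rep(0, n_states), iterations = 1L))
  }
  if (solver == "davidson") .davidson(op, diagonal, n_states, init, tol,
                                      max_iterations)
  else .lobpcg(op, diagonal, n_states, init, tol, max_iterations)
}

.ritz <- function(op, V) {
  HV <- op(V)
  Hs <- crossprod(V, HV)
  ev <- eigen((Hs + t(Hs)) / 2, symmetric = TRUE)
  ord <- order(ev$values)            # eigen() sorts descending
  list(HV = HV, values = ev$values[ord], rot = ev$vectors[, ord,
                                                          drop = FALSE])
}

.davidson <- function(op, diagonal, k, init, tol, maxit) {
  n <- length(diagonal)
  V <- init(k)
  maxdim <- min(n, max(8L * k, 40L))
  for (it in seq_len(maxit)) {
    V <- .orthonormalize(V)
    r <- .ritz(op, V)
    vals <- r$values[seq_len(k)]
    X <- V %*% r$rot[, seq_len(k), drop = FALSE]
    HX <- r$HV %*% r$rot[, seq_len(k), drop = FALSE]
    R <- HX - X %*% diag(vals, k)
    rn <- sqrt(colSums(R^2))
    if (all(rn <= tol)) {
      return(list(values = vals, vectors = X, residual_norms = rn,
                  iterations = it))
    }
    # preconditioned residuals
    newdirs <- sapply(seq_len(k), function(j) {
      d <- diagonal - vals[j]
      d[abs(d) < 1e-8] <- 1e-8
      R[, j] / d
    })
    if (ncol(V) + k > maxdim) V <- X        # collapse / restart
    V <- cbind(V, newdirs)
  }
  stop(sprintf(
    "Davidson did not converge in %d iterations; residual norms: %s",
    maxit, paste(signif(rn, 3), collapse = " ")))
}

.lobpcg <- function(op, diagonal, k, init, tol, maxit) {
  n <- length(diagonal)
  X <- .orthonormalize(init(k))
  P <- NULL
  for (it in seq_len(maxit)) {
    HX <- op(X)
    lam <- colSums(X * HX)
    R <- HX - X %*% diag(lam, k)
    rn <- sqrt(colSums(R^2))
    if (all(rn <= tol)) {
      # final Rayleigh-Ritz for ordered, orthonormal output
      r <- .ritz(op, .orthonormalize(X))
      X <- .orthonormalize(X) %*% r$rot[, seq_len(k), drop = FALSE]
      return(list(values = r$values[seq_len(k)], vectors = X,
                  residual_norms = rn, iterations = it))
    }
    W <- sapply(seq_len(k), function(j) {
      d <- diagonal - lam[j]
      d[abs(d) < 1e-8] <- 1e-8
      R[, j] / d
    })
    S <- .orthonormalize(cbind(X, W, P))
    r <- .ritz(op, S)
    Xnew <- S %*% r$rot[, seq_len(k), drop = FALSE]
    P <- Xnew - X %*% crossprod(X, Xnew)
    P <- if (is.null(.orthonormalize(P))) NULL else .orthonormalize(P)
    X <- Xnew
  }
  stop(sprintf(
    "LOBPCG did not converge in %d iterations; residual norms: %s",
    maxit, paste(signif(rn, 3), collapse = " ")))
}

# ---------------------------------------------------------------------------

# state RDMs from a CI vector: gamma_pq = <c|E_pq|c>,
# Gamma_pqrs = <c|E_pq E_rs|c> - delta_qr <c|E_ps|c>
.ci_rdms <- function(cvec, det) {
  no <- det$norb
  na <- det$n_alpha_strings; nb <- det$n_beta_strings
  C <- matrix(cvec, na, nb)
  G <- matrix(0, na * nb, no * no)
  for (q in seq_len(no)) for (p in seq_len(no)) {
    G[, (q - 1L) * no + p] <- .apply_Epq(det, p, q, C)
  }
  g1 <- matrix(crossprod(G, as.vector(C)), no, no)  # gamma[p,q]
  # <E_pq E_rs> = <E_qp c, E_rs c>
  M <- crossprod(G)                                  # M[(qp),(rs)]
  d2 <- array(0, c(no, no, no, no))
  for (p in seq_len(no)) for (q in seq_len(no)) {
    kqp <- (p - 1L) * no + q                         # column (q,p)
    for (r in seq_len(no)) for (s in seq_len(no)) {
      v <- M[kqp, (s - 1L) * no + r]
      if (q == r) v <- v - g1[p, s]
      d2[p, q, r, s] <- v
    }
  }
  list(rdm1 = g1, rdm2 = d2)
}

# <S^2> = Ms(Ms+1) + n_beta - sum_pq <a+_pa a_qa a+_qb a_pb>
.ci_s2 <- function(cvec, det) {
  cas <- det$cas
  no <- det$norb
  na <- det$n_alpha_strings; nb <- det$n_beta_strings
  C <- matrix(cvec, na, nb)
  ms <- cas$spin_projection
  term <- 0
  for (p in seq_len(no)) for (q in seq_len(no)) {
    ka <- (q - 1L) * no + p        # alpha E_pq
    kb <- (p - 1L) * no + q        # beta  E_qp
    term <- term + sum(C * as.matrix(det$Ea[[ka]] %*% C %*%
                                       Matrix::t(det$Eb[[kb]])))
  }
  ms * (ms + 1) + cas$n_beta - term
}

#' CASCI: configuration interaction in a complete active space
#'
#' Freezes the lowest orbitals of a converged SCF result, transforms the
#' integrals into the active window, and solves for the lowest states of the
#' determinant-basis active-space Hamiltonian with a direct-CI iterative
#' eigensolver. Returned energies are total energies (electronic + nuclear
#' repulsion + charge-nucleus embedding).
#'
#' @param scf a \code{qmmd_scf}.
#' @param cas a \code{\link{cas_space}}.
#' @param n_states number of states.
#' @param weights state-averaging weights (default equal); must sum to 1.
#' @param solver \code{"davidson"} or \code{"lobpcg"}.
#' @param eri optional precomputed AO ERI tensor.
#' @return list of class \code{qmmd_casci}: \code{state_energies} (hartree,
#'   ascending), \code{ci_vectors} (orthonormal columns),
#'   \code{one_rdm_per_state}, \code{two_rdm_per_state}, state-averaged
#'   \code{sa_rdm1}/\code{sa_rdm2}, \code{s2} per state,
#'   \code{n_determinants}, the \code{detspace} and active \code{mo}
#'   integrals.
#' @export
casci <- function(scf, cas, n_states = 1L, weights = NULL,
                  solver = c("davidson", "lobpcg"), eri = NULL) {
  solver <- match.arg(solver)
  nelec <- 2L * scf$n_occ
  n_core <- (nelec - cas$n_active_electrons) / 2
  if (n_core != round(n_core) || n_core < 0) {
    stop("active electron count incompatible with total electron count")
  }
  n_core <- as.integer(n_core)
  if (n_core + cas$n_active_orbitals > scf$basis$n_basis) {
    stop("active space exceeds basis dimension")
  }
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  if (length(weights) != n_states || abs(sum(weights) - 1) > 1e-10) {
    stop("weights must have length n_states and sum to 1")
  }
  mo <- transform_integrals(scf, n_core = n_core,
                            n_active = cas$n_active_orbitals, eri = eri)
  det <- enumerate_determinants(cas)
  if (n_states > det$n_determinants) {
    stop("more states requested than determinants")
  }
  na <- det$n_alpha_strings; nb <- det$n_beta_strings
  op <- function(V) {
    apply(V, 2, function(v) sigma_vector(v, mo, det))
  }
  sol <- solve_ci(op, .ci_diagonal(mo, det), n_states, solver = solver)
  # deterministic tie-break for (near-)degenerate states: energy, then index
  # of the largest CI coefficient
  ord <- order(sol$values,
               apply(abs(sol$vectors), 2, which.max))
  vals <- sol$values[ord]
  vecs <- sol$vectors[, ord, drop = FALSE]
  rdms <- lapply(seq_len(n_states), function(j) .ci_rdms(vecs[, j], det))
  sa1 <- Reduce(`+`, Map(function(r, w) w * r$rdm1, rdms, weights))
  sa2 <- Reduce(`+`, Map(function(r, w) w * r$rdm2, rdms, weights))
  structure(list(
    state_energies = vals + mo$frozen_core_energy,
    ci_energies = vals,
    ci_vectors = vecs,
    one_rdm_per_state = lapply(rdms, `[[`, "rdm1"),
    two_rdm_per_state = lapply(rdms, `[[`, "rdm2"),
    sa_rdm1 = sa1, sa_rdm2 = sa2,
    s2 = vapply(seq_len(n_states), function(j) .ci_s2(vecs[, j], det),
                numeric(1)),
    weights = weights,
    n_determinants = det$n_determinants,
    detspace = det, mo = mo, n_core = n_core, cas = cas
  ), class = "qmmd_casci")
}

#' @export
print.qmmd_casci <- function(x, ...) {
  cat(sprintf("<qmmd_casci: %d determinants, %d state(s)>\n",
              x$n_determinants, length(x$state_energies)))
  for (i in seq_along(x$state_energies)) {
    cat(sprintf("  state %d: %.10f hartree  <S^2> = %.4f\n", i - 1L,
                x$state_energies[i], x$s2[i]))
  }
  invisible(x)
}
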