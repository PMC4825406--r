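#' QM/MM partition of a topology
#'
#' Decomposes the system into a QM and an MM part. Bonds crossing the
#' boundary are cut and each cut bond receives one hydrogen link atom
#' (placed by \code{\link{place_link_atoms}}). Embedding charges follow the
#' charge-redistribution scheme: the MM boundary atom and its MM-bonded
#' neighbors do not interact electrostatically with the QM region; their
#' omitted charge is redistributed uniformly over the remaining MM atoms of
#' the same residue. Bonded terms with at least one QM and one MM atom are
#' kept and evaluated molecular-mechanically (boundary bonded terms).
#'
#' @param topology a \code{\link{topology_spec}}.
#' @param qm_atoms indices of the QM atoms (non-empty).
#' @return object of class \code{qmmd_partition}: \code{qm_atoms},
#'   \code{mm_atoms}, \code{cut_bonds} (2-column matrix, QM boundary atom
#'   first), \code{link_distance} (1.10 A), \code{excluded_charge_atoms},
#'   \code{redistributed_charges} (full-length vector; QM entries NA),
#'   \code{boundary_bonded_terms} (list of data.frames).
#' @export
build_partition <- function(topology, qm_atoms) {
  na <- nrow(topology$atoms)
  qm_atoms <- sort(unique(as.integer(qm_atoms)))
  if (length(qm_atoms) == 0L) stop("QM selection is empty")
  if (min(qm_atoms) < 1L || max(qm_atoms) > na) {
    stop("QM selection outside the topology")
  }
  mm_atoms <- setdiff(seq_len(na), qm_atoms)
  inqm <- logical(na); inqm[qm_atoms] <- TRUE
  b <- topology$bonds
  cut <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("qm", "mm")))
  if (nrow(b)) {
    ci <- which(xor(inqm[b$i], inqm[b$j]))
    if (length(ci)) {
      cut <- cbind(qm = ifelse(inqm[b$i[ci]], b$i[ci], b$j[ci]),
                   mm = ifelse(inqm[b$i[ci]], b$j[ci], b$i[ci]))
      cut <- cut[order(cut[, 1], cut[, 2]), , drop = FALSE]
    }
  }
  # charge redistribution
  chg <- topology$atoms$charge
  red <- chg
  red[qm_atoms] <- NA_real_
  excluded <- integer(0)
  if (nrow(cut)) {
    adj <- vector("list", na)
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
      adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    }
    for (mb in unique(cut[, 2])) {
      excluded <- c(excluded, mb, intersect(adj[[mb]], mm_atoms))
    }
    excluded <- sort(unique(excluded))
    for (res in unique(topology$atoms$residue[excluded])) {
      res_ex <- excluded[topology$atoms$residue[excluded] == res]
      omitted <- sum(red[res_ex])
      red[res_ex] <- 0
      receivers <- setdiff(
        intersect(which(topology$atoms$residue == res), mm_atoms),
        excluded)
      if (length(receivers) == 0L) {
        if (abs(omitted) > 1e-12) {
          stop(sprintf(
            "residue %s has no remaining MM atoms to receive charge",
            res))
        }
        next   # nothing to redistribute: zero omitted charge
      }
      red[receivers] <- red[receivers] + omitted / length(receivers)
    }
  }
  keep_terms <- function(df, cols) {
    if (!nrow(df)) return(df)
    m <- sapply(cols, function(cc) inqm[df[[cc]]])
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    nq <- rowSums(m)
    df[nq > 0 & nq < length(cols), , drop = FALSE]
  }
  boundary <- list(bonds = keep_terms(topology$bonds, c("i", "j")),
                   angles = keep_terms(topology$angles, c("i", "j", "k")),
                   torsions = keep_terms(topology$torsions,
                                         c("i", "j", "k", "l")))
  structure(list(qm_atoms = qm_atoms, mm_atoms = mm_atoms,
                 cut_bonds = cut, link_distance = 1.10,
                 excluded_charge_atoms = excluded,
                 redistributed_charges = red,
                 boundary_bonded_terms = boundary,
                 topology = topology),
            class = "qmmd_partition")
}

#' @export
print.qmmd_partition <- function(x, ...) {
  cat(sprintf(
    "<qmmd_partition: %d QM / %d MM atoms, %d cut bond(s)>\n",
    length(x$qm_atoms), length(x$mm_atoms), nrow(x$cut_bonds)))
  invisible(x)
}

#' Link-atom coordinates
#'
#' One hydrogen per cut bond, placed on the line from the QM boundary atom
#' to the MM boundary atom at a fixed 1.10 A from the QM boundary atom (the
#' fixed distance avoids introducing an extra degree of freedom). The link
#' atoms are appended to the QM geometry and treated as QM atoms.
#'
#' @param partition a \code{\link{build_partition}} result.
#' @param positions full-system coordinates, n x 3 Angstrom.
#' @return matrix (possibly 0-row) of link-atom coordinates, one row per
#'   cut bond.
#' @export
place_link_atoms <- function(partition, positions) {
  cut <- partition$cut_bonds
  out <- matrix(numeric(0), ncol = 3)
  if (!nrow(cut)) return(out)
  d0 <- partition$link_distance
  out <- matrix(0, nrow(cut), 3)
  for (k in seq_len(nrow(cut))) {
    xq <- positions[cut[k, 1], ]
    xm <- positions[cut[k, 2], ]
    u <- xm - xq
    r <- sqrt(sum(u^2))
    if (r < 1e-9) stop("coincident boundary atoms: link direction undefined")
    out[k, ] <- xq + d0 * u / r
  }
  out
}

#' Redistributed embedding charges
#'
#' The per-atom embedding charge map of a partition (QM atoms excluded).
#' Total MM charge is conserved exactly by construction.
#'
#' @param partition a \code{qmmd_partition}.
#' @return data.frame with \code{atom} (MM atom index) and \code{charge}.
#' @export
redistribute_charges <- function(partition) {
  mm <- partition$mm_atoms
  data.frame(atom = mm, charge = partition$redistributed_charges[mm])
}

#' Boundary bonded terms of a partition
#'
#' @param partition a \code{qmmd_partition}.
#' @return list of data.frames \code{bonds}, \code{angles},
#'   \code{torsions}: every bonded term with at least one QM and one MM
#'   atom.
#' @export
boundary_bonded_terms <- function(partition) partition$boundary_bonded_terms

#' QM method configuration for QM/MM runs
#'
#' @param method one of \code{"hf"}, \code{"mp2"}, \code{"cis"},
#'   \code{"casci"}, \code{"sa_casscf"}.
#' @param basis basis name or library (see \code{\link{load_basis}}).
#' @param state_index adiabatic state the forces follow (0 = ground).
#' @param n_states states computed for excited-state methods.
#' @param cas a \code{\link{cas_space}} for CASCI/CASSCF.
#' @param weights SA weights for \code{sa_casscf}.
#' @param scf an \code{\link{scf_config}}.
#' @param fd_displacement central-difference displacement for QM nuclear
#'   gradients, Angstrom.
#' @return list of class \code{qmmd_qm_config}.
#' @export
qm_config <- function(method = c("hf", "mp2", "cis", "casci", "sa_casscf"),
                      basis = "toy-minimal", state_index = 0L,
                      n_states = NULL, cas = NULL, weights = NULL,
                      scf = scf_config(), fd_displacement = 1e-3) {
  method <- match.arg(method)
  if (method %in% c("casci", "sa_casscf") && is.null(cas)) {
    stop("CASCI/CASSCF require a cas_space")
  }
  if (is.null(n_states)) {
    n_states <- if (state_index > 0L) state_index + 1L else 1L
  }
  if (method %in% c("cis", "casci", "sa_casscf") &&
      state_index + 1L > n_states) {
    stop("state_index outside the computed states")
  }
  structure(list(method = method, basis = basis,
                 state_index = as.integer(state_index),
                 n_states = as.integer(n_states), cas = cas,
                 weights = weights, scf = scf,
                 fd_displacement = fd_displacement),
            class = "qmmd_qm_config")
}

# run the QM method on a QM-region geometry under embedding charges.
# returns state energies (total, embedded), the followed state's full AO
# density (electron count normalization), and the SCF result.
.qm_run <- function(geomQ, basis, charges, qc) {
  scf <- run_rhf(geomQ, basis, charges, qc$scf)
  if (!scf$converged) stop("QM SCF did not converge: ", scf$diagnostic)
  Dscf <- 2 * scf$density
  st <- qc$state_index
  if (qc$method == "hf") {
    return(list(energies = scf$total_energy, state_energy = scf$total_energy,
                density = Dscf, scf = scf))
  }
  if (qc$method == "mp2") {
    mo <- transform_integrals(scf)
    e2 <- mp2_energy(mo, scf$orbital_energies, scf$n_occ)
    e <- scf$total_energy + e2
    return(list(energies = e, state_energy = e, density = Dscf, scf = scf,
                mp2_correction = e2))
  }
  if (qc$method == "cis") {
    mo <- transform_integrals(scf)
    nst <- max(qc$n_states - 1L, 1L)
    cis <- cis_states(mo, scf$orbital_energies, scf$n_occ, nst,
                      reference_energy = scf$total_energy)
    energies <- c(scf$total_energy, cis$state_energies)
    D <- Dscf
    if (st > 0L) {
      t_ia <- matrix(cis$ci_vectors[, st], scf$n_occ, cis$n_virt)
      occ <- seq_len(scf$n_occ)
      virt <- scf$n_occ + seq_len(cis$n_virt)
      dmo <- matrix(0, mo$n_orb, mo$n_orb)
      dmo[occ, occ] <- -tcrossprod(t_ia)
      dmo[virt, virt] <- crossprod(t_ia)
      C <- scf$mo_coefficients
      D <- Dscf + C %*% dmo %*% t(C)
    }
    return(list(energies = energies, state_energy = energies[st + 1L],
                density = D, scf = scf))
  }
  # casci / sa_casscf
  if (qc$method == "casci") {
    ci <- casci(scf, qc$cas, n_states = qc$n_states, weights = qc$weights)
    C <- scf$mo_coefficients
  } else {
    cw <- qc$weights
    if (is.null(cw)) cw <- rep(1 / qc$n_states, qc$n_states)
    cas_res <- sa_casscf(geomQ, basis, charges, qc$cas,
                         n_states = qc$n_states, weights = cw, scf = scf)
    ci <- cas_res$ci
    C <- cas_res$mo_coefficients
  }
  nc <- ci$n_core
  act <- nc + seq_len(qc$cas$n_active_orbitals)
  Cc <- C[, seq_len(nc), drop = FALSE]
  Ca <- C[, act, drop = FALSE]
  D <- 2 * tcrossprod(Cc) +
    Ca %*% ci$one_rdm_per_state[[st + 1L]] %*% t(Ca)
  list(energies = ci$state_energies, state_energy =
         ci$state_energies[st + 1L], density = D, scf = scf, ci = ci)
}

# QM-region geometry: QM atoms plus link hydrogens
.qm_geometry <- function(geom, partition, positions) {
  links <- place_link_atoms(partition, positions)
  els <- c(geom$elements[partition$qm_atoms],
           rep("H", nrow(links)))
  geometry(els, rbind(positions[partition$qm_atoms, , drop = FALSE],
                      links))
}

# embedding charge set (nonzero redistributed charges only)
.embedding_charges <- function(partition, positions) {
  mm <- partition$mm_atoms
  q <- partition$redistributed_charges[mm]
  keep <- which(abs(q) > 0)
  list(charges = point_charges(positions[mm[keep], , drop = FALSE],
                               q[keep]),
       atoms = mm[keep])
}

#' Total QM/MM energy and forces
#'
#' Assembles the additive QM/MM total energy
#' \deqn{E_{tot} = E_{QM} + E_{MM} + E_{QM/MM}, \qquad
#'       E_{QM/MM} = E_{ele} + E_{vdW}}
#' where the electrostatic coupling E_ele (charge-electron plus
#' charge-nucleus) comes from the embedded QM calculation over the
#' redistributed MM charges, and E_vdW is the Lennard-Jones interaction
#' between QM and MM atoms evaluated by the MM engine. QM nuclear forces
#' are central finite differences of the followed state energy; link-atom
#' forces are projected onto the two boundary atoms by the chain rule of
#' the placement rule; forces on embedding charges use the
#' frozen-density Hellmann-Feynman field (exact for variational
#' wavefunctions).
#'
#' @param positions full-system coordinates, Angstrom.
#' @param geom full-system \code{qmmd_geometry} (elements/masses).
#' @param partition a \code{\link{build_partition}} result.
#' @param qc a \code{\link{qm_config}}.
#' @param nb a \code{\link{nonbonded_config}}.
#' @param restraint optional \code{\link{spherical_restraint}}.
#' @param forces if \code{FALSE}, skip all force evaluations (energy-only).
#' @return list with \code{report} (class \code{qmmd_energy_report}),
#'   \code{forces} (n x 3, kcal/mol/A; NULL in energy-only mode),
#'   \code{state_energies} (hartree) and the \code{qm} backend result.
#' @export
total_energy_forces <- function(positions, geom, partition, qc,
                                nb = nonbonded_config(), restraint = NULL,
                                forces = TRUE) {
  x <- as.matrix(positions)
  topo <- partition$topology
  na <- nrow(topo$atoms)
  kcal <- qmmd_constants$kcalmol_per_hartree
  inqm <- logical(na); inqm[partition$qm_atoms] <- TRUE

  basis_obj <- function(gQ) load_basis(gQ, qc$basis)

  emb <- .embedding_charges(partition, x)
  gQ <- .qm_geometry(geom, partition, x)
  bQ <- basis_obj(gQ)
  qm <- .qm_run(gQ, bQ, emb$charges, qc)

  # E_ele with the followed state's density
  Vext <- attraction_matrix(gQ, bQ, emb$charges)
  e_chg_elec <- sum(qm$density * Vext)
  e_chg_nuc <- nuclear_charge_interaction(gQ, emb$charges)
  e_ele <- e_chg_elec + e_chg_nuc                    # hartree
  e_qm <- qm$state_energy - e_ele                    # hartree

  # ---- MM side ------------------------------------------------------------
  lj <- .lj_vectors(topo)
  mm_atoms <- partition$mm_atoms
  # bonded terms with at least one MM atom (QM-internal terms dropped;
  # boundary terms kept and treated molecular-mechanically)
  keep_mm <- function(df, cols) {
    if (!nrow(df)) return(df)
    m <- sapply(cols, function(cc) inqm[df[[cc]]])
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    df[rowSums(m) < length(cols), , drop = FALSE]
  }
  F0 <- matrix(0, na, 3)
  rb <- .bond_ef(x, keep_mm(topo$bonds, c("i", "j")), F0)
  ra <- .angle_ef(x, keep_mm(topo$angles, c("i", "j", "k")), rb$F)
  rt <- .torsion_ef(x, keep_mm(topo$torsions, c("i", "j", "k", "l")), ra$F)
  e_bonded <- rb$e + ra$e + rt$e

  pairs <- neighbor_pairs(x, nb$cutoff, topo$exclusions)
  if (nrow(topo$pairs14) && nrow(pairs)) {
    key <- paste(pairs[, 1], pairs[, 2])
    k14 <- paste(topo$pairs14[, 1], topo$pairs14[, 2])
    pairs <- pairs[!(key %in% k14), , drop = FALSE]
  }
  split_qmmm <- function(p) {
    if (!nrow(p)) return(list(mm = p, cross = p))
    nq <- inqm[p[, 1]] + inqm[p[, 2]]
    list(mm = p[nq == 0, , drop = FALSE],
         cross = p[nq == 1, , drop = FALSE])
  }
  ps <- split_qmmm(pairs)
  p14 <- split_qmmm(partition$topology$pairs14)
  chg <- topo$atoms$charge
  zero <- rep(0, na)
  rmm <- .nonbonded_ef(x, ps$mm, chg, lj$eps, lj$rmin2, rt$F)
  rx <- .nonbonded_ef(x, ps$cross, zero, lj$eps, lj$rmin2, rmm$F)
  rmm14 <- .nonbonded_ef(x, p14$mm, chg, lj$eps, lj$rmin2, rx$F,
                         see = topo$scale14_ee, slj = topo$scale14_lj)
  rx14 <- .nonbonded_ef(x, p14$cross, zero, lj$eps, lj$rmin2, rmm14$F,
                        see = topo$scale14_ee, slj = topo$scale14_lj)
  Fmm <- rx14$F
  e_res <- 0
  if (!is.null(restraint)) {
    rr <- .restraint_ef(x, restraint, Fmm)
    e_res <- rr$e
    Fmm <- rr$F
  }
  e_mm <- e_bonded + rmm$e_lj + rmm$e_coul + rmm14$e_lj + rmm14$e_coul +
    e_res
  e_vdw <- rx$e_lj + rx14$e_lj

  e_ele_kcal <- e_ele * kcal
  e_qmmm <- e_ele_kcal + e_vdw
  e_tot <- e_qm * kcal + e_mm + e_qmmm
  report <- structure(list(
    E_QM = e_qm, E_MM = e_mm, E_ele = e_ele, E_vdW = e_vdw,
    E_QMMM = e_qmmm, E_tot = e_tot,
    E_ele_terms = list(charge_electron = e_chg_elec,
                       charge_nucleus = e_chg_nuc),
    mm_terms = c(bonded = e_bonded, lj = rmm$e_lj + rmm14$e_lj,
                 coulomb = rmm$e_coul + rmm14$e_coul, restraint = e_res)
  ), class = "qmmd_energy_report")

  if (!forces) {
    return(list(report = report, forces = NULL,
                state_energies = qm$energies, qm = qm))
  }

  # ---- QM-region nuclear forces by central differences --------------------
  nQ <- length(partition$qm_atoms)
  nL <- nrow(partition$cut_bonds)
  h <- qc$fd_displacement
  qm_energy_at <- function(xyzQ) {
    gq <- geometry(gQ$elements, xyzQ)
    bq <- basis_obj(gq)
    r <- .qm_run(gq, bq, emb$charges, qc)
    r$state_energy
  }
  xyzQ0 <- gQ$coords
  Fq <- matrix(0, nQ + nL, 3)
  for (a in seq_len(nQ + nL)) {
    for (d in 1:3) {
      xp <- xyzQ0; xp[a, d] <- xp[a, d] + h
      xm <- xyzQ0; xm[a, d] <- xm[a, d] - h
      Fq[a, d] <- -(qm_energy_at(xp) - qm_energy_at(xm)) / (2 * h)
    }
  }
  Fq <- Fq * kcal                                   # kcal/mol/A
  Ftot <- Fmm
  Ftot[partition$qm_atoms, ] <- Ftot[partition$qm_atoms, ] +
    Fq[seq_len(nQ), , drop = FALSE]
  # link-atom force projection: R_H = R_Q + d0 u, u = (R_M-R_Q)/r
  if (nL > 0L) {
    d0 <- partition$link_distance
    for (k in seq_len(nL)) {
      iq <- partition$cut_bonds[k, 1]; im <- partition$cut_bonds[k, 2]
      u <- x[im, ] - x[iq, ]
      r <- sqrt(sum(u^2)); u <- u / r
      Puu <- diag(3) - tcrossprod(u)
      JM <- (d0 / r) * Puu
      JQ <- diag(3) - JM
      fh <- Fq[nQ + k, ]
      Ftot[iq, ] <- Ftot[iq, ] + as.vector(t(JQ) %*% fh)
      Ftot[im, ] <- Ftot[im, ] + as.vector(t(JM) %*% fh)
    }
  }
  # ---- forces on embedding charges (frozen-density field) -----------------
  if (length(emb$atoms)) {
    qvals <- partition$redistributed_charges[emb$atoms]
    xb <- gQ$coords
    for (ci in seq_along(emb$atoms)) {
      ai <- emb$atoms[ci]
      fc <- numeric(3)
      for (d in 1:3) {
        cp <- x[ai, ]; cp[d] <- cp[d] + h
        cm <- x[ai, ]; cm[d] <- cm[d] - h
        vp <- attraction_matrix(gQ, bQ,
                                point_charges(matrix(cp, 1), qvals[ci]))
        vm <- attraction_matrix(gQ, bQ,
                                point_charges(matrix(cm, 1), qvals[ci]))
        ep <- sum(qm$density * vp) +
          nuclear_charge_interaction(gQ, point_charges(matrix(cp, 1),
                                                       qvals[ci]))
        em <- sum(qm$density * vm) +
          nuclear_charge_interaction(gQ, point_charges(matrix(cm, 1),
                                                       qvals[ci]))
        fc[d] <- -(ep - em) / (2 * h)
      }
      Ftot[ai, ] <- Ftot[ai, ] + fc * kcal
    }
  }
  list(report = report, forces = Ftot, state_energies = qm$energies,
       qm = qm)
}

#' @export
print.qmmd_energy_report <- function(x, ...) {
  kcal <- qmmd_constants$kcalmol_per_hartree
  cat(sprintf("<qmmd_energy_report (kcal/mol unless noted)>\n"))
  cat(sprintf("  E_QM    = %14.6f hartree\n", x$E_QM))
  cat(sprintf("  E_MM    = %14.6f\n", x$E_MM))
  cat(sprintf("  E_ele   = %14.6f hartree (%.6f kcal/mol)\n",
              x$E_ele, x$E_ele * kcal))
  cat(sprintf("  E_vdW   = %14.6f\n", x$E_vdW))
  cat(sprintf("  E_QM/MM = %14.6f\n", x$E_QMMM))
  cat(sprintf("  E_tot   = %14.6f\n", x$E_tot))
  invisible(x)
}
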