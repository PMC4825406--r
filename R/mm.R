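#' Molecular-mechanics topology
#'
#' AMBER-functional-form topology: harmonic bonds \eqn{k_b (r-r_0)^2},
#' harmonic angles \eqn{k_\theta (\theta-\theta_0)^2}, periodic torsions
#' \eqn{(V_n/2)(1+\cos(n\phi-\gamma))}, Lennard-Jones
#' \eqn{\epsilon[(R_{min}/r)^{12} - 2 (R_{min}/r)^6]} with
#' Lorentz-Berthelot-style combination (\eqn{R_{min} = R_{min,i}/2 +
#' R_{min,j}/2}, \eqn{\epsilon = \sqrt{\epsilon_i \epsilon_j}}), and Coulomb
#' with the electrostatic constant 332.0637128 kcal mol^-1 A e^-2.
#' 1-2 and 1-3 pairs are excluded; 1-4 pairs are scaled by the AMBER
#' convention (electrostatics / 1.2, LJ / 2) by default.
#'
#' @param atoms data.frame with columns \code{name}, \code{type},
#'   \code{charge} (e), \code{mass} (amu), \code{residue} (integer id).
#' @param bonds data.frame \code{i, j, kb} (kcal/mol/A^2), \code{r0} (A);
#'   may have zero rows.
#' @param angles data.frame \code{i, j, k, ktheta} (kcal/mol/rad^2),
#'   \code{theta0} (rad).
#' @param torsions data.frame \code{i, j, k, l, vn2} (kcal/mol; the
#'   barrier V_n/2), \code{periodicity}, \code{phase} (rad).
#' @param lj data.frame \code{type, eps} (kcal/mol), \code{rmin2}
#'   (R_min/2, A).
#' @param scale14_ee multiplicative 1-4 electrostatic scaling (default
#'   1/1.2).
#' @param scale14_lj multiplicative 1-4 LJ scaling (default 1/2).
#' @return object of class \code{qmmd_topology}; exclusion and 1-4 pair
#'   lists are derived from the bond graph at construction.
#' @export
topology_spec <- function(atoms, bonds = NULL, angles = NULL,
                          torsions = NULL, lj = NULL,
                          scale14_ee = 1 / 1.2, scale14_lj = 0.5) {
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "kb", "r0"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "ktheta", "theta0"))
  if (is.null(torsions)) {
    torsions <- empty(c("i", "j", "k", "l", "vn2", "periodicity", "phase"))
  }
  if (is.null(lj)) {
    lj <- data.frame(type = character(0), eps = numeric(0),
                     rmin2 = numeric(0))
  }
  na <- nrow(atoms)
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           torsions$i, torsions$j, torsions$k, torsions$l)
  if (length(idx) && (min(idx) < 1 || max(idx) > na)) {
    stop("bonded term references an atom outside the topology")
  }
  if (nrow(torsions) && any(torsions$periodicity < 1)) {
    stop("torsion periodicities must be >= 1")
  }
  if (nrow(lj) && any(lj$eps < 0)) stop("LJ epsilon must be >= 0")
  # bond graph -> 1-2, 1-3 exclusions and 1-4 scaled pairs
  adj <- vector("list", na)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
      adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
    }
  }
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ex12 <- character(0); ex13 <- character(0); p14 <- character(0)
  for (a in seq_len(na)) {
    for (b1 in adj[[a]]) {
      if (b1 != a) ex12 <- c(ex12, pair_key(a, b1))
      for (b2 in adj[[b1]]) {
        if (b2 != a) ex13 <- c(ex13, pair_key(a, b2))
        for (b3 in adj[[b2]]) {
          if (b3 != a && b3 != b1) p14 <- c(p14, pair_key(a, b3))
        }
      }
    }
  }
  ex <- unique(c(ex12, ex13))
  p14 <- setdiff(unique(p14), ex)
  split_pairs <- function(keys) {
    if (!length(keys)) return(matrix(integer(0), ncol = 2))
    m <- do.call(rbind, strsplit(keys, " "))
    matrix(as.integer(m), ncol = 2)
  }
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 torsions = torsions, lj = lj,
                 exclusions = split_pairs(ex),
                 pairs14 = split_pairs(p14),
                 scale14_ee = scale14_ee, scale14_lj = scale14_lj),
            class = "qmmd_topology")
}

#' @export
print.qmmd_topology <- function(x, ...) {
  cat(sprintf(paste0("<qmmd_topology: %d atoms, %d bonds, %d angles, ",
                     "%d torsions>\n"),
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$torsions)))
  invisible(x)
}

#' Nonbonded interaction settings
#'
#' Plain atom-based truncation at \code{cutoff} (no switching function, no
#' Ewald: the intended systems are non-periodic droplets). The pair list is
#' rebuilt every \code{update_interval} dynamics steps (default: every
#' step).
#'
#' @param cutoff cutoff distance, Angstrom.
#' @param update_interval steps between pair-list rebuilds.
#' @return list of class \code{qmmd_nonbonded}.
#' @export
nonbonded_config <- function(cutoff = 12, update_interval = 1L) {
  stopifnot(cutoff > 0, update_interval >= 1)
  structure(list(cutoff = cutoff,
                 update_interval = as.integer(update_interval)),
            class = "qmmd_nonbonded")
}

#' Spherical droplet restraint
#'
#' Harmonic wall \eqn{U = k\, d^2} with \eqn{d = \max(0, |r - c| - R)}
#' applied to each designated atom (typically water oxygens) outside the
#' sphere. The quadratic-without-1/2 convention matches the bond/angle
#' convention of the force-field functional form.
#'
#' @param center 3-vector, Angstrom.
#' @param radius sphere radius, Angstrom.
#' @param force_constant k, kcal/mol/A^2 (droplet simulations here use
#'   100).
#' @param atoms indices the restraint acts on.
#' @return list of class \code{qmmd_restraint}.
#' @export
spherical_restraint <- function(center, radius, force_constant = 100,
                                atoms) {
  stopifnot(radius > 0, force_constant >= 0)
  structure(list(center = as.numeric(center), radius = radius,
                 force_constant = force_constant,
                 atoms = as.integer(atoms)),
            class = "qmmd_restraint")
}

#' Nonbonded pair list
#'
#' All unordered atom pairs within the cutoff, minus the excluded pairs.
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param cutoff cutoff distance, Angstrom.
#' @param exclusions 2-column matrix of excluded pairs (unordered).
#' @return 2-column integer matrix with \code{i < j}.
#' @export
neighbor_pairs <- function(positions, cutoff, exclusions = NULL) {
  stopifnot(cutoff > 0)
  n <- nrow(positions)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  d2 <- as.matrix(stats::dist(positions))^2
  sel <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  if (!is.null(exclusions) && nrow(exclusions) && nrow(sel)) {
    key <- paste(sel[, 1], sel[, 2])
    exkey <- paste(pmin(exclusions[, 1], exclusions[, 2]),
                   pmax(exclusions[, 1], exclusions[, 2]))
    sel <- sel[!(key %in% exkey), , drop = FALSE]
  }
  unname(sel[order(sel[, 1], sel[, 2]), , drop = FALSE])
}

# ---- bonded term energies + analytic forces -------------------------------

.bond_ef <- function(x, bonds, F) {
  e <- 0
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    d <- x[i, ] - x[j, ]
    r <- sqrt(sum(d^2))
    dr <- r - bonds$r0[b]
    e <- e + bonds$kb[b] * dr^2
    fv <- -2 * bonds$kb[b] * dr * d / r
    F[i, ] <- F[i, ] + fv
    F[j, ] <- F[j, ] - fv
  }
  list(e = e, F = F)
}

.angle_ef <- function(x, angles, F) {
  e <- 0
  for (a in seq_len(nrow(angles))) {
    i <- angles$i[a]; j <- angles$j[a]; k <- angles$k[a]
    rij <- x[i, ] - x[j, ]; rkj <- x[k, ] - x[j, ]
    nij <- sqrt(sum(rij^2)); nkj <- sqrt(sum(rkj^2))
    cth <- sum(rij * rkj) / (nij * nkj)
    cth <- max(-1 + 1e-12, min(1 - 1e-12, cth))
    th <- acos(cth)
    dth <- th - angles$theta0[a]
    e <- e + angles$ktheta[a] * dth^2
    # dE/dtheta, dtheta/dcos = -1/sin
    dEdth <- 2 * angles$ktheta[a] * dth
    sth <- sqrt(1 - cth^2)
    di <- (rkj / (nij * nkj) - cth * rij / nij^2)
    dk <- (rij / (nij * nkj) - cth * rkj / nkj^2)
    Fi <- dEdth / sth * di
    Fk <- dEdth / sth * dk
    F[i, ] <- F[i, ] + Fi
    F[k, ] <- F[k, ] + Fk
    F[j, ] <- F[j, ] - Fi - Fk
  }
  list(e = e, F = F)
}

.torsion_ef <- function(x, tors, F) {
  e <- 0
  for (t in seq_len(nrow(tors))) {
    i <- tors$i[t]; j <- tors$j[t]; k <- tors$k[t]; l <- tors$l[t]
    b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
            b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    nb2 <- sqrt(sum(b2^2))
    m1 <- sum(n1^2); m2 <- sum(n2^2)
    phi <- atan2(sum(n1 * b3) * nb2, sum(n1 * n2))
    n <- tors$periodicity[t]
    e <- e + tors$vn2[t] * (1 + cos(n * phi - tors$phase[t]))
    dEdphi <- -tors$vn2[t] * n * sin(n * phi - tors$phase[t])
    # standard dihedral-angle gradients
    gi <- -(nb2 / m1) * n1
    gl <- (nb2 / m2) * n2
    s1 <- sum(b1 * b2) / nb2^2
    s3 <- sum(b3 * b2) / nb2^2
    gj <- -(1 + s1) * gi + s3 * gl
    gk <- s1 * gi - (1 + s3) * gl
    F[i, ] <- F[i, ] - dEdphi * gi
    F[j, ] <- F[j, ] - dEdphi * gj
    F[k, ] <- F[k, ] - dEdphi * gk
    F[l, ] <- F[l, ] - dEdphi * gl
  }
  list(e = e, F = F)
}

# lj/coulomb over a pair list; scale factors applied uniformly
.nonbonded_ef <- function(x, pairs, chg, eps_i, rmin_i, F,
                          see = 1, slj = 1) {
  if (!nrow(pairs)) return(list(e_lj = 0, e_coul = 0, F = F))
  kq <- qmmd_constants$coulomb_kcal
  e_lj <- 0; e_coul <- 0
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    d <- x[i, ] - x[j, ]
    r2 <- sum(d^2); r <- sqrt(r2)
    qq <- see * kq * chg[i] * chg[j] / r
    e_coul <- e_coul + qq
    fmag <- qq / r2                      # -d/dr (q/r) * (1/r) direction
    eps <- sqrt(eps_i[i] * eps_i[j])
    if (eps > 0) {
      rmin <- rmin_i[i] + rmin_i[j]
      s6 <- (rmin^2 / r2)^3
      elj <- slj * eps * (s6^2 - 2 * s6)
      e_lj <- e_lj + elj
      fmag <- fmag + slj * eps * 12 * (s6^2 - s6) / r2
    }
    fv <- fmag * d
    F[i, ] <- F[i, ] + fv
    F[j, ] <- F[j, ] - fv
  }
  list(e_lj = e_lj, e_coul = e_coul, F = F)
}

.restraint_ef <- function(x, restraint, F) {
  e <- 0
  for (i in restraint$atoms) {
    d <- x[i, ] - restraint$center
    r <- sqrt(sum(d^2))
    over <- r - restraint$radius
    if (over > 0) {
      e <- e + restraint$force_constant * over^2
      F[i, ] <- F[i, ] - 2 * restraint$force_constant * over * d / r
    }
  }
  list(e = e, F = F)
}

# map atom type -> (eps, rmin/2) vectors per atom
.lj_vectors <- function(topology) {
  ty <- topology$atoms$type
  m <- match(ty, topology$lj$type)
  if (anyNA(m)) {
    stop("missing LJ parameters for type(s): ",
         paste(unique(ty[is.na(m)]), collapse = ", "))
  }
  list(eps = topology$lj$eps[m], rmin2 = topology$lj$rmin2[m])
}

#' MM energy and forces
#'
#' Evaluates the full force-field energy with a term-by-term breakdown and
#' analytic forces (\code{-}gradient of the returned energy).
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param topology a \code{\link{topology_spec}}.
#' @param nb a \code{\link{nonbonded_config}}.
#' @param restraint optional \code{\link{spherical_restraint}}.
#' @param pairs optional precomputed neighbor pair list (rebuilt when
#'   \code{NULL}).
#' @return list with \code{energy} (kcal/mol), \code{terms} (named vector:
#'   bond, angle, torsion, lj, coulomb, lj14, coulomb14, restraint) and
#'   \code{forces} (n x 3, kcal/mol/A).
#' @export
mm_energy_forces <- function(positions, topology, nb = nonbonded_config(),
                             restraint = NULL, pairs = NULL) {
  x <- as.matrix(positions)
  na <- nrow(topology$atoms)
  if (nrow(x) != na) stop("positions do not conform to the topology")
  F <- matrix(0, na, 3)
  lj <- .lj_vectors(topology)
  rb <- .bond_ef(x, topology$bonds, F)
  ra <- .angle_ef(x, topology$angles, rb$F)
  rt <- .torsion_ef(x, topology$torsions, ra$F)
  if (is.null(pairs)) {
    pairs <- neighbor_pairs(x, nb$cutoff, topology$exclusions)
    # the scaled 1-4 pairs are handled separately below
    if (nrow(topology$pairs14) && nrow(pairs)) {
      key <- paste(pairs[, 1], pairs[, 2])
      k14 <- paste(topology$pairs14[, 1], topology$pairs14[, 2])
      pairs <- pairs[!(key %in% k14), , drop = FALSE]
    }
  }
  rn <- .nonbonded_ef(x, pairs, topology$atoms$charge, lj$eps, lj$rmin2,
                      rt$F)
  r14 <- .nonbonded_ef(x, topology$pairs14, topology$atoms$charge, lj$eps,
                       lj$rmin2, rn$F, see = topology$scale14_ee,
                       slj = topology$scale14_lj)
  Fcur <- r14$F
  e_res <- 0
  if (!is.null(restraint)) {
    rr <- .restraint_ef(x, restraint, Fcur)
    e_res <- rr$e
    Fcur <- rr$F
  }
  terms <- c(bond = rb$e, angle = ra$e, torsion = rt$e,
             lj = rn$e_lj, coulomb = rn$e_coul,
             lj14 = r14$e_lj, coulomb14 = r14$e_coul, restraint = e_res)
  list(energy = sum(terms), terms = terms, forces = Fcur, pairs = pairs)
}

#' TIP3P water topology
#'
#' Builds the topology of \code{n_waters} TIP3P molecules laid out as
#' consecutive O-H-H triplets in the geometry. Standard TIP3P charges
#' (O -0.834 e, H +0.417 e) and oxygen LJ parameters are assigned; the
#' waters are flexible (harmonic OH bonds and HOH angle), since droplet
#' dynamics here use no constraint algorithm.
#'
#' @param n_waters number of water molecules.
#' @param geom a \code{qmmd_geometry} whose atoms (or last
#'   \code{3 n_waters} atoms) are O,H,H triplets.
#' @param first_atom index of the first water atom inside \code{geom}.
#' @param first_residue residue id of the first water.
#' @return a \code{\link{topology_spec}}.
#' @export
tip3p_topology <- function(n_waters, geom, first_atom = 1L,
                           first_residue = 1L) {
  need <- 3L * n_waters
  if (n_atoms(geom) < first_atom + need - 1L) {
    stop("geometry too small for the requested water count")
  }
  els <- geom$elements[first_atom - 1L + seq_len(need)]
  if (!all(els == rep(c("O", "H", "H"), n_waters))) {
    stop("water block must consist of O,H,H triplets")
  }
  atoms <- data.frame(
    name = rep(c("OW", "HW1", "HW2"), n_waters),
    type = rep(c("OW", "HW", "HW"), n_waters),
    charge = rep(c(-0.834, 0.417, 0.417), n_waters),
    mass = rep(c(15.9994, 1.00794, 1.00794), n_waters),
    residue = first_residue - 1L + rep(seq_len(n_waters), each = 3L),
    stringsAsFactors = FALSE)
  o <- 3L * (seq_len(n_waters) - 1L) + 1L
  bonds <- data.frame(i = c(o, o), j = c(o + 1L, o + 2L),
                      kb = 553, r0 = 0.9572)
  angles <- data.frame(i = o + 1L, j = o, k = o + 2L,
                       ktheta = 100, theta0 = 104.52 * pi / 180)
  lj <- data.frame(type = c("OW", "HW"), eps = c(0.1521, 0),
                   rmin2 = c(1.7683, 0), stringsAsFactors = FALSE)
  topology_spec(atoms, bonds, angles, lj = lj)
}

#' Merge two topologies
#'
#' Concatenates atoms and bonded terms, offsetting the indices of the
#' second topology; LJ type tables are unioned (conflicting duplicate
#' parameter sets are an error).
#'
#' @param t1,t2 \code{qmmd_topology} objects.
#' @return merged \code{qmmd_topology}.
#' @export
topology_merge <- function(t1, t2) {
  off <- nrow(t1$atoms)
  roff <- if (nrow(t1$atoms)) max(t1$atoms$residue) else 0L
  a2 <- t2$atoms
  a2$residue <- a2$residue + roff
  shift <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- df[[cc]] + off
    df
  }
  lj <- unique(rbind(t1$lj, t2$lj))
  if (anyDuplicated(lj$type)) {
    stop("conflicting LJ parameters for type(s): ",
         paste(lj$type[duplicated(lj$type)], collapse = ", "))
  }
  topology_spec(rbind(t1$atoms, a2),
                rbind(t1$bonds, shift(t2$bonds, c("i", "j"))),
                rbind(t1$angles, shift(t2$angles, c("i", "j", "k"))),
                rbind(t1$torsions, shift(t2$torsions,
                                         c("i", "j", "k", "l"))),
                lj,
                scale14_ee = t1$scale14_ee, scale14_lj = t1$scale14_lj)
}
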