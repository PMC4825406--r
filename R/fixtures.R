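#' Toy conjugated chromophore fixture
#'
#' A planar s-trans butadiene-like molecule (C4H6, 10 atoms; well under the
#' 27-atom chromophore it stands in for) with an MM topology whose
#' equilibrium bond lengths and angles are set to the generated geometry,
#' so the returned structure is a local minimum of its own force field.
#' The pi system makes CAS(4,4) the natural active-space suggestion; the
#' net MM charge is zero.
#'
#' @return list with \code{geometry}, \code{topology}, \code{qm_atoms}
#'   (all atoms) and \code{suggested_cas} (a \code{\link{cas_space}}).
#' @export
gen_toy_chromophore <- function() {
  d_cc_double <- 1.34; d_cc_single <- 1.47; d_ch <- 1.09
  u <- function(a) c(cos(a), sin(a), 0)
  C1 <- c(0, 0, 0)
  C2 <- C1 + d_cc_double * u(0)
  C3 <- C2 + d_cc_single * u(pi / 3)
  C4 <- C3 + d_cc_double * u(0)
  hdir <- function(center, n1, n2) {
    v <- -( (n1 - center) / sqrt(sum((n1 - center)^2)) +
            (n2 - center) / sqrt(sum((n2 - center)^2)) )
    v / sqrt(sum(v^2))
  }
  H11 <- C1 + d_ch * u(2 * pi / 3)
  H12 <- C1 + d_ch * u(-2 * pi / 3)
  H2 <- C2 + d_ch * hdir(C2, C1, C3)
  H3 <- C3 + d_ch * hdir(C3, C2, C4)
  H41 <- C4 + d_ch * u(pi / 3)
  H42 <- C4 + d_ch * u(-pi / 3)
  coords <- rbind(C1, C2, C3, C4, H11, H12, H2, H3, H41, H42)
  els <- c(rep("C", 4), rep("H", 6))
  g <- geometry(els, coords)
  atoms <- data.frame(
    name = c("C1", "C2", "C3", "C4", "H11", "H12", "H2", "H3", "H41",
             "H42"),
    type = c(rep("CA", 4), rep("HA", 6)),
    charge = c(rep(-0.15, 4), rep(0.10, 6)),
    mass = g$masses, residue = 1L, stringsAsFactors = FALSE)
  bonds <- data.frame(
    i = c(1, 2, 3, 1, 1, 2, 3, 4, 4),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
    kb = c(549, 317, 549, rep(367, 6)), r0 = NA)
  bonds$r0 <- vapply(seq_len(nrow(bonds)), function(b) {
    sqrt(sum((coords[bonds$i[b], ] - coords[bonds$j[b], ])^2))
  }, numeric(1))
  ang <- function(i, j, k) {
    a <- coords[i, ] - coords[j, ]; b <- coords[k, ] - coords[j, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
  angles <- data.frame(
    i = c(1, 2, 5, 5, 6, 1, 1, 7, 2, 2, 8, 3, 3, 9, 9, 10),
    j = c(2, 3, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 4, 4),
    k = c(3, 4, 2, 6, 2, 3, 7, 3, 4, 8, 4, 9, 10, 10, 3, 3),
    ktheta = 50, theta0 = NA)
  angles$theta0 <- vapply(seq_len(nrow(angles)), function(a) {
    ang(angles$i[a], angles$j[a], angles$k[a])
  }, numeric(1))
  # planar pi-system torsions: n = 2, phase = pi gives E = vn2 (1 - cos 2phi),
  # minimized (and gradient-free) at the planar values phi = 0 or pi
  torsions <- rbind(
    # central C2-C3 bond
    data.frame(i = c(1, 1, 7, 7), j = 2, k = 3, l = c(4, 8, 4, 8),
               vn2 = 1.0),
    # C1=C2 double bond
    data.frame(i = c(5, 5, 6, 6), j = 1, k = 2, l = c(3, 7, 3, 7),
               vn2 = 5.0),
    # C3=C4 double bond
    data.frame(i = c(2, 2, 8, 8), j = 3, k = 4, l = c(9, 10, 9, 10),
               vn2 = 5.0))
  torsions$periodicity <- 2L
  torsions$phase <- pi
  lj <- data.frame(type = c("CA", "HA"), eps = c(0.086, 0.015),
                   rmin2 = c(1.908, 1.459), stringsAsFactors = FALSE)
  topo <- topology_spec(atoms, bonds, angles, torsions, lj)
  # relax the idealized geometry on its own force field (the scaled 1-4
  # nonbonded terms shift the minimum slightly off the ideal values)
  opt <- stats::optim(
    as.vector(coords),
    function(p) mm_energy_forces(matrix(p, ncol = 3), topo)$energy,
    function(p) -as.vector(mm_energy_forces(matrix(p, ncol = 3),
                                            topo)$forces),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  g <- geometry(els, matrix(opt$par, ncol = 3))
  list(geometry = g, topology = topo, qm_atoms = seq_len(10),
       suggested_cas = cas_space(4, 4))
}

#' Toy diatomic solute fixture
#'
#' A neutral homonuclear diatomic (default H2 at its equilibrium bond
#' length) with a minimal MM topology, usable as the QM solute of a small
#' solvated droplet.
#'
#' @param element element symbol.
#' @param bond_length Angstrom.
#' @return list with \code{geometry}, \code{topology}, \code{qm_atoms}.
#' @export
gen_diatomic_solute <- function(element = "H", bond_length = 0.7414) {
  g <- geometry(c(element, element),
                rbind(c(0, 0, -bond_length / 2), c(0, 0, bond_length / 2)))
  atoms <- data.frame(name = c("X1", "X2"), type = "XS", charge = 0,
                      mass = g$masses, residue = 1L,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = 1L, j = 2L, kb = 350, r0 = bond_length)
  lj <- data.frame(type = "XS", eps = 0.0157, rmin2 = 0.6,
                   stringsAsFactors = FALSE)
  list(geometry = g, topology = topology_spec(atoms, bonds, lj = lj),
       qm_atoms = 1:2)
}

#' Solvated droplet fixture: a sphere of TIP3P waters around a solute
#'
#' Waters are placed uniformly inside a sphere centred on the solute
#' centre of mass, rejecting placements with O-O distances below 2.4 A or
#' oxygens within 2.4 A of a solute atom, with random orientations. Pure
#' function of the seed and arguments. The droplet restraint centre is the
#' solute centre of mass.
#'
#' @param radius sphere radius, Angstrom (the reference protocol uses 15).
#' @param n_waters number of waters (449 at the reference scale).
#' @param solute optional fixture list (\code{geometry}, \code{topology})
#'   as returned by \code{\link{gen_toy_chromophore}} /
#'   \code{\link{gen_diatomic_solute}}; omitted for a pure droplet.
#' @param seed RNG seed.
#' @param min_dist placement clash distance, Angstrom.
#' @return list with \code{geometry} (solute atoms first), \code{topology}
#'   (merged), \code{qm_atoms}, \code{water_oxygens} (indices, for the
#'   restraint), \code{center} (restraint centre), \code{n_waters}.
#' @export
gen_water_sphere <- function(radius, n_waters, solute = NULL, seed = 1L,
                             min_dist = 2.4) {
  stopifnot(radius > 0, n_waters >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!is.null(solute)) {
    sg <- solute$geometry
    center <- colSums(sg$coords * sg$masses) / sum(sg$masses)
    scoords <- sg$coords
  } else {
    center <- c(0, 0, 0)
    scoords <- matrix(numeric(0), ncol = 3)
  }
  # sanity bound: each water needs roughly a min_dist-sized cell
  if (n_waters > 0 &&
      n_waters * (4 / 3) * pi * (min_dist / 2)^3 >
        (4 / 3) * pi * radius^3) {
    stop("impossible packing density for the requested sphere")
  }
  opos <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(opos) < n_waters) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, n_waters)) {
      stop("failed to place waters without clashes; lower the density")
    }
    p <- center + stats::runif(3, -radius, radius)
    if (sum((p - center)^2) > radius^2) next
    if (nrow(scoords) &&
        min(sqrt(rowSums(sweep(scoords, 2, p)^2))) < min_dist) next
    if (nrow(opos) &&
        min(sqrt(rowSums(sweep(opos, 2, p)^2))) < min_dist) next
    opos <- rbind(opos, p)
  }
  # build each water with a random orientation
  roh <- 0.9572; theta <- 104.52 * pi / 180
  wcoords <- matrix(0, 0, 3)
  for (w in seq_len(n_waters)) {
    # random rotation from a normalized quaternion
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    h1 <- c(roh * sin(theta / 2), 0, roh * cos(theta / 2))
    h2 <- c(-roh * sin(theta / 2), 0, roh * cos(theta / 2))
    o <- opos[w, ]
    wcoords <- rbind(wcoords, o, o + as.vector(R %*% h1),
                     o + as.vector(R %*% h2))
  }
  wg_els <- rep(c("O", "H", "H"), n_waters)
  if (!is.null(solute)) {
    all_g <- geometry(c(solute$geometry$elements, wg_els),
                      rbind(solute$geometry$coords, wcoords))
    wg <- geometry(wg_els, wcoords)
    topo <- topology_merge(solute$topology, tip3p_topology(n_waters, wg))
    nsol <- n_atoms(solute$geometry)
    qm <- solute$qm_atoms
  } else {
    all_g <- geometry(wg_els, wcoords)
    topo <- tip3p_topology(n_waters, all_g)
    nsol <- 0L
    qm <- integer(0)
  }
  list(geometry = all_g, topology = topo, qm_atoms = qm,
       water_oxygens = nsol + 3L * (seq_len(n_waters) - 1L) + 1L,
       center = center, n_waters = n_waters)
}

#' Synthetic Amdahl timing table
#'
#' Constructs elapsed times from Amdahl's law,
#' \eqn{T_N = T_1 (f + (1-f)/N)}, so that the scaling report recovers the
#' serial fraction \eqn{f} exactly.
#'
#' @param serial_fraction f in [0, 1].
#' @param t1 reference elapsed time, seconds.
#' @param core_counts vector of core counts; the first is the reference.
#' @return a \code{\link{timing_table}}.
#' @export
gen_timing_table <- function(serial_fraction, t1, core_counts) {
  stopifnot(serial_fraction >= 0, serial_fraction <= 1, t1 > 0)
  N <- core_counts / core_counts[1]
  tn <- t1 * (serial_fraction + (1 - serial_fraction) / N)
  timing_table(n_cpus = core_counts, n_threads = rep(1L,
                                                     length(core_counts)),
               n_cores = core_counts, elapsed_time = tn,
               reference_row = 1L)
}
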