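# shared fixture builders (all constructed in code at test time)

fix_h2 <- function(r = 0.7414) {
  geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
}

fix_water <- function() {
  geometry(c("O", "H", "H"),
           rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                 c(0, -0.7572, -0.4692)))
}

# ethane-like fixture with explicit bonds/angles/torsions and charges
fix_ethane_topology <- function() {
  # C1 H111 H112 H113 C2 H211 H212 H213 (indices 1..8)
  atoms <- data.frame(
    name = c("C1", "H11", "H12", "H13", "C2", "H21", "H22", "H23"),
    type = c("CT", rep("HC", 3), "CT", rep("HC", 3)),
    charge = c(-0.3, 0.1, 0.1, 0.1, -0.3, 0.1, 0.1, 0.1),
    mass = c(12.011, rep(1.008, 3), 12.011, rep(1.008, 3)),
    residue = 1L, stringsAsFactors = FALSE)
  bonds <- data.frame(
    i = c(1, 1, 1, 1, 5, 5, 5),
    j = c(5, 2, 3, 4, 6, 7, 8),
    kb = c(310, rep(340, 6)), r0 = c(1.526, rep(1.09, 6)))
  ang <- function(i, j, k) data.frame(i = i, j = j, k = k, ktheta = 50,
                                      theta0 = 109.5 * pi / 180)
  angles <- rbind(
    ang(2, 1, 3), ang(2, 1, 4), ang(3, 1, 4),
    ang(2, 1, 5), ang(3, 1, 5), ang(4, 1, 5),
    ang(6, 5, 7), ang(6, 5, 8), ang(7, 5, 8),
    ang(6, 5, 1), ang(7, 5, 1), ang(8, 5, 1))
  torsions <- expand.grid(i = 2:4, l = 6:8)
  torsions <- data.frame(i = torsions$i, j = 1L, k = 5L, l = torsions$l,
                         vn2 = 0.15, periodicity = 3L, phase = 0)
  lj <- data.frame(type = c("CT", "HC"), eps = c(0.1094, 0.0157),
                   rmin2 = c(1.908, 1.487), stringsAsFactors = FALSE)
  topology_spec(atoms, bonds, angles, torsions, lj)
}

fix_ethane_coords <- function() {
  # staggered ethane, Angstrom; CH bonds tilted 109.5 deg off the CC axis
  d <- 1.526; dch <- 1.09
  th <- 109.5 * pi / 180
  c1 <- c(0, 0, 0); c2 <- c(0, 0, d)
  h1 <- t(sapply(0:2, function(k) {
    a <- 2 * pi * k / 3
    c1 + dch * c(sin(th) * cos(a), sin(th) * sin(a), cos(th))
  }))
  h2 <- t(sapply(0:2, function(k) {
    a <- pi / 3 + 2 * pi * k / 3
    c2 + dch * c(sin(th) * cos(a), sin(th) * sin(a), -cos(th))
  }))
  unname(rbind(c1, h1, c2, h2))
}

fix_ethane_geometry <- function() {
  x <- fix_ethane_coords()
  geometry(c("C", "H", "H", "H", "C", "H", "H", "H"), x)
}

suppress_scf_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("DIIS|SCF not converged", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
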