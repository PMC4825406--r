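test_that("forces are the negative gradient on random configurations", {
  set.seed(21)
  ch <- gen_toy_chromophore()
  configs <- list(
    list(x = gen_water_sphere(4, 2, seed = 11)$geometry$coords,
         topo = gen_water_sphere(4, 2, seed = 11)$topology),
    list(x = ch$geometry$coords + matrix(rnorm(30, sd = 0.05), ncol = 3),
         topo = ch$topology),
    list(x = fix_ethane_coords() + matrix(rnorm(24, sd = 0.04), ncol = 3),
         topo = fix_ethane_topology()))
  h <- 1e-5
  for (cf in configs) {
    r <- mm_energy_forces(cf$x, cf$topo)
    maxrel <- 0
    for (a in seq_len(nrow(cf$x))) for (d in 1:3) {
      xp <- cf$x; xp[a, d] <- xp[a, d] + h
      xm <- cf$x; xm[a, d] <- xm[a, d] - h
      fd <- -(mm_energy_forces(xp, cf$topo)$energy -
                mm_energy_forces(xm, cf$topo)$energy) / (2 * h)
      maxrel <- max(maxrel, abs(fd - r$forces[a, d]) /
                      max(1, abs(fd)))
    }
    expect_lt(maxrel, 1e-5)
    # Newton's third law without a restraint
    expect_equal(colSums(r$forces), rep(0, 3), tolerance = 1e-8)
  }
})

test_that("bonded terms vanish at equilibrium; Coulomb constant is exact", {
  # one water at its equilibrium internal geometry, no partner in range
  ws <- gen_water_sphere(3, 1, seed = 2)
  r <- mm_energy_forces(ws$geometry$coords, ws$topology)
  expect_equal(unname(r$terms["bond"] + r$terms["angle"] +
                        r$terms["torsion"]), 0, tolerance = 1e-16)
  # two unit charges 1 A apart -> the electrostatic conversion constant
  atoms <- data.frame(name = c("A", "B"), type = "Q", charge = 1,
                      mass = 1, residue = 1:2)
  lj <- data.frame(type = "Q", eps = 0, rmin2 = 1)
  topo <- topology_spec(atoms, lj = lj)
  r2 <- mm_energy_forces(rbind(c(0, 0, 0), c(1, 0, 0)), topo)
  expect_equal(r2$energy, 332.0637128, tolerance = 1e-10)
})

test_that("spherical restraint follows the k d^2 convention", {
  xw <- rbind(c(16, 0, 0), c(16.76, 0.59, 0), c(16.76, -0.59, 0))
  topo <- tip3p_topology(1, geometry(c("O", "H", "H"), xw))
  rs <- spherical_restraint(c(0, 0, 0), 15, 100, atoms = 1L)
  r <- mm_energy_forces(xw, topo, restraint = rs)
  expect_equal(unname(r$terms["restraint"]), 100 * (16 - 15)^2,
               tolerance = 1e-12)
  # inside the sphere: inactive
  rs2 <- spherical_restraint(c(0, 0, 0), 20, 100, atoms = 1L)
  r2 <- mm_energy_forces(xw, topo, restraint = rs2)
  expect_equal(unname(r2$terms["restraint"]), 0)
})

test_that("neighbor pairs: brute-force parity, cutoff edge, exclusions", {
  set.seed(31)
  x <- matrix(runif(500 * 3, 0, 20), 500)
  cutoff <- 4.5
  pairs <- neighbor_pairs(x, cutoff)
  # O(N^2) oracle
  ref <- list()
  for (i in 1:499) for (j in (i + 1):500) {
    if (sum((x[i, ] - x[j, ])^2) <= cutoff^2) {
      ref[[length(ref) + 1L]] <- c(i, j)
    }
  }
  ref <- do.call(rbind, ref)
  expect_equal(nrow(pairs), nrow(ref))
  expect_equal(pairs, ref[order(ref[, 1], ref[, 2]), ])
  # two atoms just beyond the cutoff -> empty
  expect_equal(nrow(neighbor_pairs(rbind(c(0, 0, 0),
                                         c(0, 0, cutoff + 1e-9)),
                                   cutoff)), 0L)
  # an excluded 1-2 pair never appears
  topo <- fix_ethane_topology()
  p <- neighbor_pairs(fix_ethane_coords(), 12, topo$exclusions)
  expect_false(any(p[, 1] == 1 & p[, 2] == 5))
})

test_that("TIP3P topology: counts, neutrality, parameters", {
  ws <- gen_water_sphere(4, 1, seed = 1)
  topo <- ws$topology
  expect_equal(nrow(topo$atoms), 3L)
  expect_equal(sum(topo$atoms$charge), 0, tolerance = 1e-12)
  expect_equal(topo$atoms$charge[1], -2 * topo$atoms$charge[2])
  # malformed triplet rejected
  g_bad <- geometry(c("H", "O", "H"), diag(3))
  expect_error(tip3p_topology(1, g_bad), "triplet")
  # larger droplet: per-water neutrality survives the merge
  ws9 <- gen_water_sphere(6, 9, seed = 5)
  expect_equal(nrow(ws9$topology$atoms), 27L)
  for (w in 1:9) {
    expect_equal(sum(ws9$topology$atoms$charge[(3 * w - 2):(3 * w)]), 0,
                 tolerance = 1e-12)
  }
})

test_that("energy is invariant under rigid motion; torsions are periodic", {
  ws <- gen_water_sphere(4, 3, seed = 13)
  x <- ws$geometry$coords
  e1 <- mm_energy_forces(x, ws$topology)$energy
  R <- random_rotation(3)
  x2 <- t(R %*% t(x)) + rep(c(5, -3, 1), each = nrow(x))
  e2 <- mm_energy_forces(x2, ws$topology)$energy
  expect_equal(e1, e2, tolerance = 1e-9)

  # rotating a dihedral by 2 pi / n leaves the torsion term unchanged
  topo <- fix_ethane_topology()
  x0 <- fix_ethane_coords()
  tors_only <- topo
  tors_only$atoms$charge <- 0
  tors_only$lj$eps <- 0
  e_t <- function(x) mm_energy_forces(x, tors_only)$energy
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0,
                               sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                             byrow = TRUE)
  x_rot <- x0
  x_rot[6:8, ] <- t(rotz(2 * pi / 3) %*% t(x0[6:8, ]))  # n = 3 torsions
  expect_equal(e_t(x_rot), e_t(x0), tolerance = 1e-9)
})

test_that("missing LJ type errors with the type name", {
  atoms <- data.frame(name = "X", type = "ZZ", charge = 0, mass = 1,
                      residue = 1)
  topo <- topology_spec(atoms,
                        lj = data.frame(type = "Q", eps = 0, rmin2 = 1))
  expect_error(mm_energy_forces(matrix(0, 1, 3), topo), "ZZ")
})
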