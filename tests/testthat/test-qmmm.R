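test_that("partition: whole-system selection, droplet, and ethane cut", {
  topo <- fix_ethane_topology()
  # whole system QM: no cuts, no link atoms, legal empty MM part
  pall <- build_partition(topo, 1:8)
  expect_equal(nrow(pall$cut_bonds), 0L)
  expect_equal(nrow(place_link_atoms(pall, fix_ethane_coords())), 0L)
  expect_length(pall$mm_atoms, 0L)
  bt <- boundary_bonded_terms(pall)
  expect_equal(nrow(bt$bonds) + nrow(bt$angles) + nrow(bt$torsions), 0L)

  # solute QM in water: no covalent cut across the boundary
  ws <- gen_water_sphere(5, 4, solute = gen_diatomic_solute(), seed = 6)
  psol <- build_partition(ws$topology, ws$qm_atoms)
  expect_equal(nrow(psol$cut_bonds), 0L)

  # one methyl QM: exactly one cut bond
  p <- build_partition(topo, c(1, 2, 3, 4))
  expect_equal(nrow(p$cut_bonds), 1L)
  expect_equal(unname(p$cut_bonds[1, ]), c(1L, 5L))
  expect_error(build_partition(topo, integer(0)), "empty")
})

test_that("link atoms sit on the bond axis at exactly 1.10 A", {
  topo <- fix_ethane_topology()
  p <- build_partition(topo, 1:4)
  x <- fix_ethane_coords()
  # canonical example: boundary atoms at z = 0 and z = 1.54
  x2 <- x
  x2[1, ] <- c(0, 0, 0); x2[5, ] <- c(0, 0, 1.54)
  links <- place_link_atoms(p, x2)
  expect_equal(links[1, ], c(0, 0, 1.10), tolerance = 1e-12)
  # general geometry: distance 1.10 and collinearity
  links <- place_link_atoms(p, x)
  d <- links[1, ] - x[1, ]
  expect_equal(sqrt(sum(d^2)), 1.10, tolerance = 1e-12)
  cr <- c(d[2] * (x[5, 3] - x[1, 3]) - d[3] * (x[5, 2] - x[1, 2]),
          d[3] * (x[5, 1] - x[1, 1]) - d[1] * (x[5, 3] - x[1, 3]),
          d[1] * (x[5, 2] - x[1, 2]) - d[2] * (x[5, 1] - x[1, 1]))
  expect_equal(cr, rep(0, 3), tolerance = 1e-12)
  # coincident boundary atoms are an error
  x3 <- x; x3[5, ] <- x3[1, ]
  expect_error(place_link_atoms(p, x3), "coincident")
})

test_that("charge redistribution conserves the MM total exactly", {
  topo <- fix_ethane_topology()
  p <- build_partition(topo, 1:4)
  red <- redistribute_charges(p)
  # excluded set: MM boundary atom C2 and its MM-bonded hydrogens
  expect_setequal(p$excluded_charge_atoms, 5:8)
  expect_equal(sum(red$charge), sum(topo$atoms$charge[5:8]),
               tolerance = 1e-12)
  # no cut bonds -> identity map
  ws <- gen_water_sphere(5, 3, solute = gen_diatomic_solute(), seed = 2)
  pw <- build_partition(ws$topology, ws$qm_atoms)
  rw <- redistribute_charges(pw)
  expect_equal(rw$charge, ws$topology$atoms$charge[pw$mm_atoms])

  # property: random multi-residue topologies conserve total MM charge
  set.seed(41)
  for (trial in 1:8) {
    na <- sample(6:12, 1)
    atoms <- data.frame(name = paste0("A", 1:na), type = "Q",
                        charge = round(rnorm(na), 3), mass = 1,
                        residue = sort(sample(1:2, na, replace = TRUE)))
    # random spanning-ish bond set
    bonds <- data.frame(i = 1:(na - 1), j = 2:na, kb = 300, r0 = 1)
    topo_r <- topology_spec(atoms, bonds,
                            lj = data.frame(type = "Q", eps = 0,
                                            rmin2 = 1))
    qm <- sort(sample(na, sample(2:(na - 3), 1)))
    pr <- tryCatch(build_partition(topo_r, qm), error = function(e) NULL)
    if (is.null(pr)) next   # residue left with no receiving atoms
    rr <- redistribute_charges(pr)
    expect_equal(sum(rr$charge), sum(atoms$charge[pr$mm_atoms]),
                 tolerance = 1e-12)
    # excluded atoms carry zero embedding charge
    expect_true(all(pr$redistributed_charges[pr$excluded_charge_atoms]
                    == 0))
  }
})

test_that("boundary bonded terms: ethane enumeration oracle", {
  topo <- fix_ethane_topology()
  p <- build_partition(topo, 1:4)
  bt <- boundary_bonded_terms(p)
  # enumeration: bonds/angles/torsions with >=1 atom on each side
  cnt <- function(df, cols) {
    if (!nrow(df)) return(0L)
    inqm <- seq_len(8) %in% 1:4
    sum(apply(df[cols], 1, function(r) {
      k <- sum(inqm[as.integer(r)]); k > 0 && k < length(cols)
    }))
  }
  expect_equal(nrow(bt$bonds), cnt(topo$bonds, c("i", "j")))
  expect_equal(nrow(bt$angles), cnt(topo$angles, c("i", "j", "k")))
  expect_equal(nrow(bt$torsions), cnt(topo$torsions,
                                      c("i", "j", "k", "l")))
  expect_equal(nrow(bt$bonds), 1L)
  expect_equal(nrow(bt$angles), 6L)
  expect_equal(nrow(bt$torsions), 9L)
})

test_that("energy report identities hold exactly; limits behave", {
  kcal <- qmmd_constants$kcalmol_per_hartree
  ws <- gen_water_sphere(4, 2, seed = 11)
  part <- build_partition(ws$topology, 1:3)
  qc <- qm_config(method = "hf", basis = "toy-minimal")
  r <- total_energy_forces(ws$geometry$coords, ws$geometry, part, qc,
                           forces = FALSE)
  rep <- r$report
  expect_equal(rep$E_tot, rep$E_QM * kcal + rep$E_MM + rep$E_QMMM)
  expect_equal(rep$E_QMMM, rep$E_ele * kcal + rep$E_vdW)
  expect_equal(rep$E_ele, rep$E_ele_terms$charge_electron +
                 rep$E_ele_terms$charge_nucleus)

  # empty MM region: E_tot = E_QM, E_QM/MM = 0
  sol <- gen_diatomic_solute()
  pall <- build_partition(sol$topology, 1:2)
  r2 <- total_energy_forces(sol$geometry$coords, sol$geometry, pall, qc,
                            forces = FALSE)
  expect_equal(r2$report$E_QMMM, 0)
  expect_equal(r2$report$E_MM, 0)
  expect_equal(r2$report$E_tot, r2$report$E_QM * kcal)

  # all MM charges zero: E_ele = 0, E_QM/MM = E_vdW (Eq 2 limit)
  ws0 <- ws
  ws0$topology$atoms$charge <- 0
  part0 <- build_partition(ws0$topology, 1:3)
  r3 <- total_energy_forces(ws0$geometry$coords, ws0$geometry, part0, qc,
                            forces = FALSE)
  expect_equal(r3$report$E_ele, 0)
  expect_equal(r3$report$E_QMMM, r3$report$E_vdW)
})

test_that("total forces match central differences (QM water + MM water)", {
  ws <- gen_water_sphere(4, 2, seed = 11)
  geom <- ws$geometry
  part <- build_partition(ws$topology, 1:3)
  qc <- qm_config(method = "hf", basis = "toy-minimal")
  r <- total_energy_forces(geom$coords, geom, part, qc)
  x <- geom$coords
  h <- 2e-4
  relerr <- 0
  for (a in 1:6) for (d in 1:3) {
    xp <- x; xp[a, d] <- xp[a, d] + h
    xm <- x; xm[a, d] <- xm[a, d] - h
    ep <- total_energy_forces(xp, geom, part, qc,
                              forces = FALSE)$report$E_tot
    em <- total_energy_forces(xm, geom, part, qc,
                              forces = FALSE)$report$E_tot
    fd <- -(ep - em) / (2 * h)
    relerr <- max(relerr, abs(fd - r$forces[a, d]) / max(1, abs(fd)))
  }
  expect_lt(relerr, 1e-4)
})

test_that("link-atom forces project onto boundary atoms across a cut", {
  # QM methyl of ethane with an explicit link atom: total forces still
  # match finite differences of E_tot (chain-rule projection included)
  topo <- fix_ethane_topology()
  geom <- fix_ethane_geometry()
  part <- build_partition(topo, 1:4)
  qc <- qm_config(method = "hf", basis = "toy-minimal",
                  scf = scf_config(charge = 0))
  x <- geom$coords
  r <- total_energy_forces(x, geom, part, qc)
  h <- 2e-4
  relerr <- 0
  for (a in c(1, 2, 5, 6)) for (d in 1:3) {   # both boundary atoms
    xp <- x; xp[a, d] <- xp[a, d] + h
    xm <- x; xm[a, d] <- xm[a, d] - h
    ep <- total_energy_forces(xp, geom, part, qc,
                              forces = FALSE)$report$E_tot
    em <- total_energy_forces(xm, geom, part, qc,
                              forces = FALSE)$report$E_tot
    fd <- -(ep - em) / (2 * h)
    relerr <- max(relerr, abs(fd - r$forces[a, d]) / max(1, abs(fd)))
  }
  expect_lt(relerr, 2e-3)
})
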