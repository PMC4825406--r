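test_that("H2 RHF matches the independent s-only reference to 1e-6", {
  g <- fix_h2()
  b <- load_basis(g, "toy-minimal")
  r <- run_rhf(g, b)
  expect_true(r$converged)
  # reference: closed-form s integrals + plain damped Roothaan, built in
  # the test helper with no shared code
  sto3g_h <- list(exps = c(3.42525091, 0.62391373, 0.16885540),
                  coefs = c(0.15432897, 0.53532814, 0.44463454))
  sto3g_h$coefs <- sto3g_h$coefs * s_norm(sto3g_h$exps)
  atoms <- list(
    list(Z = 1, pos = c(0, 0, 0), exps = sto3g_h$exps,
         coefs = sto3g_h$coefs / s_norm(sto3g_h$exps)),
    list(Z = 1, pos = c(0, 0, 0.7414 * BOHR), exps = sto3g_h$exps,
         coefs = sto3g_h$coefs / s_norm(sto3g_h$exps)))
  ref <- reference_rhf_s(atoms, n_elec = 2)
  expect_equal(r$total_energy, ref$energy, tolerance = 1e-6)
})

test_that("He in a single s function has the closed-form energy", {
  g <- geometry("He", matrix(0, 1, 3))
  a <- 1.6875^2 / 2   # arbitrary positive exponent would do
  b <- basis_set(list(gaussian_shell(1, 0, a, 1.0)), g)
  r <- run_rhf(g, b)
  h11 <- kinetic_matrix(g, b)[1, 1] + nuclear_attraction_matrix(g, b)[1, 1]
  e1111 <- eri_tensor(g, b)[1, 1, 1, 1]
  expect_equal(r$total_energy, 2 * h11 + e1111, tolerance = 1e-10)
})

test_that("embedded RHF matches the reference and the multipole limit", {
  g <- fix_h2()
  b <- load_basis(g, "toy-minimal")
  # charge near H2: full reference comparison
  cp <- matrix(c(0, 1.5, 0.4), 1)
  ch <- point_charges(cp, -0.5)
  r <- run_rhf(g, b, ch)
  sto3g_h <- list(exps = c(3.42525091, 0.62391373, 0.16885540),
                  coefs = c(0.15432897, 0.53532814, 0.44463454))
  atoms <- list(
    list(Z = 1, pos = c(0, 0, 0), exps = sto3g_h$exps,
         coefs = sto3g_h$coefs),
    list(Z = 1, pos = c(0, 0, 0.7414 * BOHR), exps = sto3g_h$exps,
         coefs = sto3g_h$coefs))
  ref <- reference_rhf_s(atoms, 2, ext_pos = cp * BOHR, ext_q = -0.5)
  expect_equal(r$total_energy, ref$energy, tolerance = 1e-6)

  # neutral molecule + distant charge: interaction ~ dipole/R^2, so
  # E_int * R^2 approaches a constant as R doubles
  gw <- fix_water()
  bw <- load_basis(gw, "toy-minimal")
  e0 <- run_rhf(gw, bw)$total_energy
  eint <- function(R) {
    ch <- point_charges(matrix(c(0, 0, R), 1), 0.7)
    run_rhf(gw, bw, ch)$total_energy - e0
  }
  RB <- 40 * BOHR  # 40 A in bohr for the scale factor
  c1 <- eint(40) * 40^2
  c2 <- eint(80) * 80^2
  expect_gt(abs(c1), 1e-6)          # the dipole term is actually there
  expect_equal(c2 / c1, 1, tolerance = 0.02)
})

test_that("build_fock equals the brute-force tensor contraction", {
  g <- fix_water()
  b <- load_basis(g, "toy-minimal")
  eri <- eri_tensor(g, b)
  n <- b$n_basis
  set.seed(3)
  P <- crossprod(matrix(rnorm(n * n), n))
  h <- crossprod(matrix(rnorm(n * n), n))
  F <- build_fock(P, h, eri)
  Fb <- h
  for (i in 1:n) for (j in 1:n) {
    Fb[i, j] <- Fb[i, j] + sum(P * (2 * eri[i, j, , ] - eri[i, , , j]))
  }
  expect_equal(F, Fb, tolerance = 1e-12)
  expect_equal(build_fock(0 * P, h, eri), h)
  # J and K are linear in P
  jk1 <- coulomb_exchange(P, eri)
  jk2 <- coulomb_exchange(2 * P, eri)
  expect_equal(jk2$J, 2 * jk1$J, tolerance = 1e-12)
  expect_equal(jk2$K, 2 * jk1$K, tolerance = 1e-12)
  expect_error(build_fock(P[1:3, 1:3], h, eri), "dimension")
})

test_that("orthogonalizer back-ends satisfy X'SX = I and agree on H2", {
  expect_equal(orthogonalizer(diag(3)), diag(3))
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  for (m in c("symmetric", "cholesky")) {
    X <- orthogonalizer(S, m)
    expect_equal(t(X) %*% S %*% X, diag(2), tolerance = 1e-12)
  }
  g <- fix_h2(); b <- load_basis(g, "toy-minimal")
  e1 <- run_rhf(g, b, config = scf_config(orthogonalizer = "symmetric"))
  e2 <- run_rhf(g, b, config = scf_config(orthogonalizer = "cholesky"))
  expect_equal(e1$total_energy, e2$total_energy, tolerance = 1e-10)
  expect_error(orthogonalizer(matrix(c(1, 2, 2, 1), 2)), "eigenvalue")
})

test_that("DIIS: identity on single history, sum-to-1, and speedup", {
  F1 <- matrix(rnorm(9), 3)
  out <- diis_extrapolate(list(F1), list(matrix(1, 3, 3)))
  expect_equal(unclass(out), F1, ignore_attr = TRUE)
  set.seed(8)
  fh <- lapply(1:4, function(i) crossprod(matrix(rnorm(9), 3)))
  eh <- lapply(1:4, function(i) matrix(rnorm(9), 3) * 0.1^i)
  out <- diis_extrapolate(fh, eh)
  expect_equal(sum(attr(out, "coefficients")), 1, tolerance = 1e-12)
  expect_error(diis_extrapolate(list(), list()), "non-empty")

  g <- fix_water(); b <- load_basis(g, "toy-minimal")
  with_diis <- run_rhf(g, b, config = scf_config(diis_depth = 8))
  damped <- run_rhf(g, b, config = scf_config(diis_depth = 0,
                                              damping = 0.3))
  expect_true(with_diis$converged && damped$converged)
  expect_lt(with_diis$iterations, damped$iterations)
  # damped Roothaan energy is monotonically non-increasing
  expect_true(all(diff(damped$log$energy) < 1e-10))
})

test_that("stored and direct SCF agree; embedding bookkeeping is exact", {
  g <- fix_water(); b <- load_basis(g, "toy-minimal")
  ch <- point_charges(rbind(c(3, 0.5, 0), c(-2.5, 1, 1)), c(0.4, -0.4))
  rs <- run_rhf(g, b, ch, scf_config(mode = "stored"))
  rd <- run_rhf(g, b, ch, scf_config(mode = "direct"))
  expect_equal(rs$total_energy, rd$total_energy, tolerance = 1e-9)
  # total = electronic + nuclear repulsion + charge-nucleus term
  expect_equal(rs$total_energy,
               rs$electronic_energy + rs$nuclear_repulsion +
                 rs$embedding_energy_terms$charge_nucleus,
               tolerance = 1e-12)
  # converged density is idempotent in the S metric
  PSP <- rs$density %*% rs$overlap %*% rs$density
  expect_equal(PSP, rs$density, tolerance = 1e-6)
  # all charges zero is bitwise the gas-phase result
  ch0 <- point_charges(ch$positions, c(0, 0))
  r0 <- run_rhf(g, b, ch0)
  rg <- run_rhf(g, b)
  expect_identical(r0$total_energy, rg$total_energy)
  expect_identical(r0$mo_coefficients, rg$mo_coefficients)
})

test_that("energy is invariant under rigid rotation+translation", {
  g <- fix_water(); b <- load_basis(g, "toy-minimal")
  ch <- point_charges(rbind(c(2.5, 0, 1)), -0.6)
  e1 <- run_rhf(g, b, ch)$total_energy
  R <- random_rotation(11)
  shift <- c(0.3, -1.2, 2.0)
  g2 <- geometry(g$elements,
                 t(R %*% t(g$coords)) + rep(shift, each = 3))
  ch2 <- point_charges(t(R %*% t(ch$positions)) +
                         rep(shift, each = 1), ch$charges)
  b2 <- load_basis(g2, "toy-minimal")
  e2 <- run_rhf(g2, b2, ch2)$total_energy
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("SCF guards: odd electrons, linear dependence, non-convergence", {
  g <- geometry("H", matrix(0, 1, 3))
  b <- load_basis(g, "toy-minimal")
  expect_error(run_rhf(g, b), "even electron")
  # two identical shells on one centre -> singular overlap
  b2 <- basis_set(list(gaussian_shell(1, 0, 1.0, 1.0),
                       gaussian_shell(1, 0, 1.0, 1.0)), g)
  expect_error(orthogonalizer(overlap_matrix(g, b2)), "eigenvalue")
  # an impossible iteration budget reports non-convergence, not silence
  gw <- fix_water(); bw <- load_basis(gw, "toy-minimal")
  expect_warning(
    r <- run_rhf(gw, bw, config = scf_config(max_iterations = 2)),
    "not converged")
  expect_false(r$converged)
  expect_match(r$diagnostic, "not converged")
})
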