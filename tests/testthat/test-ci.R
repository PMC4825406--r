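test_that("determinant counts match the binomial closed form", {
  expect_equal(enumerate_determinants(cas_space(2, 2))$n_determinants, 4L)
  expect_equal(enumerate_determinants(cas_space(2, 1))$n_determinants, 1L)
  expect_equal(enumerate_determinants(cas_space(4, 4))$n_determinants,
               36L)
  for (ne in c(2, 4, 6)) for (no in 2:6) {
    if (ne > 2 * no) next
    det <- enumerate_determinants(cas_space(ne, no))
    expect_equal(det$n_determinants,
                 choose(no, ne / 2)^2,
                 info = sprintf("CAS(%d,%d)", ne, no))
    # deterministic ordering: re-enumeration is identical
    det2 <- enumerate_determinants(cas_space(ne, no))
    expect_identical(det$alpha_strings, det2$alpha_strings)
  }
  # nonzero spin projection
  expect_equal(enumerate_determinants(
    cas_space(4, 4, spin_projection = 1))$n_determinants,
    choose(4, 3) * choose(4, 1))
  expect_error(cas_space(6, 2), "n_active_electrons")
})

test_that("sigma vector equals dense H c and is linear", {
  g <- fix_h2(); b <- load_basis(g, "toy-dz")
  scf <- run_rhf(g, b)
  for (spec in list(c(2, 3), c(2, 4), c(4, 4))) {
    cas <- cas_space(spec[1], spec[2])
    nc <- (2 * scf$n_occ - spec[1]) / 2
    if (nc < 0 || nc + spec[2] > b$n_basis) next
    mo <- transform_integrals(scf, n_core = nc, n_active = spec[2])
    det <- enumerate_determinants(cas)
    H <- ci_hamiltonian_dense(mo, det)
    expect_equal(H, t(H), tolerance = 1e-12)
    nd <- det$n_determinants
    set.seed(5)
    # unit vectors reproduce single columns of the dense matrix
    for (d in sample(nd, min(4, nd))) {
      e_d <- numeric(nd); e_d[d] <- 1
      expect_equal(sigma_vector(e_d, mo, det), H[, d], tolerance = 1e-10)
    }
    v1 <- rnorm(nd); v2 <- rnorm(nd)
    s1 <- sigma_vector(v1, mo, det)
    expect_equal(s1, as.vector(H %*% v1), tolerance = 1e-10)
    expect_equal(sigma_vector(2.5 * v1 - 0.7 * v2, mo, det),
                 2.5 * s1 - 0.7 * sigma_vector(v2, mo, det),
                 tolerance = 1e-9)
    # Rayleigh quotient bounded below by the lowest eigenvalue
    vn <- v1 / sqrt(sum(v1^2))
    expect_gte(sum(vn * sigma_vector(vn, mo, det)) + 1e-10,
               min(eigen(H, symmetric = TRUE)$values))
  }
})

test_that("Davidson and LOBPCG match a dense solver on random matrices", {
  set.seed(123)
  A <- matrix(rnorm(200 * 200), 200)
  A <- (A + t(A)) / 2
  evd <- eigen(A, symmetric = TRUE)
  lo <- sort(evd$values)[1:3]
  op <- function(V) A %*% V
  for (solver in c("davidson", "lobpcg")) {
    r <- solve_ci(op, diag(A), 3, solver = solver)
    expect_equal(r$values, lo, tolerance = 1e-9,
                 info = solver)
    # ascending, orthonormal states with small residuals
    expect_true(all(diff(r$values) >= -1e-12))
    expect_equal(crossprod(r$vectors), diag(3), tolerance = 1e-6)
    expect_true(all(r$residual_norms <= 1e-6))
    for (j in 1:3) {
      expect_lt(sqrt(sum((A %*% r$vectors[, j] -
                            r$values[j] * r$vectors[, j])^2)), 1e-5)
    }
  }
  # diagonal operator: exact answer immediately
  d <- sort(rnorm(50))
  rd <- solve_ci(function(V) d * V, d, 2)
  expect_equal(rd$values, d[1:2], tolerance = 1e-10)
  expect_error(solve_ci(op, diag(A), 0), "n_states")
})

test_that("CASCI: variational chain and dense-oracle equality", {
  g <- fix_h2(); b <- load_basis(g, "toy-dz")
  scf <- run_rhf(g, b)
  fci <- casci(scf, cas_space(2, 4))          # full CI in this basis
  cas22 <- casci(scf, cas_space(2, 2))
  expect_lte(fci$state_energies[1], cas22$state_energies[1] + 1e-12)
  expect_lte(cas22$state_energies[1], scf$total_energy + 1e-12)
  # CAS(2,1) is the single determinant: equals RHF
  cas21 <- casci(scf, cas_space(2, 1))
  expect_equal(cas21$state_energies[1], scf$total_energy,
               tolerance = 1e-10)
  # 3-state CAS(2,2) against dense diagonalization
  ci3 <- casci(scf, cas_space(2, 2), n_states = 3)
  mo <- ci3$mo
  H <- ci_hamiltonian_dense(mo, ci3$detspace)
  ev <- sort(eigen(H, symmetric = TRUE)$values)[1:3]
  expect_equal(ci3$ci_energies, ev, tolerance = 1e-8)
  # states orthonormal, energies ascending, sensible <S^2>
  expect_equal(crossprod(ci3$ci_vectors), diag(3), tolerance = 1e-8)
  expect_true(all(diff(ci3$state_energies) >= -1e-10))
  expect_true(all(abs(ci3$s2 - round(ci3$s2)) < 1e-6))
})

test_that("CASCI is invariant under core and virtual rotations", {
  gw <- fix_water(); bw <- load_basis(gw, "toy-minimal")
  scf <- run_rhf(gw, bw)
  cas <- cas_space(2, 2)      # core = 4 orbitals, active = 5,6, virtual 7
  e_ref <- casci(scf, cas)$state_energies[1]
  set.seed(9)
  Qc <- qr.Q(qr(matrix(rnorm(16), 4)))
  scf2 <- scf
  scf2$mo_coefficients[, 1:4] <- scf$mo_coefficients[, 1:4] %*% Qc
  expect_equal(casci(scf2, cas)$state_energies[1], e_ref,
               tolerance = 1e-9)
  # single virtual orbital: a sign flip is the only rotation
  scf3 <- scf
  scf3$mo_coefficients[, 7] <- -scf3$mo_coefficients[, 7]
  expect_equal(casci(scf3, cas)$state_energies[1], e_ref,
               tolerance = 1e-9)
})

test_that("state-averaged RDMs reproduce the CI energies", {
  g <- fix_h2(); b <- load_basis(g, "toy-dz")
  scf <- run_rhf(g, b)
  w <- c(0.6, 0.4)
  ci <- casci(scf, cas_space(2, 2), n_states = 2, weights = w)
  mo <- ci$mo
  # E_state = sum gamma h + 1/2 sum Gamma (pq|rs), active space only
  for (s in 1:2) {
    e <- sum(ci$one_rdm_per_state[[s]] * mo$one_electron) +
      0.5 * sum(ci$two_rdm_per_state[[s]] * mo$two_electron)
    expect_equal(e + mo$frozen_core_energy, ci$state_energies[s],
                 tolerance = 1e-9)
  }
  expect_equal(ci$sa_rdm1,
               w[1] * ci$one_rdm_per_state[[1]] +
                 w[2] * ci$one_rdm_per_state[[2]], tolerance = 1e-12)
  # RDM traces: n_active_electrons
  expect_equal(sum(diag(ci$sa_rdm1)), 2, tolerance = 1e-9)
})

test_that("infeasible CAS requests error", {
  g <- fix_h2(); b <- load_basis(g, "toy-minimal")
  scf <- run_rhf(g, b)
  expect_error(casci(scf, cas_space(2, 5)), "basis dimension")
  expect_error(casci(scf, cas_space(2, 2), n_states = 10),
               "more states")
})
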