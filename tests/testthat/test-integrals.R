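test_that("overlap: normalization, symmetry and quadrature oracle", {
  g1 <- geometry("H", matrix(0, 1, 3))
  b1 <- basis_set(list(gaussian_shell(1, 0, 1.0, 1.0)), g1)
  expect_equal(overlap_matrix(g1, b1)[1, 1], 1.0, tolerance = 1e-12)

  # contracted mixed-shell basis on a random two-atom geometry
  set.seed(42)
  g <- geometry(c("C", "O"), matrix(rnorm(6), 2, 3))
  b <- basis_set(list(gaussian_shell(1, 0, c(1.3, 0.4), c(0.7, 0.5)),
                      gaussian_shell(1, 1, c(0.9, 0.3), c(0.6, 0.6)),
                      gaussian_shell(2, 2, c(1.1, 0.35), c(0.5, 0.7)),
                      gaussian_shell(2, 0, 0.8, 1.0)), g)
  S <- overlap_matrix(g, b)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_equal(diag(S), rep(1, b$n_basis), tolerance = 1e-10)
  expect_true(min(eigen(S, symmetric = TRUE)$values) > 0)

  # two s primitives with unit exponents, 1 bohr apart, vs quadrature
  ang <- 0.52917721092
  g2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, ang)))
  b2 <- basis_set(list(gaussian_shell(1, 0, 1.0, 1.0),
                       gaussian_shell(2, 0, 1.0, 1.0)), g2)
  S2 <- overlap_matrix(g2, b2)
  nrm <- (2 / pi)^0.75
  q <- nrm^2 * quad_overlap(c(0, 0, 0), c(0, 0, 0), 1, 1, c(0, 0, 0),
                            c(0, 0, 1))
  expect_equal(S2[1, 2], q, tolerance = 1e-8)
})

test_that("overlap and kinetic match quadrature for p and d shells", {
  g <- geometry(c("C", "H"), rbind(c(0, 0, 0), c(0.2, -0.3, 0.5)))
  ad <- 0.9; ap <- 1.3
  b <- basis_set(list(gaussian_shell(1, 2, ad, 1.0),
                      gaussian_shell(2, 1, ap, 1.0)), g)
  S <- overlap_matrix(g, b)
  Tm <- kinetic_matrix(g, b)
  A <- g$coords[1, ] * BOHR; B <- g$coords[2, ] * BOHR
  comps_d <- list(c(2, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 2, 0),
                  c(0, 1, 1), c(0, 0, 2))
  comps_p <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (i in seq_along(comps_d)) {
    # normalization constants recovered from the unit diagonal: use the
    # quadrature self-overlaps as the independent normalizer
    ni <- 1 / sqrt(quad_overlap(comps_d[[i]], comps_d[[i]], ad, ad, A, A))
    for (j in seq_along(comps_p)) {
      nj <- 1 / sqrt(quad_overlap(comps_p[[j]], comps_p[[j]], ap, ap, B,
                                  B))
      sq <- ni * nj * quad_overlap(comps_d[[i]], comps_p[[j]], ad, ap, A,
                                   B)
      tq <- ni * nj * quad_kinetic(comps_d[[i]], comps_p[[j]], ad, ap, A,
                                   B)
      expect_equal(S[i, 6 + j], sq, tolerance = 1e-8)
      expect_equal(Tm[i, 6 + j], tq, tolerance = 1e-8)
    }
  }
  expect_true(min(eigen(Tm, symmetric = TRUE)$values) >= -1e-10)
})

test_that("kinetic diagonal of a single s primitive is 3a/2", {
  g1 <- geometry("H", matrix(0, 1, 3))
  for (a in c(0.3, 1.0, 4.2)) {
    b <- basis_set(list(gaussian_shell(1, 0, a, 1.0)), g1)
    expect_equal(kinetic_matrix(g1, b)[1, 1], 1.5 * a, tolerance = 1e-10)
  }
})

test_that("attraction: closed form, linearity, empty and coincident", {
  g1 <- geometry("H", matrix(0, 1, 3))
  b1 <- basis_set(list(gaussian_shell(1, 0, 1.0, 1.0)), g1)
  ang <- 0.52917721092
  # unit charge at 1.5 bohr: erf closed form for (s|1/r|s)
  ch <- point_charges(matrix(c(0, 0, 1.5 * ang), 1), 1.0)
  V <- attraction_matrix(g1, b1, ch)
  expect_equal(V[1, 1], -erf(sqrt(2) * 1.5) / 1.5, tolerance = 1e-8)
  # empty set -> zero matrix
  expect_equal(attraction_matrix(g1, b1, no_charges()),
               matrix(0, 1, 1))
  # exact linearity in the charges
  ch2 <- point_charges(ch$positions, 2 * ch$charges)
  expect_equal(attraction_matrix(g1, b1, ch2), 2 * V)
  # a charge on top of the basis centre is legal (Boys limit)
  ch0 <- point_charges(matrix(0, 1, 3), 1.0)
  V0 <- attraction_matrix(g1, b1, ch0)
  expect_false(anyNA(V0))
  expect_equal(V0[1, 1], -2 * sqrt(2 / pi), tolerance = 1e-8)
})

test_that("eri: closed-form oracle, 8-fold symmetry, generator parity", {
  g1 <- geometry("H", matrix(0, 1, 3))
  b1 <- basis_set(list(gaussian_shell(1, 0, 1.0, 1.0)), g1)
  eri <- eri_tensor(g1, b1)
  expect_equal(eri[1, 1, 1, 1],
               s_eri(1, 1, 1, 1, rep(0, 3), rep(0, 3), rep(0, 3),
                     rep(0, 3)),
               tolerance = 1e-7)

  g <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.4, 0.7, -0.2)))
  b <- basis_set(list(gaussian_shell(1, 0, c(1.2, 0.5), c(0.6, 0.5)),
                      gaussian_shell(1, 1, 0.8, 1.0),
                      gaussian_shell(2, 0, 0.45, 1.0)), g)
  E <- eri_tensor(g, b)
  n <- b$n_basis
  set.seed(1)
  for (trial in 1:25) {
    ix <- sample(n, 4, replace = TRUE)
    i <- ix[1]; j <- ix[2]; k <- ix[3]; l <- ix[4]
    v <- E[i, j, k, l]
    expect_equal(E[j, i, k, l], v)
    expect_equal(E[i, j, l, k], v)
    expect_equal(E[k, l, i, j], v)
    expect_equal(E[l, k, j, i], v)
  }
  gen <- eri_tensor(g, b, mode = "generator")
  for (trial in 1:20) {
    ix <- sample(n, 4, replace = TRUE)
    expect_equal(gen(ix[1], ix[2], ix[3], ix[4]),
                 E[ix[1], ix[2], ix[3], ix[4]], tolerance = 1e-12)
  }
  # two-centre s case against the closed form (primitive-normalized
  # already by construction)
  expect_equal(E[1, 1, n, n],
               {
         sh1 <- b$shells[[1]]
         A <- g$coords[1, ] * BOHR; Bc <- g$coords[2, ] * BOHR
         acc <- 0
         for (u in 1:2) for (v in 1:2) {
           acc <- acc + sh1$contraction_coeffs[u] *
             sh1$contraction_coeffs[v] /
             (s_norm(sh1$exponents[u]) * s_norm(sh1$exponents[v])) *
             s_eri(sh1$exponents[u], sh1$exponents[v], 0.45, 0.45,
                   A, A, Bc, Bc)
         }
         acc * b$norm[1]^2
       }, tolerance = 1e-7)
})

test_that("all integrals are translation invariant", {
  g <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0.1), c(0, 0.76, -0.47),
                      c(0, -0.76, -0.47)))
  mk <- function(gg) {
    b <- basis_set(list(gaussian_shell(1, 0, c(5.0, 1.2), c(0.4, 0.7)),
                        gaussian_shell(1, 1, 0.9, 1.0),
                        gaussian_shell(2, 0, 1.1, 1.0),
                        gaussian_shell(3, 0, 1.1, 1.0)), gg)
    ch <- point_charges(gg$coords[3, , drop = FALSE] + 2.5, -0.8)
    list(S = overlap_matrix(gg, b), T = kinetic_matrix(gg, b),
         V = attraction_matrix(gg, b, ch), E = eri_tensor(gg, b))
  }
  a <- mk(g)
  shift <- c(1.7, -2.2, 0.9)
  g2 <- geometry(g$elements, sweep(g$coords, 2, -shift))
  b2 <- mk(g2)
  expect_equal(a$S, b2$S, tolerance = 1e-10)
  expect_equal(a$T, b2$T, tolerance = 1e-10)
  expect_equal(a$V, b2$V, tolerance = 1e-10)
  expect_equal(a$E, b2$E, tolerance = 1e-10)
})

test_that("degenerate inputs error cleanly", {
  g1 <- geometry("H", matrix(0, 1, 3))
  expect_error(basis_set(list(), g1), "no basis functions")
  expect_error(gaussian_shell(1, 3, 1.0, 1.0), "angular momentum")
  expect_error(gaussian_shell(1, 0, -1.0, 1.0), "positive")
  b1 <- basis_set(list(gaussian_shell(1, 0, 1.0, 1.0)), g1)
  gen <- eri_tensor(g1, b1, mode = "generator")
  expect_error(gen(1, 1, 1, 2))
})
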