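# Independent oracles used across the suite. Everything here is
# deliberately written from first principles (quadrature, closed forms,
# brute-force loops) and never calls the package's integral recursions.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

BOHR <- 1 / 0.52917721092   # A -> bohr

# --- Gauss-Hermite nodes/weights (Golub-Welsch), weight exp(-x^2) --------
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  ev <- eigen(J, symmetric = TRUE)
  list(x = ev$values, w = sqrt(pi) * ev$vectors[1, ]^2)
}

# 1-D integral of (x-A)^la (x-B)^lb exp(-a(x-A)^2 - b(x-B)^2), exact by GH
dim1_gauss_product <- function(la, lb, a, b, A, B, gh = gauss_hermite(24)) {
  p <- a + b
  mu <- a * b / p
  P <- (a * A + b * B) / p
  t <- P + gh$x / sqrt(p)
  sum(gh$w * (t - A)^la * (t - B)^lb) * exp(-mu * (A - B)^2) / sqrt(p)
}

# quadrature overlap of two primitive Cartesian Gaussians (bohr inputs)
quad_overlap <- function(compA, compB, a, b, A, B) {
  prod(vapply(1:3, function(d) {
    dim1_gauss_product(compA[d], compB[d], a, b, A[d], B[d])
  }, numeric(1)))
}

# quadrature kinetic: -1/2 Laplacian applied symbolically to the ket,
# integrated dimension-wise with the GH rule
quad_kinetic <- function(compA, compB, a, b, A, B) {
  d2 <- function(l, bb, dim) {
    # second derivative of (x-B)^l exp(-bb (x-B)^2) expressed as overlap
    # integrals of shifted powers
    t1 <- if (l >= 2) l * (l - 1) *
      dim1_gauss_product(compA[dim], l - 2, a, bb, A[dim], B[dim]) else 0
    t2 <- -2 * bb * (2 * l + 1) *
      dim1_gauss_product(compA[dim], l, a, bb, A[dim], B[dim])
    t3 <- 4 * bb^2 *
      dim1_gauss_product(compA[dim], l + 2, a, bb, A[dim], B[dim])
    t1 + t2 + t3
  }
  s <- vapply(1:3, function(d) {
    dim1_gauss_product(compA[d], compB[d], a, b, A[d], B[d])
  }, numeric(1))
  lap <- vapply(1:3, function(d) d2(compB[d], b, d), numeric(1))
  -0.5 * (lap[1] * s[2] * s[3] + s[1] * lap[2] * s[3] +
            s[1] * s[2] * lap[3])
}

# closed-form integrals over *normalized s* primitives (bohr inputs)
s_norm <- function(a) (2 * a / pi)^0.75
s_overlap <- function(a, b, A, B) {
  p <- a + b
  s_norm(a) * s_norm(b) * (pi / p)^1.5 *
    exp(-a * b / p * sum((A - B)^2))
}
s_kinetic <- function(a, b, A, B) {
  p <- a + b; mu <- a * b / p; r2 <- sum((A - B)^2)
  mu * (3 - 2 * mu * r2) * s_overlap(a, b, A, B)
}
boys0 <- function(x) ifelse(x < 1e-12, 1 - x / 3,
                            0.5 * sqrt(pi / pmax(x, 1e-300)) *
                              erf(sqrt(pmax(x, 0))))
s_attraction <- function(a, b, A, B, C) {
  # (a_A | 1/|r-C| | b_B), normalized s primitives
  p <- a + b
  P <- (a * A + b * B) / p
  s_norm(a) * s_norm(b) * (2 * pi / p) *
    exp(-a * b / p * sum((A - B)^2)) * boys0(p * sum((P - C)^2))
}
s_eri <- function(a, b, c, d, A, B, C, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p; Q <- (c * C + d * D) / q
  s_norm(a) * s_norm(b) * s_norm(c) * s_norm(d) *
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((A - B)^2) - c * d / q * sum((C - D)^2)) *
    boys0(p * q / (p + q) * sum((P - Q)^2))
}

# --- reference RHF over s-only bases (closed forms + plain Roothaan) -----
# atoms: list of list(Z=, pos_bohr=, exps=, coefs=) with one contracted
# s function per atom; coefs are plain contraction weights.
reference_rhf_s <- function(atoms, n_elec, ext_pos = NULL, ext_q = NULL,
                            max_iter = 200) {
  nf <- length(atoms)
  contr <- function(f) {
    # contract a primitive-pair kernel over two shells
    M <- matrix(0, nf, nf)
    for (i in 1:nf) for (j in 1:nf) {
      ai <- atoms[[i]]; aj <- atoms[[j]]
      acc <- 0
      for (u in seq_along(ai$exps)) for (v in seq_along(aj$exps)) {
        acc <- acc + ai$coefs[u] * aj$coefs[v] *
          f(ai$exps[u], aj$exps[v], ai$pos, aj$pos)
      }
      M[i, j] <- acc
    }
    M
  }
  S <- contr(s_overlap)
  T <- contr(s_kinetic)
  V <- matrix(0, nf, nf)
  for (at in atoms) {
    V <- V - at$Z * contr(function(a, b, A, B) s_attraction(a, b, A, B,
                                                            at$pos))
  }
  if (!is.null(ext_pos)) {
    for (k in seq_along(ext_q)) {
      V <- V - ext_q[k] *
        contr(function(a, b, A, B) s_attraction(a, b, A, B, ext_pos[k, ]))
    }
  }
  # normalize contracted functions
  nn <- 1 / sqrt(diag(S))
  S <- S * outer(nn, nn); T <- T * outer(nn, nn); V <- V * outer(nn, nn)
  eri <- array(0, rep(nf, 4))
  for (i in 1:nf) for (j in 1:nf) for (k in 1:nf) for (l in 1:nf) {
    ai <- atoms[[i]]; aj <- atoms[[j]]; ak <- atoms[[k]]; al <- atoms[[l]]
    acc <- 0
    for (u in seq_along(ai$exps)) for (v in seq_along(aj$exps))
      for (w in seq_along(ak$exps)) for (z in seq_along(al$exps)) {
        acc <- acc + ai$coefs[u] * aj$coefs[v] * ak$coefs[w] *
          al$coefs[z] * s_eri(ai$exps[u], aj$exps[v], ak$exps[w],
                              al$exps[z], ai$pos, aj$pos, ak$pos, al$pos)
      }
    eri[i, j, k, l] <- acc * nn[i] * nn[j] * nn[k] * nn[l]
  }
  h <- T + V
  X <- {
    ev <- eigen(S, symmetric = TRUE)
    ev$vectors %*% diag(1 / sqrt(ev$values), nf) %*% t(ev$vectors)
  }
  nocc <- n_elec / 2
  P <- matrix(0, nf, nf)
  e_old <- Inf
  for (it in 1:max_iter) {
    G <- matrix(0, nf, nf)
    for (i in 1:nf) for (j in 1:nf) {
      G[i, j] <- sum(P * (2 * eri[i, j, , ] - eri[i, , , j]))
    }
    F <- h + G
    e <- sum(P * (h + F))
    Fp <- t(X) %*% F %*% X
    C <- X %*% eigen((Fp + t(Fp)) / 2, symmetric = TRUE)$vectors[,
      order(eigen((Fp + t(Fp)) / 2, symmetric = TRUE)$values),
      drop = FALSE]
    Pn <- tcrossprod(C[, seq_len(nocc), drop = FALSE])
    if (abs(e - e_old) < 1e-12 && max(abs(Pn - P)) < 1e-10) {
      P <- Pn; break
    }
    P <- 0.5 * Pn + 0.5 * P   # damped for robustness
    e_old <- e
  }
  enn <- 0
  if (length(atoms) > 1) {
    for (i in 1:(length(atoms) - 1)) for (j in (i + 1):length(atoms)) {
      enn <- enn + atoms[[i]]$Z * atoms[[j]]$Z /
        sqrt(sum((atoms[[i]]$pos - atoms[[j]]$pos)^2))
    }
  }
  eqn <- 0
  if (!is.null(ext_pos)) {
    for (at in atoms) for (k in seq_along(ext_q)) {
      eqn <- eqn + at$Z * ext_q[k] /
        sqrt(sum((at$pos - ext_pos[k, ])^2))
    }
  }
  G <- matrix(0, nf, nf)
  for (i in 1:nf) for (j in 1:nf) {
    G[i, j] <- sum(P * (2 * eri[i, j, , ] - eri[i, , , j]))
  }
  e_elec <- sum(P * (2 * h + G))
  list(energy = e_elec + enn + eqn, electronic = e_elec,
       nuclear = enn, charge_nucleus = eqn)
}

# random rigid rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}
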