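test_that("velocity initialization: zeros at 0 K, reproducible, correct KE", {
  m <- rep(18, 500)
  expect_equal(initialize_velocities(m, 0), matrix(0, 500, 3))
  v1 <- initialize_velocities(m, 300, seed = 5)
  v2 <- initialize_velocities(m, 300, seed = 5)
  expect_identical(v1, v2)
  expect_error(initialize_velocities(numeric(0), 300), "no atoms")
  # net momentum removed
  expect_equal(colSums(v1 * m), rep(0, 3), tolerance = 1e-10)
  # mean kinetic energy over repeated draws ~ (3N/2) kB T within 3 sigma
  kes <- vapply(1:100, function(s) {
    kinetic_temperature(initialize_velocities(m, 300, seed = s),
                        m)$kinetic
  }, numeric(1))
  expected <- 1.5 * 500 * qmmd_constants$kB_kcalmol * 300
  se <- stats::sd(kes) / 10
  expect_lt(abs(mean(kes) - expected), 3 * se + 0.01 * expected)
})

test_that("velocity Verlet: free flight, harmonic drift, reversibility", {
  # zero force: exact uniform linear motion
  free <- function(x) list(energy = 0, forces = 0 * x, extras = list())
  st <- list(positions = matrix(c(0, 0, 0), 1), velocities =
               matrix(c(0.01, -0.02, 0.005), 1),
             forces = matrix(0, 1, 3), masses = 1, time = 0)
  for (i in 1:50) st <- velocity_verlet_step(st, free, 0.5)
  expect_equal(st$positions, matrix(c(0.01, -0.02, 0.005) * 25, 1),
               tolerance = 1e-12)

  # 1-D harmonic oscillator: relative energy drift < 1e-6 over 1e4 steps
  k <- 10; m <- 1
  spring <- function(x) list(energy = k * x[1, 1]^2,
                             forces = matrix(c(-2 * k * x[1, 1], 0, 0), 1),
                             extras = list())
  period <- 2 * pi * sqrt(m / (2 * k * qmmd_constants$akma_accel))
  dt <- period / 100
  st <- list(positions = matrix(c(0.2, 0, 0), 1),
             velocities = matrix(0, 1, 3), forces =
               spring(matrix(c(0.2, 0, 0), 1))$forces, masses = m,
             time = 0)
  etot <- function(s) spring(s$positions)$energy +
    kinetic_temperature(s$velocities, m)$kinetic
  e0 <- etot(st)
  es <- numeric(10000)
  for (i in 1:10000) {
    st <- velocity_verlet_step(st, spring, dt)
    es[i] <- etot(st)
  }
  # symplectic integrator: the energy oscillates at O((w dt)^2) but has
  # no secular drift; compare the first and last thousand-step means
  expect_lt(abs(mean(es[9001:10000]) - mean(es[1:1000])) / e0, 1e-6)

  # time reversibility: negate velocities, return to the start
  ws <- gen_water_sphere(4, 2, seed = 11)
  bk <- mm_backend(ws$topology)
  x0 <- ws$geometry$coords
  v0 <- initialize_velocities(ws$geometry$masses, 80, seed = 2)
  st <- list(positions = x0, velocities = v0,
             forces = bk(x0)$forces, masses = ws$geometry$masses,
             time = 0)
  for (i in 1:200) st <- velocity_verlet_step(st, bk, 0.25)
  st$velocities <- -st$velocities
  for (i in 1:200) st <- velocity_verlet_step(st, bk, 0.25)
  expect_equal(st$positions, x0, tolerance = 1e-8)
})

test_that("run_md: zero steps, determinism, energy columns", {
  ws <- gen_water_sphere(4, 2, seed = 11)
  bk <- mm_backend(ws$topology)
  tr0 <- run_md(ws$geometry$coords, ws$geometry$masses, bk,
                md_config(n_steps = 0))
  expect_equal(nrow(tr0$energies), 1L)
  expect_length(tr0$frames, 1L)

  cfg <- md_config(timestep = 0.25, n_steps = 40,
                   initial_temperature = 60, seed = 9)
  tr1 <- run_md(ws$geometry$coords, ws$geometry$masses, bk, cfg)
  tr2 <- run_md(ws$geometry$coords, ws$geometry$masses, bk, cfg)
  expect_identical(tr1$energies, tr2$energies)   # same seed, same path
  expect_true(all(diff(tr1$energies$time_fs) > 0))
})

test_that("NVE drift bound scales roughly as dt^2", {
  ws <- gen_water_sphere(4, 2, seed = 11)
  bk <- mm_backend(ws$topology)
  drift <- function(dt, n) {
    tr <- run_md(ws$geometry$coords, ws$geometry$masses, bk,
                 md_config(timestep = dt, n_steps = n,
                           initial_temperature = 60, seed = 9))
    max(tr$energies$total) - min(tr$energies$total)
  }
  d1 <- drift(0.25, 400)
  d2 <- drift(0.5, 200)
  expect_lt(d1, d2)                # smaller step, smaller fluctuation
  expect_lt(d2 / d1, 16)           # and not absurdly off the dt^2 law
  expect_gt(d2 / d1, 1.5)
})

test_that("heating schedule reaches the target temperature", {
  ws <- gen_water_sphere(5, 5, seed = 23)
  bk <- mm_backend(ws$topology,
                   restraint = spherical_restraint(ws$center, 5, 100,
                                                   ws$water_oxygens))
  # compressed protocol: 1 -> 300 K over 0.25 ps, then hold 0.05 ps
  cfg <- md_config(timestep = 0.25, n_steps = 1200,
                   initial_temperature = 1,
                   heating = list(t_start = 1, t_end = 300,
                                  duration_ps = 0.25),
                   thermostat = "rescale", rescale_interval = 10,
                   seed = 4)
  tr <- run_md(ws$geometry$coords, ws$geometry$masses, bk, cfg)
  late <- tr$energies$temperature[tr$energies$time_fs > 250]
  expect_lt(abs(mean(late) - 300) / 300, 0.10)
})

test_that("emission analysis: bins, Gaussian recovery, unit identity", {
  # single frame -> one occupied bin
  e1 <- emission_analysis(c(363))
  expect_equal(sum(e1$histogram$count), 1L)
  expect_equal(sum(e1$histogram$count > 0), 1L)

  # synthetic Gaussian emulating the reported distribution shape
  set.seed(77)
  nm <- stats::rnorm(1e4, 363, 28)
  em <- emission_analysis(nm, bin_width_nm = 10)
  expect_lt(abs(em$mean_nm - 363) / 363, 0.01)
  expect_lt(abs(em$sd_nm - 28) / 28, 0.05)
  expect_equal(sum(em$histogram$count), 1e4)
  # bin width respected
  expect_equal(unique(em$histogram$nm_hi - em$histogram$nm_lo), 10)
  # minimum emission energy corresponds to the longest wavelength
  expect_equal(em$min_ev, qmmd_constants$evnm / max(nm), tolerance = 1e-12)

  # eV <-> nm conversion: 3.43 eV ~ 361.5 nm, consistent with a reported
  # 363 nm within two-decimal print rounding
  expect_equal(qmmd_constants$evnm / 3.43, 361.47, tolerance = 0.01)
  expect_lt(abs(qmmd_constants$evnm / 363 - 3.43), 0.015)

  # ground-state-only trajectory errors
  ws <- gen_water_sphere(4, 2, seed = 11)
  tr <- run_md(ws$geometry$coords, ws$geometry$masses,
               mm_backend(ws$topology), md_config(n_steps = 2))
  expect_error(emission_analysis(tr), "no emission")
})

test_that("trajectory statistics are independent of the logging interval", {
  ws <- gen_water_sphere(4, 2, seed = 11)
  bk <- mm_backend(ws$topology)
  cfg1 <- md_config(timestep = 0.25, n_steps = 30,
                    initial_temperature = 50, seed = 2, log_interval = 1)
  cfg5 <- md_config(timestep = 0.25, n_steps = 30,
                    initial_temperature = 50, seed = 2, log_interval = 5)
  tr1 <- run_md(ws$geometry$coords, ws$geometry$masses, bk, cfg1)
  tr5 <- run_md(ws$geometry$coords, ws$geometry$masses, bk, cfg5)
  expect_identical(tr1$energies, tr5$energies)
  expect_equal(tr5$frames[[length(tr5$frames)]]$positions,
               tr1$frames[[length(tr1$frames)]]$positions)
})
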