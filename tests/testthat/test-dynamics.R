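# MD engine: velocity initialization, integrators, thermostats, driver.

test_that("velocity initialization: exact rescale, zero T, ensemble statistics", {
  pot <- elastic_network_molecule(12, seed = 2)
  sys <- pot$system
  v <- init_velocities(sys, 300, "rescale_exact", seed = 1)
  st <- list(velocities = v, masses = sys$masses, periodic = FALSE)
  expect_equal(temperature(st), 300, tolerance = 1e-10)
  expect_lt(max(abs(colSums(sys$masses * v))), 1e-12)   # no COM momentum
  expect_equal(init_velocities(sys, 0, "rescale_exact"), matrix(0, 12, 3))
  # mean kinetic energy over many draws ~ (N_dof/2) k_B T at the draw temp
  kes <- vapply(1:1000, function(s)
    euclidff:::kinetic_energy(init_velocities(sys, 100, "boltzmann_2T",
                                              seed = s), sys$masses),
    numeric(1))
  expected <- 0.5 * (3 * 12 - 3) * ff_constants$k_B * 200   # draws at 2T
  expect_lt(abs(mean(kes) - expected) / (stats::sd(kes) / sqrt(1000)), 4)
})

test_that("temperature bookkeeping: conventions and scaling", {
  m <- c(12, 12)
  st <- list(velocities = matrix(0, 2, 3), masses = m, periodic = FALSE)
  expect_equal(temperature(st), 0)
  st$velocities <- matrix(0.01, 2, 3)
  T1 <- temperature(st)
  st$velocities <- 2 * st$velocities
  expect_equal(temperature(st), 4 * T1)
  lone <- list(velocities = matrix(1, 1, 3), masses = 1, periodic = FALSE)
  expect_error(temperature(lone), "single isolated atom")
})

test_that("velocity Verlet: free flight, harmonic period, time reversal", {
  # free particle: exact uniform motion
  free_pot <- make_potential(atomic_system(18, matrix(0, 1, 3)),
                             function(p) list(energy = 0,
                                              forces = matrix(0, nrow(p), 3)),
                             check_forces = FALSE)
  st <- euclidff:::.md_state(free_pot$system, matrix(c(0.01, 0, 0), 1),
                             free_pot$ef(free_pot$system$positions))
  for (k in 1:100) st <- verlet_step(st, free_pot, 1)
  expect_equal(st$positions[1, 1], 0.01 * 100, tolerance = 1e-12)

  # diatomic spring: period 2 pi sqrt(mu / k-eff)
  k_spring <- 20
  pot <- harmonic_molecule(rbind(c(1, 2)), k = k_spring, r0 = 1.5,
                           z = c(6, 6),
                           positions = rbind(c(0, 0, 0), c(1.55, 0, 0)))
  sys <- pot$system
  mu <- prod(sys$masses) / sum(sys$masses)
  omega <- sqrt(k_spring / mu * ff_constants$accel_unit)
  period <- 2 * pi / omega
  dt <- period / 400
  st <- euclidff:::.md_state(sys, matrix(0, 2, 3), pot$ef(sys$positions))
  nsteps <- round(period / dt)
  lens <- numeric(nsteps)
  for (k in seq_len(nsteps)) {
    st <- verlet_step(st, pot, dt)
    lens[k] <- st$positions[2, 1] - st$positions[1, 1]
  }
  # bond length back near its start after one period
  expect_equal(lens[nsteps], 1.55, tolerance = 1e-4)
  expect_lt(min(lens), 1.451)   # swung through the other turning point

  # time reversal: integrate, flip velocities, integrate back
  set.seed(21)
  pot2 <- elastic_network_molecule(8, seed = 3)
  v0 <- init_velocities(pot2$system, 300, "rescale_exact", seed = 5)
  st <- euclidff:::.md_state(pot2$system, v0, pot2$ef(pot2$system$positions))
  for (k in 1:100) st <- verlet_step(st, pot2, 0.25)
  st$velocities <- -st$velocities
  for (k in 1:100) st <- verlet_step(st, pot2, 0.25)
  expect_lt(max(abs(st$positions - pot2$system$positions)), 1e-8)
})

test_that("Langevin with zero friction reproduces the Verlet trajectory", {
  pot <- elastic_network_molecule(6, seed = 4)
  v0 <- init_velocities(pot$system, 200, "rescale_exact", seed = 2)
  s1 <- euclidff:::.md_state(pot$system, v0, pot$ef(pot$system$positions))
  s2 <- s1
  for (k in 1:200) {
    s1 <- verlet_step(s1, pot, 0.5)
    s2 <- langevin_step(s2, pot, 0.5, T = 200, gamma = 0)
  }
  expect_equal(s2$positions, s1$positions, tolerance = 1e-12)
})

test_that("Langevin thermostat reaches its target temperature and variance", {
  # single particle in a 3-D harmonic trap: closed-form stationary variance
  k_trap <- 5
  trap <- make_potential(
    atomic_system(18, matrix(0, 1, 3), masses = 40),
    function(p) list(energy = 0.5 * k_trap * sum(p^2),
                     forces = -k_trap * p),
    check_forces = FALSE)
  st <- structure(list(positions = matrix(0, 1, 3),
                       velocities = matrix(0, 1, 3), masses = 40,
                       time = 0, epot = 0, forces = matrix(0, 1, 3),
                       periodic = TRUE),  # count all 3 dof for one particle
                  class = "md_state")
  set.seed(31)
  Ttar <- 300
  nst <- 60000
  pos2 <- numeric(nst); kes <- numeric(nst)
  for (s in seq_len(nst)) {
    st <- langevin_step(st, trap, dt = 2, T = Ttar, gamma = 0.05)
    pos2[s] <- sum(st$positions^2)
    kes[s] <- euclidff:::kinetic_energy(st$velocities, st$masses)
  }
  burn <- seq_len(5000)
  Tmean <- mean(2 * kes[-burn] / (3 * ff_constants$k_B))
  expect_lt(abs(Tmean - Ttar) / Ttar, 0.05)
  var_ref <- 3 * ff_constants$k_B * Ttar / k_trap     # <|x|^2> = 3 kBT / k
  expect_lt(abs(mean(pos2[-burn]) - var_ref) / var_ref, 0.05)
})

test_that("Nose-Hoover: NVE limit, target temperature, conserved quantity", {
  pot <- elastic_network_molecule(8, seed = 6)
  v0 <- init_velocities(pot$system, 250, "rescale_exact", seed = 3)
  # tau -> infinity approaches NVE
  s_nve <- euclidff:::.md_state(pot$system, v0, pot$ef(pot$system$positions))
  s_nh <- s_nve
  for (k in 1:200) {
    s_nve <- verlet_step(s_nve, pot, 0.5)
    s_nh <- nose_hoover_step(s_nh, pot, 0.5, T = 250, tau = 1e9)
  }
  expect_equal(s_nh$positions, s_nve$positions, tolerance = 1e-6)
  # long run: mean temperature within 5% and small extended-energy drift
  traj_T <- numeric(0)
  st <- euclidff:::.md_state(pot$system, v0, pot$ef(pot$system$positions))
  econs <- numeric(0)
  for (k in 1:40000) {
    st <- nose_hoover_step(st, pot, 0.25, T = 250, tau = 25)
    if (k %% 10 == 0) {
      traj_T <- c(traj_T, temperature(st))
      econs <- c(econs, euclidff:::nose_hoover_energy(st, 250, 25))
    }
  }
  expect_lt(abs(mean(traj_T[-(1:400)]) - 250) / 250, 0.05)
  # secular drift of the conserved quantity (slope x duration), separated
  # from the bounded O(dt^2) oscillation
  fit <- stats::lm(econs ~ seq_along(econs))
  drift <- abs(stats::coef(fit)[2]) * length(econs) / abs(econs[1])
  expect_lt(drift, 1e-3)
})

test_that("run_md frame bookkeeping and reproducibility", {
  pot <- elastic_network_molecule(6, seed = 7)
  t1 <- run_md(pot$system, pot, "verlet", dt = 0.5, steps = 1000,
               stride = 10, seed = 4, T_target = 100)
  expect_length(t1$frames, 101)
  expect_equal(t1$frames[[101]]$time, 500)
  t2 <- run_md(pot$system, pot, "langevin", dt = 0.5, steps = 200,
               stride = 5, seed = 9, T_target = 100)
  t3 <- run_md(pot$system, pot, "langevin", dt = 0.5, steps = 200,
               stride = 5, seed = 9, T_target = 100)
  expect_identical(t2$frames[[41]]$positions, t3$frames[[41]]$positions)
})
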