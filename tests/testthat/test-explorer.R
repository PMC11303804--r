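# PES exploration: relaxation, RMSD over SO(3), escape, hopping,
# disconnectivity.

test_that("relaxation: quadratic bowl, LJ dimer, already-relaxed input", {
  # exact quadratic bowl: quasi-Newton lands on the analytic minimum
  ctr <- rbind(c(0.3, -0.2, 0.5), c(1.8, 0.1, -0.4))
  bowl <- make_potential(
    atomic_system(c(18, 18), ctr + 0.3),
    function(p) list(energy = 0.5 * sum((p - ctr)^2), forces = -(p - ctr)),
    check_forces = FALSE)
  res <- relax(bowl$system, bowl, f_max = 1e-8)
  expect_equal(res$system$positions, ctr, tolerance = 1e-6)

  sigma <- 3.405
  pot <- lj_potential(2, sigma = sigma)
  start <- pot$system
  start$positions <- rbind(c(0, 0, 0), c(4.2, 0, 0))
  res <- relax(start, pot, f_max = 1e-8)
  expect_equal(dist(res$system$positions)[1], lj_dimer_r_eq(sigma),
               tolerance = 1e-5)
  expect_equal(res$energy, -0.0104, tolerance = 1e-8)

  # already-relaxed input comes back unchanged
  res2 <- relax(res$system, pot, f_max = 1e-6)
  expect_equal(res2$system$positions, res$system$positions,
               tolerance = 1e-12)
  expect_equal(res2$iterations, 0)
})

test_that("rmsd_so3: rigid copies, two-atom closed form, grid-search oracle", {
  set.seed(51)
  A <- rand_system(6)
  R <- rand_rotation()
  B <- A
  B$positions <- A$positions %*% t(R) + matrix(c(2, -3, 1), 6, 3, byrow = TRUE)
  expect_lt(rmsd_so3(A, B), 1e-10)

  # diatomic stretched by delta along the bond: rmsd = delta / sqrt(2)
  # (each atom moves delta/2 from the COM-centered reference)
  d0 <- 2.0; delta <- 0.3
  P <- atomic_system(c(18, 18), rbind(c(0, 0, 0), c(d0, 0, 0)))
  Q <- atomic_system(c(18, 18), rbind(c(0, 0, 0), c(d0 + delta, 0, 0)))
  expect_equal(rmsd_so3(P, Q), delta / 2, tolerance = 1e-10)

  # Kabsch equals brute-force minimization over a fine rotation grid
  C <- rand_system(5)
  D <- C
  D$positions <- C$positions + matrix(stats::rnorm(15, sd = 0.3), 5, 3)
  got <- rmsd_so3(C, D)
  center <- function(s) {
    w <- s$masses / sum(s$masses)
    sweep(s$positions, 2, colSums(w * s$positions))
  }
  Pc <- center(C); Qc <- center(D)
  euler_rmsd <- function(a, b, g) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    sqrt(sum((Qc - Pc %*% t(Rz1 %*% Ry %*% Rz2))^2) / 5)
  }
  angs <- seq(0, 2 * pi, length.out = 25)[-25]
  coarse <- expand.grid(a = angs, b = seq(0, pi, length.out = 13), g = angs)
  vals <- vapply(seq_len(nrow(coarse)), function(q)
    euler_rmsd(coarse$a[q], coarse$b[q], coarse$g[q]), numeric(1))
  # refine around the best coarse candidates (several basins exist)
  best <- min(vals)
  for (cand in order(vals)[1:20]) {
    arg <- as.numeric(coarse[cand, ])
    loc <- vals[cand]
    step <- pi / 12
    for (pass in 1:3) {
      grid <- expand.grid(a = arg[1] + seq(-step, step, length.out = 5),
                          b = arg[2] + seq(-step, step, length.out = 5),
                          g = arg[3] + seq(-step, step, length.out = 5))
      for (q in seq_len(nrow(grid))) {
        v <- euler_rmsd(grid$a[q], grid$b[q], grid$g[q])
        if (v < loc) { loc <- v; arg <- as.numeric(grid[q, ]) }
      }
      step <- step / 4
    }
    best <- min(best, loc)
  }
  expect_lte(got, best + 1e-12)
  expect_lt(best - got, 5e-3)    # refined-grid resolution
  expect_error(rmsd_so3(A, atomic_system(c(1, 1), matrix(0, 2, 3))),
               "composition")
})

test_that("escape: step count, zero-temperature fixed point, barrier bound", {
  pot <- double_well_molecule()
  minA <- relax(pot$system, pot, f_max = 1e-8)
  expect_equal(round(1000 / 0.5), 2000)   # 1 ps at 0.5 fs
  esc0 <- escape(minA, pot, T = 0, escape_fs = 50, dt = 0.5, seed = 1)
  back <- relax(esc0$system, pot, f_max = 1e-8)
  expect_lt(rmsd_so3(back$system, minA$system), 1e-6)
  esc <- escape(minA, pot, T = 600, escape_fs = 500, dt = 0.5, seed = 2)
  expect_gte(esc$e_max, minA$energy)
})

test_that("double-well molecule: two minima and a barrier-bounded transition", {
  barrier <- 0.4
  pot <- double_well_molecule(r_short = 1.0, r_long = 2.0, barrier = barrier)
  hist <- minima_hop(pot$system, pot, T0 = 1500, E_diff = 1, adapt = 1.05,
                     rmsd_threshold = 0.1, max_minima = 2, max_trials = 40,
                     escape_fs = 300, dt = 0.25, f_max = 1e-6, seed = 2)
  expect_length(hist$minima, 2)
  seps <- sort(vapply(hist$minima, function(m)
    dist(m$system$positions)[1], numeric(1)))
  expect_equal(seps, c(1, 2), tolerance = 1e-4)
  # recorded transition-state estimate is an upper bound on the barrier
  tr <- hist$transitions
  expect_gt(nrow(tr), 0)
  expect_gte(min(tr$e_ts), barrier - 1e-9)
})

test_that("identity merging groups rigid-motion copies into one entry", {
  pot <- double_well_molecule()
  minA <- relax(pot$system, pot, f_max = 1e-8)
  set.seed(53)
  copies <- lapply(1:5, function(k) {
    s <- minA$system
    R <- rand_rotation()
    s$positions <- s$positions %*% t(R) + matrix(stats::rnorm(3), 2, 3,
                                                 byrow = TRUE)
    s
  })
  for (s in copies) {
    m2 <- relax(s, pot, f_max = 1e-8)
    expect_lt(rmsd_so3(m2$system, minA$system), 0.1)
  }
})

test_that("stored minima energies are reproducible by re-relaxation", {
  pot <- lj_potential(4)
  hist <- minima_hop(pot$system, pot, T0 = 40, E_diff = 0.05, adapt = 1.05,
                     max_minima = 3, max_trials = 15, escape_fs = 2000,
                     dt = 5, f_max = 1e-6, seed = 4)
  for (k in seq_along(hist$minima)) {
    re <- relax(hist$minima[[k]]$system, pot, f_max = 1e-6)
    expect_lt(abs(re$energy - hist$energies[k]), 1e-6)
  }
})

test_that("disconnectivity: merge levels respect barriers and minima", {
  hist <- structure(list(
    minima = vector("list", 3),
    energies = c(-1.0, -0.8, -0.5),
    visits = c(2L, 1L, 1L),
    discovered = c(0L, 1L, 3L),
    transitions = data.frame(a = c(1L, 2L, 1L), b = c(2L, 3L, 2L),
                             e_ts = c(-0.2, 0.3, -0.35)),
    trials = 4L), class = "minima_history")
  g <- disconnectivity(hist, level_spacing = 0.05)
  # single component at the top; merge energies never below the minima
  expect_equal(length(unique(g$components)), 1)
  expect_true(all(g$merges$level >= apply(g$merges[, c("a", "b")], 1,
                                          function(ab)
                                            max(hist$energies[ab]))))
  # chain merges in ascending barrier order: (1,2) joins before (2,3)
  first12 <- min(g$merges$level[(g$merges$a == 1 & g$merges$b == 2) |
                                  (g$merges$a == 2 & g$merges$b == 1)])
  first23 <- min(g$merges$level[(g$merges$a == 2 & g$merges$b == 3) |
                                  (g$merges$a == 3 & g$merges$b == 2)])
  expect_lt(first12, first23)
  # two minima, one transition: single merge at the transition level grid
  hist2 <- hist
  hist2$minima <- vector("list", 2)
  hist2$energies <- c(-1, -0.9)
  hist2$transitions <- data.frame(a = 1L, b = 2L, e_ts = -0.4)
  g2 <- disconnectivity(hist2, level_spacing = 0.1)
  expect_equal(nrow(g2$merges), 1)
  expect_gte(g2$merges$level[1], -0.4)
  expect_lt(g2$merges$level[1], -0.4 + 0.1 + 1e-12)
  # disconnected minima are reported, not an error
  hist3 <- hist2
  hist3$transitions <- hist3$transitions[0, ]
  g3 <- disconnectivity(hist3)
  expect_equal(length(unique(g3$components)), 2)
})
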