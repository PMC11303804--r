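# The Euclidean transformer: building blocks, symmetries, forces,
# parameter bookkeeping, checkpointing.

test_that("embedding lookup and its error handling", {
  model <- small_model()
  f <- embed_features(c(6, 6, 1), model)
  expect_equal(f[1, ], f[2, ])
  expect_false(isTRUE(all.equal(f[1, ], f[3, ])))
  p <- c(3, 1, 2)
  expect_equal(embed_features(c(6, 6, 1)[p], model), f[p, ])
  expect_error(embed_features(119, model), "embedding table")
})

test_that("EV initialization: empty, single-neighbor and symmetric shells", {
  cfg <- model_config(feature_dim = 32, heads = 4, n_blocks = 1,
                      degrees = 0:3, r_cut = 5, mean_neighbors = 2)
  lone <- atomic_system(6, matrix(0, 1, 3))
  expect_equal(init_ev(lone, build_neighbors(lone, 5), cfg),
               matrix(0, 1, 16))
  # single neighbor along +z: x_00 = phi(r) Y_00 / <N>
  r <- 2
  pair <- atomic_system(c(6, 6), rbind(c(0, 0, 0), c(0, 0, r)))
  ev <- init_ev(pair, build_neighbors(pair, 5), cfg)
  expect_equal(ev[1, 1], cutoff(r, 5) / (2 * sqrt(pi)) / 2, tolerance = 1e-12)
  # centrosymmetric shell: odd-degree blocks vanish
  oct <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
               c(0, 0, 2), c(0, 0, -2))
  shell <- atomic_system(rep(6, 7), rbind(c(0, 0, 0), oct))
  evs <- init_ev(shell, build_neighbors(shell, 3), cfg)
  odd <- c(2:4, 10:16)     # l = 1 and l = 3 blocks in the 0:3 layout
  expect_lt(max(abs(evs[1, odd])), 1e-14)
  expect_gt(abs(evs[1, 1]), 0)
})

test_that("cutoff function hits its anchor values and vanishes beyond", {
  expect_equal(cutoff(0, 5), 1)
  expect_equal(cutoff(5, 5), 0)
  expect_equal(cutoff(2.5, 5), 0.5)
  expect_equal(cutoff(7, 5), 0)
})

test_that("radial basis: unit peak at centers, bounded in (0, 1]", {
  cfg <- model_config(feature_dim = 32, heads = 4, degrees = 0:1,
                      r_cut = 5, n_rbf = 8, mean_neighbors = 1)
  mu <- cfg$rbf_centers
  r_at_center <- -log(mu[4])
  g <- rbf(r_at_center, cfg)
  expect_equal(g[1, 4], 1, tolerance = 1e-12)
  set.seed(11)
  g2 <- rbf(stats::runif(50, 0, 6), cfg)
  expect_true(all(g2 > 0 & g2 <= 1))
})

test_that("zeroed filter weights silence attention; zeroed interaction is identity", {
  set.seed(12)
  sys <- rand_system(5)
  model <- small_model(degrees = 0:3, T = 1)
  # zero both filter branches -> w = 0 -> alpha = 0 -> attention is a no-op
  m0 <- model
  for (nm in c("W1u", "b1u", "W2u", "b2u", "W1g", "b1g", "W2g", "b2g"))
    m0$params$blocks[[1]][[nm]][] <- 0
  st <- forward_states(sys, m0)
  expect_equal(st$blocks[[1]]$f_att, st$f0, tolerance = 1e-14)
  expect_equal(st$blocks[[1]]$x_att, st$x0, tolerance = 1e-14)
  # additionally zero the interaction block -> whole block is the identity
  m00 <- m0
  m00$params$blocks[[1]]$Wi[] <- 0
  m00$params$blocks[[1]]$bi[] <- 0
  st2 <- forward_states(sys, m00)
  expect_equal(st2$blocks[[1]]$f, st2$f0, tolerance = 1e-14)
  expect_equal(st2$blocks[[1]]$x, st2$x0, tolerance = 1e-14)
})

test_that("energy is invariant under rotation, translation, permutation, inversion", {
  set.seed(13)
  for (trial in 1:5) {
    n <- sample(3:10, 1)
    sys <- rand_system(n)
    model <- small_model(seed = trial)
    E0 <- forward_energy(sys, model)$energy
    R <- rand_rotation()
    sR <- sys; sR$positions <- sys$positions %*% t(R)
    sT <- sys; sT$positions <- sys$positions + 5
    p <- sample(n)
    sP <- atomic_system(sys$atomic_numbers[p], sys$positions[p, ])
    sI <- sys; sI$positions <- -sys$positions
    for (s2 in list(sR, sT, sP, sI)) {
      expect_equal(forward_energy(s2, model)$energy, E0,
                   tolerance = 1e-10)
    }
  }
})

test_that("features stay invariant and EV equivariant after every block", {
  set.seed(14)
  sys <- rand_system(6)
  model <- small_model(degrees = 0:3, T = 2)
  R <- rand_rotation()
  sR <- sys; sR$positions <- sys$positions %*% t(R)
  st <- forward_states(sys, model)
  stR <- forward_states(sR, model)
  degrees <- model$config$degrees
  rot_rows <- function(X) {
    out <- X
    ofs <- 0
    for (l in degrees) {
      idx <- ofs + seq_len(2 * l + 1)
      out[, idx] <- X[, idx] %*% t(wigner_d(R, l))
      ofs <- ofs + 2 * l + 1
    }
    out
  }
  expect_equal(stR$x0, rot_rows(st$x0), tolerance = 1e-10)
  for (t in seq_along(st$blocks)) {
    expect_equal(stR$blocks[[t]]$f_att, st$blocks[[t]]$f_att,
                 tolerance = 1e-10)
    expect_equal(stR$blocks[[t]]$f, st$blocks[[t]]$f, tolerance = 1e-10)
    expect_equal(stR$blocks[[t]]$x_att, rot_rows(st$blocks[[t]]$x_att),
                 tolerance = 1e-10)
    expect_equal(stR$blocks[[t]]$x, rot_rows(st$blocks[[t]]$x),
                 tolerance = 1e-10)
  }
})

test_that("isolated fragments are additive and the energy is size-consistent", {
  model <- small_model()
  lone <- atomic_system(6, matrix(0, 1, 3))
  pairFar <- atomic_system(c(6, 6), rbind(c(0, 0, 0), c(50, 0, 0)))
  E1 <- forward_energy(lone, model)$energy
  E2 <- forward_energy(pairFar, model)$energy
  expect_equal(E2, 2 * E1, tolerance = 1e-12)
})

test_that("energy is continuous as an atom crosses the cutoff sphere", {
  model <- small_model(degrees = 0:3, T = 2)
  rc <- model$config$r_cut
  probe <- function(d) {
    sys <- atomic_system(c(6, 6, 1),
                         rbind(c(0, 0, 0), c(1.2, 0, 0), c(d, 0.3, 0)))
    forward_energy(sys, model)$energy
  }
  eps <- 1e-8
  expect_lt(abs(probe(rc - eps) - probe(rc + eps)), 1e-8)
  # and a coarse scan shows no jump anywhere near the cutoff
  ds <- seq(rc - 0.01, rc + 0.01, length.out = 21)
  es <- vapply(ds, probe, numeric(1))
  expect_lt(max(abs(diff(es))), 1e-4)
})

test_that("analytic forces: zero net force, covariance, finite differences", {
  set.seed(15)
  sys <- rand_system(6)
  model <- small_model()
  fr <- forces(sys, model)
  expect_lt(max(abs(colSums(fr$forces))), 1e-10)
  R <- rand_rotation()
  sR <- sys; sR$positions <- sys$positions %*% t(R)
  frR <- forces(sR, model)
  expect_equal(frR$forces, fr$forces %*% t(R), tolerance = 1e-9)
  h <- 1e-4
  fd <- matrix(0, 6, 3)
  for (i in 1:6) for (k in 1:3) {
    sp <- sys; sp$positions[i, k] <- sp$positions[i, k] + h
    sm <- sys; sm$positions[i, k] <- sm$positions[i, k] - h
    fd[i, k] <- -(forward_energy(sp, model)$energy -
                    forward_energy(sm, model)$energy) / (2 * h)
  }
  expect_lt(max(abs(fd - fr$forces)) / max(abs(fr$forces)), 1e-5)
})

test_that("parameter counts: determinism, embedding arithmetic, degree scaling", {
  cfg <- model_config(feature_dim = 32, heads = 4, n_blocks = 2,
                      degrees = 0:3, max_atomic_number = 10)
  p1 <- init_params(cfg, seed = 7)
  p2 <- init_params(cfg, seed = 7)
  expect_identical(count_params(p1), count_params(p2))
  expect_identical(euclidff:::params_flatten_any(p1), euclidff:::params_flatten_any(p2))
  expect_equal(length(p1$emb), 10 * 32)
  # invariant-only vs full-degree models at production width differ little
  inv <- model_config(feature_dim = 132, heads = 4, n_blocks = 3,
                      degrees = 0L)
  eqv <- model_config(feature_dim = 132, heads = 4, n_blocks = 3,
                      degrees = 0:3)
  ci <- count_params(init_params(inv, 1))
  ce <- count_params(init_params(eqv, 1))
  expect_lt(abs(ci - ce) / max(ci, ce), 0.25)
})

test_that("checkpoints round-trip the model bit for bit", {
  set.seed(16)
  sys <- rand_system(5)
  model <- small_model(seed = 3)
  E0 <- forward_energy(sys, model)$energy
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  m2 <- load_checkpoint(path)
  expect_identical(forward_energy(sys, m2)$energy, E0)
  expect_identical(euclidff:::params_flatten_any(m2$params),
                   euclidff:::params_flatten_any(model$params))
  # corrupted file fails with a checked error, not a crash
  writeLines("not json at all {", path)
  expect_error(load_checkpoint(path), "corrupt|checkpoint")
})
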