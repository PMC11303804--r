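# Analytic toy potentials and synthetic labeled datasets. These stand in
# for quantum-chemistry-labeled configuration datasets: every stage of the
# package (training, dynamics, stability, observurables, exploration) can be
# exercised against them with exactly known energies and forces.

#' Lennard-Jones cluster potential
#'
#' All-pair 12-6 Lennard-Jones energy
#' \eqn{E = \sum_{i<j} 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} with
#' analytic forces. Defaults are argon-like (\eqn{\epsilon} = 0.0104 eV,
#' \eqn{\sigma} = 3.405 A), so that cluster energetics, sampling
#' temperatures and MD time steps live on physically familiar scales.
#'
#' @param n_atoms number of atoms in the template cluster.
#' @param epsilon well depth, eV.
#' @param sigma length parameter, Angstrom.
#' @param z atomic number used for the template atoms (default 18, argon).
#' @return an `ff_potential` whose template is a compact cluster geometry.
#' @export
lj_potential <- function(n_atoms = 7, epsilon = 0.0104, sigma = 3.405,
                         z = 18) {
  ef <- function(positions) {
    n <- nrow(positions)
    en <- 0
    f <- matrix(0, n, 3)
    for (i in seq_len(n - 1)) {
      d <- positions[(i + 1):n, , drop = FALSE] -
        matrix(positions[i, ], n - i, 3, byrow = TRUE)
      r2 <- rowSums(d * d)
      s6 <- (sigma^2 / r2)^3
      en <- en + sum(4 * epsilon * (s6^2 - s6))
      # dE/dr2 = 4 eps (-12 s12 + 6 s6)/(2 r2); force on j is -dE/dd
      coef <- 4 * epsilon * (-12 * s6^2 + 6 * s6) / r2
      fij <- coef * d          # dE/dd rows
      f[(i + 1):n, ] <- f[(i + 1):n, ] - fij
      f[i, ] <- f[i, ] + colSums(fij)
    }
    list(energy = en, forces = f)
  }
  sys <- atomic_system(rep(z, n_atoms), .compact_cluster(n_atoms, 2^(1/6) * sigma))
  make_potential(sys, ef, label = sprintf("LJ%d cluster", n_atoms))
}

# deterministic compact starting geometry: atoms placed on a slightly
# perturbed icosahedral-ish shell around the origin
.compact_cluster <- function(n, a) {
  set.seed(n)
  pos <- matrix(stats::rnorm(3 * n), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) * a * 0.9
  pos[1, ] <- 0
  jitter <- matrix(stats::runif(3 * n, -0.05, 0.05) * a, ncol = 3)
  pos + jitter
}

#' Harmonic "molecule" potential
#'
#' \eqn{E = \sum_{bonds} \frac{1}{2} k (r - r_0)^2} over a fixed bond
#' topology, with exact analytic forces and a closed-form normal-mode
#' spectrum for simple topologies. The topology must be connected.
#'
#' @param topology 2-column integer matrix of bonded atom pairs.
#' @param k spring constant(s), eV/A^2 (recycled over bonds).
#' @param r0 rest length(s), Angstrom (recycled over bonds).
#' @param z atomic numbers of the atoms (default all carbon).
#' @param positions optional template geometry; defaults to a near-rest
#'   chain layout along x.
#' @export
harmonic_molecule <- function(topology, k = 30, r0 = 1.5, z = NULL,
                              positions = NULL) {
  topology <- matrix(as.integer(topology), ncol = 2)
  n <- max(topology)
  # connectivity check by flood fill
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(c(topology[topology[, 1] %in% frontier, 2],
                    topology[topology[, 2] %in% frontier, 1]))
    frontier <- nxt[!seen[nxt]]
    seen[frontier] <- TRUE
  }
  if (!all(seen)) stop("bond topology is disconnected")
  k <- rep_len(k, nrow(topology))
  r0 <- rep_len(r0, nrow(topology))
  if (is.null(z)) z <- rep(6L, n)
  if (is.null(positions)) {
    positions <- cbind(seq_len(n) * mean(r0), 0, 0)
    positions <- positions + matrix(stats::runif(3 * n, -0.01, 0.01), ncol = 3)
  }
  ef <- function(pos) {
    d <- pos[topology[, 2], , drop = FALSE] - pos[topology[, 1], , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    en <- sum(0.5 * k * (r - r0)^2)
    coef <- k * (r - r0) / r
    fb <- coef * d                    # dE/dd rows
    f <- scatter_rows(fb, topology[, 1], nrow(pos)) -
      scatter_rows(fb, topology[, 2], nrow(pos))
    list(energy = en, forces = f)
  }
  sys <- atomic_system(z, positions)
  make_potential(sys, ef, label = "harmonic molecule")
}

#' Elastic-network harmonic molecule
#'
#' A compact blob of atoms with harmonic springs between all pairs closer
#' than `bond_cut`, rest lengths equal to the initial distances -- so the
#' starting geometry is an exact minimum with a full-rank vibrational
#' spectrum (3n - 6 positive modes). This is the workhorse fixture for
#' equipartition and spectral checks: every internal degree of freedom is
#' harmonically bound.
#'
#' @param n_atoms number of atoms.
#' @param k spring constant, eV/A^2.
#' @param spacing typical nearest-neighbor distance, Angstrom.
#' @param bond_cut bonding cutoff, Angstrom (default `1.7 * spacing`).
#' @param z atomic number (default carbon).
#' @param seed seed for the blob geometry.
#' @export
elastic_network_molecule <- function(n_atoms = 16, k = 30, spacing = 1.5,
                                     bond_cut = NULL, z = 6L, seed = 1) {
  if (is.null(bond_cut)) bond_cut <- 1.7 * spacing
  set.seed(seed)
  # grow a compact cluster on a jittered cubic lattice
  side <- ceiling(n_atoms^(1/3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side))) * spacing
  ctr <- colMeans(grid)
  ord <- order(rowSums((grid - matrix(ctr, nrow(grid), 3, byrow = TRUE))^2))
  pos <- grid[ord[seq_len(n_atoms)], , drop = FALSE] +
    matrix(stats::runif(3 * n_atoms, -0.1, 0.1) * spacing, ncol = 3)
  pairs <- t(utils::combn(n_atoms, 2))
  d <- sqrt(rowSums((pos[pairs[, 1], , drop = FALSE] -
                       pos[pairs[, 2], , drop = FALSE])^2))
  keep <- d < bond_cut
  harmonic_molecule(pairs[keep, , drop = FALSE], k = k, r0 = d[keep],
                    z = rep(z, n_atoms), positions = pos)
}

#' Double-well diatomic potential
#'
#' A two-atom molecule whose bond energy
#' \eqn{V(r) = B ((r-c)^2 - w^2)^2 / w^4} has two minima at separations
#' \eqn{c - w} and \eqn{c + w} (both at V = 0) separated by a barrier of
#' height `barrier` at \eqn{r = c}: the smallest landscape on which
#' minima-hopping bookkeeping (two distinct minima, transition-state
#' estimate above the analytic barrier) can be verified exactly.
#'
#' @param r_short,r_long the two minimum separations, Angstrom.
#' @param barrier barrier height at the midpoint, eV.
#' @param z atomic number of the two atoms.
#' @export
double_well_molecule <- function(r_short = 1.0, r_long = 2.0, barrier = 0.5,
                                 z = 6L) {
  c0 <- (r_short + r_long) / 2
  w <- (r_long - r_short) / 2
  ef <- function(pos) {
    d <- pos[2, ] - pos[1, ]
    r <- sqrt(sum(d * d))
    q <- (r - c0)^2 - w^2
    en <- barrier * q^2 / w^4
    dEdr <- barrier * 4 * q * (r - c0) / w^4
    fvec <- dEdr * d / r
    list(energy = en, forces = rbind(fvec, -fvec))
  }
  sys <- atomic_system(c(z, z), rbind(c(0, 0, 0), c(r_short, 0, 0)))
  make_potential(sys, ef, label = "double-well diatomic")
}

#' Labeled dataset container
#'
#' @param systems list of [atomic_system] objects.
#' @param energies reference total energies.
#' @param forces list of n x 3 reference force matrices.
#' @param units `"eV"` or `"kcal/mol"` (energies per structure, forces per
#'   Angstrom).
#' @export
labeled_dataset <- function(systems, energies, forces, units = c("eV", "kcal/mol")) {
  units <- match.arg(units)
  stopifnot(length(systems) == length(energies),
            length(systems) == length(forces))
  for (s in seq_along(systems)) {
    if (!all(dim(forces[[s]]) == dim(systems[[s]]$positions)))
      stop("forces of structure ", s, " are not n x 3")
  }
  structure(list(systems = systems, energies = as.numeric(energies),
                 forces = forces, units = units),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$systems), " structures, units ",
      x$units, "\n", sep = "")
  invisible(x)
}

#' Convert dataset units
#' @param dataset a [labeled_dataset].
#' @param units target units.
#' @export
convert_units <- function(dataset, units = c("eV", "kcal/mol")) {
  units <- match.arg(units)
  if (units == dataset$units) return(dataset)
  fac <- if (units == "kcal/mol") 23.0609 else 1 / 23.0609
  dataset$energies <- dataset$energies * fac
  dataset$forces <- lapply(dataset$forces, function(f) f * fac)
  dataset$units <- units
  dataset
}

#' Synthetic Lennard-Jones cluster dataset
#'
#' Generates labeled configurations by sampling a Langevin trajectory of the
#' analytic cluster potential at `T_sample` (after a relaxation +
#' equilibration stage) and labeling every stored frame with the analytic
#' energies and forces. This mimics how thermally sampled reference datasets
#' for force-field learning are produced, with the toy potential playing the
#' role of the reference method.
#'
#' @param n_atoms cluster size (>= 2).
#' @param n_samples number of labeled frames.
#' @param T_sample sampling temperature, K. The default 30 K keeps an
#'   argon-parameter cluster in the anharmonic-vibration regime without
#'   evaporating atoms.
#' @param seed RNG seed; the dataset is bit-reproducible per seed.
#' @param potential optionally a pre-built cluster potential (defaults to
#'   [lj_potential] with argon parameters).
#' @param stride MD steps between stored frames.
#' @param dt Langevin time step, fs.
#' @return a [labeled_dataset] with attribute `potential`.
#' @export
lj_cluster_dataset <- function(n_atoms = 7, n_samples = 100, T_sample = 30,
                               seed = 1, potential = NULL, stride = 25,
                               dt = 5) {
  if (n_atoms < 2) stop("n_atoms must be >= 2")
  pot <- if (is.null(potential)) lj_potential(n_atoms) else potential
  start <- relax(pot$system, pot, f_max = 1e-3)$system
  equil <- 400L
  steps <- equil + stride * n_samples
  traj <- run_md(start, pot, integrator = "langevin", dt = dt, steps = steps,
                 stride = 1, seed = seed, T_target = T_sample, gamma = 0.02)
  idx <- equil + stride * seq_len(n_samples) + 1L  # +1: frame 1 is t = 0
  systems <- vector("list", n_samples)
  energies <- numeric(n_samples)
  flist <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    pos <- traj$frames[[idx[s]]]$positions
    sys <- start; sys$positions <- pos
    lab <- pot$ef(pos)
    systems[[s]] <- sys
    energies[s] <- lab$energy
    flist[[s]] <- lab$forces
  }
  out <- labeled_dataset(systems, energies, flist, units = "eV")
  attr(out, "potential") <- pot
  out
}

#' Random perturbations of a minimum geometry
#'
#' @param minimum an [atomic_system] (typically a relaxed minimum).
#' @param amplitude maximal per-coordinate displacement, Angstrom.
#' @param n number of perturbed copies.
#' @param seed RNG seed.
#' @return list of [atomic_system] objects.
#' @export
perturbed_geometries <- function(minimum, amplitude, n, seed = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  set.seed(seed)
  lapply(seq_len(n), function(s) {
    sys <- minimum
    sys$positions <- sys$positions +
      matrix(stats::runif(length(sys$positions), -amplitude, amplitude), ncol = 3)
    sys
  })
}
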