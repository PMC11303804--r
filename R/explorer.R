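# Potential-energy-surface exploration by minima hopping: MD escape trials,
# quasi-Newton relaxation, rotation-minimized RMSD identity of minima,
# adaptive temperature / acceptance window, transition-state estimates and
# disconnectivity graphs.

#' Relax a structure to a local minimum
#'
#' L-BFGS minimization of the potential energy until the maximal per-atom
#' force norm drops below `f_max` (default 1e-4 eV/A). The optimizer is
#' restarted in chunks until the force criterion -- which is stricter than
#' the optimizer's own stopping rules -- is met.
#'
#' @param system starting [atomic_system].
#' @param potential an `ff_potential`.
#' @param f_max force-norm convergence threshold, eV/A.
#' @param max_steps total optimizer-iteration budget.
#' @return object of class `pes_minimum`: list with `system` (relaxed),
#'   `energy`, `f_max_final`, `iterations`.
#' @export
relax <- function(system, potential, f_max = 1e-4, max_steps = 5000) {
  if (!all(is.finite(system$positions))) stop("non-finite starting geometry")
  n <- nrow(system$positions)
  x0 <- as.vector(system$positions)
  fn <- function(x) potential$ef(matrix(x, n, 3))$energy
  gr <- function(x) -as.vector(potential$ef(matrix(x, n, 3))$forces)
  max_force_norm <- function(x) {
    f <- potential$ef(matrix(x, n, 3))$forces
    sqrt(max(rowSums(f^2)))
  }
  used <- 0L
  x <- x0
  repeat {
    if (max_force_norm(x) < f_max) break
    if (used >= max_steps)
      stop("relaxation did not converge within ", max_steps,
           " iterations (max |F| = ", format(max_force_norm(x)), " eV/A)")
    chunk <- min(200L, max_steps - used)
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = 10,
                                       pgtol = f_max / 50))
    used <- used + chunk
    if (max(abs(res$par - x)) == 0 && max_force_norm(res$par) >= f_max) {
      # optimizer stalled; tiny seeded jiggle to leave a flat spot
      res$par <- res$par + stats::rnorm(length(x), sd = 1e-6)
    }
    x <- res$par
  }
  sys <- system
  sys$positions <- matrix(x, n, 3)
  structure(list(system = sys, energy = potential$ef(sys$positions)$energy,
                 f_max_final = max_force_norm(x), iterations = used),
            class = "pes_minimum")
}

#' Rotation-minimized RMSD between two structures
#'
#' Removes the centers of mass of both structures, then minimizes the
#' root-mean-square deviation over proper rotations (Kabsch algorithm with
#' the determinant +1 constraint). Atom order is fixed: no permutation
#' search, so identical-atom permutants count as different structures.
#'
#' @param A,B [atomic_system] objects with identical atomic-number
#'   sequences.
#' @return minimal RMSD, Angstrom.
#' @export
rmsd_so3 <- function(A, B) {
  if (!identical(A$atomic_numbers, B$atomic_numbers))
    stop("structures differ in composition or atom order")
  center <- function(s) {
    w <- s$masses / sum(s$masses)
    sweep(s$positions, 2, colSums(w * s$positions))
  }
  P <- center(A); Q <- center(B)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  dif <- Q - P %*% t(R)
  sqrt(sum(dif^2) / nrow(P))
}

#' MD escape trial from a minimum
#'
#' Draws Maxwell-Boltzmann velocities rescaled exactly to `T`, runs NVE
#' velocity Verlet for `escape_fs` and returns the final geometry together
#' with the maximum potential energy visited along the path (the
#' transition-state estimate between the two endpoint minima).
#'
#' @param minimum a `pes_minimum` (or relaxed [atomic_system]).
#' @param potential an `ff_potential`.
#' @param T escape temperature, K.
#' @param escape_fs MD length, fs.
#' @param dt time step, fs.
#' @param seed RNG seed.
#' @return list with `system` (final geometry), `e_max` (max potential
#'   energy along the path, eV).
#' @export
escape <- function(minimum, potential, T, escape_fs = 1000, dt = 0.5,
                   seed = 1) {
  sys <- if (inherits(minimum, "pes_minimum")) minimum$system else minimum
  steps <- round(escape_fs / dt)
  v0 <- init_velocities(sys, T, mode = "rescale_exact", seed = seed)
  traj <- run_md(sys, potential, integrator = "verlet", dt = dt,
                 steps = steps, stride = 1, seed = seed, T_target = 0,
                 velocities = v0)
  if (!is.na(traj$failed_step))
    stop("escape MD became unstable at step ", traj$failed_step)
  out <- sys
  out$positions <- traj$frames[[length(traj$frames)]]$positions
  list(system = out, e_max = max(traj$epot))
}

#' Minima hopping exploration
#'
#' Alternates MD escape trials with relaxations, merging minima that agree
#' to within `rmsd_threshold` under the rotation-minimized RMSD, accepting
#' downhill-enough moves (`E_new - E_current < E_diff`) and adapting the
#' escape temperature and acceptance window to the visit history: the
#' temperature is raised by `adapt` when an escape falls back into a known
#' minimum and lowered when it finds a new one; `E_diff` is widened on
#' rejection and narrowed on acceptance.
#'
#' @param start starting [atomic_system].
#' @param potential an `ff_potential`.
#' @param T0 initial escape temperature, K.
#' @param E_diff initial acceptance window, eV.
#' @param adapt adaptation factor (> 1).
#' @param rmsd_threshold identity threshold, Angstrom.
#' @param max_minima stop once this many distinct minima are known.
#' @param max_trials hard cap on escape trials.
#' @param escape_fs,dt escape-MD parameters (fs).
#' @param f_max relaxation threshold, eV/A.
#' @param seed RNG seed; every escape draws from a distinct stream.
#' @return object of class `minima_history`: list with `minima` (list of
#'   `pes_minimum`), `energies`, `visits`, `discovered` (trial index),
#'   `transitions` (data frame a, b, e_ts), `trials`, `T_final`,
#'   `E_diff_final`.
#' @export
minima_hop <- function(start, potential, T0 = 1000, E_diff = 2,
                       adapt = 1.05, rmsd_threshold = 0.1, max_minima = 10,
                       max_trials = 200, escape_fs = 1000, dt = 0.5,
                       f_max = 1e-4, seed = 1) {
  cur <- relax(start, potential, f_max = f_max)
  minima <- list(cur)
  energies <- cur$energy
  visits <- 1L
  discovered <- 0L
  trans <- list()
  T_cur <- T0
  E_cur <- E_diff
  cur_id <- 1L
  trial <- 0L
  while (length(minima) < max_minima && trial < max_trials) {
    trial <- trial + 1L
    esc <- escape(minima[[cur_id]], potential, T_cur, escape_fs = escape_fs,
                  dt = dt, seed = seed * 100000L + trial)
    cand <- relax(esc$system, potential, f_max = f_max)
    # identity against current minimum and full history
    match_id <- NA_integer_
    for (k in seq_along(minima)) {
      if (abs(cand$energy - energies[k]) < 1 &&
          rmsd_so3(cand$system, minima[[k]]$system) <= rmsd_threshold) {
        match_id <- k; break
      }
    }
    if (is.na(match_id)) {
      # genuinely new minimum
      minima[[length(minima) + 1]] <- cand
      energies <- c(energies, cand$energy)
      visits <- c(visits, 1L)
      discovered <- c(discovered, trial)
      new_id <- length(minima)
      T_cur <- T_cur / adapt
    } else {
      new_id <- match_id
      visits[match_id] <- visits[match_id] + 1L
      T_cur <- T_cur * adapt
    }
    if (new_id != cur_id) {
      trans[[length(trans) + 1]] <- data.frame(a = cur_id, b = new_id,
                                               e_ts = esc$e_max)
    }
    accepted <- (cand$energy - energies[cur_id]) < E_cur
    E_cur <- if (accepted) E_cur / adapt else E_cur * adapt
    if (accepted) cur_id <- new_id
  }
  transitions <- if (length(trans)) do.call(rbind, trans)
                 else data.frame(a = integer(0), b = integer(0),
                                 e_ts = numeric(0))
  structure(list(minima = minima, energies = energies, visits = visits,
                 discovered = discovered, transitions = transitions,
                 trials = trial, T_final = T_cur, E_diff_final = E_cur,
                 rmsd_threshold = rmsd_threshold),
            class = "minima_history")
}

#' @export
print.minima_history <- function(x, ...) {
  cat("<minima_history> ", length(x$minima), " distinct minima in ",
      x$trials, " escape trials; energies: ",
      paste(signif(sort(x$energies), 6), collapse = ", "), " eV\n", sep = "")
  invisible(x)
}

# pairwise best (lowest) transition-state estimates from recorded crossings
.best_transitions <- function(transitions) {
  if (!nrow(transitions)) return(transitions)
  key <- paste(pmin(transitions$a, transitions$b),
               pmax(transitions$a, transitions$b))
  best <- tapply(transitions$e_ts, key, min)
  ab <- do.call(rbind, strsplit(names(best), " "))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             e_ts = as.numeric(best))
}

#' Disconnectivity graph over explored minima
#'
#' Union-find merging of minima below successive energy levels: two minima
#' join at the lowest level above the best transition-state estimate
#' recorded between their basins. Disconnected components (no recorded
#' crossing) remain separate trees and are reported, not an error.
#'
#' @param history a `minima_history`.
#' @param level_spacing energy grid spacing, eV.
#' @return object of class `disconnectivity_graph`: list with `levels`,
#'   `merges` (data frame level, a, b), `components` (final partition),
#'   `minima_energies`.
#' @export
disconnectivity <- function(history, level_spacing = 0.1) {
  nmin <- length(history$minima)
  tr <- .best_transitions(history$transitions)
  # every merge energy must sit at or above both endpoint minima
  if (nrow(tr)) {
    lo <- pmax(history$energies[tr$a], history$energies[tr$b])
    tr$e_ts <- pmax(tr$e_ts, lo)
  }
  e_min <- min(history$energies)
  e_top <- if (nrow(tr)) max(tr$e_ts) else e_min
  levels <- seq(e_min, e_top + level_spacing, by = level_spacing)
  parent <- seq_len(nmin)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merges <- list()
  for (lev in levels) {
    open <- which(tr$e_ts <= lev)
    for (q in open) {
      ra <- find(tr$a[q]); rb <- find(tr$b[q])
      if (ra != rb) {
        parent[max(ra, rb)] <- min(ra, rb)
        merges[[length(merges) + 1]] <- data.frame(level = lev, a = tr$a[q],
                                                   b = tr$b[q])
      }
    }
  }
  comp <- vapply(seq_len(nmin), find, integer(1))
  structure(list(levels = levels,
                 merges = if (length(merges)) do.call(rbind, merges)
                          else data.frame(level = numeric(0), a = integer(0),
                                          b = integer(0)),
                 components = comp,
                 minima_energies = history$energies),
            class = "disconnectivity_graph")
}

#' Serialize a disconnectivity graph as indented text
#' @param graph a `disconnectivity_graph`.
#' @param path output file (or `""` for stdout).
#' @export
write_disconnectivity <- function(graph, path = "") {
  lines <- c(sprintf("disconnectivity graph: %d minima, %d merges",
                     length(graph$minima_energies), nrow(graph$merges)))
  for (k in seq_len(nrow(graph$merges))) {
    m <- graph$merges[k, ]
    lines <- c(lines, sprintf("  level %.6f eV: merge %d <- %d",
                              m$level, m$a, m$b))
  }
  for (i in seq_along(graph$minima_energies)) {
    lines <- c(lines, sprintf("    minimum %d: E = %.6f eV (component %d)",
                              i, graph$minima_energies[i],
                              graph$components[i]))
  }
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(path)
}
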