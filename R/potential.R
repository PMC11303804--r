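# Potential abstraction: anything that maps positions of a fixed atomic
# composition to an energy (eV) and forces (eV/A). Toy potentials and the
# learned network model share this interface, so the MD engine, the
# relaxation code and the observables are agnostic to where forces come
# from.

#' Create a potential from an energy/force evaluator
#'
#' @param system template [atomic_system] fixing composition (and cell).
#' @param ef function(positions) returning `list(energy =, forces =)` for an
#'   n x 3 positions matrix.
#' @param label short description.
#' @param check_forces if TRUE (default), verify at construction that the
#'   forces equal the negative finite-difference gradient of the energy at a
#'   slightly perturbed template geometry (relative tolerance 1e-6).
#' @return object of class `ff_potential`.
#' @export
make_potential <- function(system, ef, label = "potential",
                           check_forces = TRUE) {
  stopifnot(inherits(system, "atomic_system"), is.function(ef))
  pot <- structure(list(system = system, ef = ef, label = label),
                   class = "ff_potential")
  if (check_forces) {
    set.seed(12345)
    pos <- system$positions + matrix(stats::runif(length(system$positions),
                                                  -0.02, 0.02), ncol = 3)
    err <- .force_fd_error(pot, pos, h = 1e-5)
    if (err > 1e-6)
      stop("potential '", label, "' fails the finite-difference force check",
           " (relative error ", format(err), ")")
  }
  pot
}

#' @export
print.ff_potential <- function(x, ...) {
  cat("<ff_potential> ", x$label, " (", length(x$system$atomic_numbers),
      " atoms)\n", sep = "")
  invisible(x)
}

# max relative deviation between analytic forces and central differences
.force_fd_error <- function(pot, pos, h = 1e-4) {
  ref <- pot$ef(pos)
  fd <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    fd[i, k] <- -(pot$ef(pp)$energy - pot$ef(pm)$energy) / (2 * h)
  }
  scale <- max(abs(ref$forces), 1e-10)
  max(abs(fd - ref$forces)) / scale
}

#' Wrap a trained (or random-weight) network model as a potential
#'
#' The neighbor list is rebuilt at every evaluation, so the potential remains
#' valid as atoms cross the cutoff sphere during dynamics.
#'
#' @param model an [mlff_model].
#' @param system template [atomic_system].
#' @export
model_potential <- function(model, system) {
  force(model); force(system)
  make_potential(system, function(positions) {
    s <- system
    s$positions <- positions
    forces(s, model)
  }, label = "network model", check_forces = FALSE)
}
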