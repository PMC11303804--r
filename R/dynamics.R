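# Molecular dynamics: velocity initialization, integrators (velocity
# Verlet, Langevin BAOAB, single Nose-Hoover), temperature bookkeeping and
# the trajectory driver. Units: Angstrom, fs, eV, amu, Kelvin.

# kinetic energy in eV from velocities (A/fs) and masses (amu)
kinetic_energy <- function(velocities, masses) {
  0.5 * sum(masses * rowSums(velocities^2)) / ff_constants$accel_unit
}

.n_dof <- function(n, periodic) {
  if (periodic) 3 * n else 3 * n - 3
}

#' Instantaneous temperature of an MD state
#'
#' \eqn{T = 2 KE / (N_{dof} k_B)} with \eqn{N_{dof} = 3N - 3} for isolated
#' systems (center-of-mass motion removed at initialization) and \eqn{3N}
#' for periodic ones.
#'
#' @param state an `md_state` (or any list with `velocities`, `masses`,
#'   optionally `periodic`).
#' @export
temperature <- function(state) {
  n <- nrow(state$velocities)
  periodic <- isTRUE(state$periodic)
  if (n == 1 && !periodic)
    stop("temperature is undefined for a single isolated atom (0 internal ",
         "degrees of freedom)")
  ke <- kinetic_energy(state$velocities, state$masses)
  2 * ke / (.n_dof(n, periodic) * ff_constants$k_B)
}

#' Initialize Maxwell-Boltzmann velocities
#'
#' Draws velocities from the Maxwell-Boltzmann distribution and removes the
#' center-of-mass momentum. Two modes:
#' \describe{
#'   \item{boltzmann_2T}{draw at twice the target temperature -- the usual
#'     start for NVE runs from a relaxed structure, where equipartition
#'     redistributes half of the kinetic energy into potential energy;}
#'   \item{rescale_exact}{draw at the target temperature and rescale so the
#'     instantaneous temperature matches it exactly.}
#' }
#'
#' @param system an [atomic_system].
#' @param T_target target temperature, K.
#' @param mode see above.
#' @param seed RNG seed.
#' @return n x 3 velocity matrix, A/fs.
#' @export
init_velocities <- function(system, T_target,
                            mode = c("boltzmann_2T", "rescale_exact"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (T_target < 0) stop("T_target must be >= 0")
  n <- length(system$masses)
  if (T_target == 0) return(matrix(0, n, 3))
  set.seed(seed)
  T_draw <- if (mode == "boltzmann_2T") 2 * T_target else T_target
  sd_v <- sqrt(ff_constants$k_B * T_draw * ff_constants$accel_unit /
                 system$masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  # remove center-of-mass momentum
  p_com <- colSums(system$masses * v) / sum(system$masses)
  v <- v - matrix(p_com, n, 3, byrow = TRUE)
  if (mode == "rescale_exact" && n > 1) {
    st <- list(velocities = v, masses = system$masses,
               periodic = any(system$pbc))
    v <- v * sqrt(T_target / temperature(st))
  }
  v
}

.md_state <- function(system, velocities, pot_eval, time = 0) {
  structure(list(positions = system$positions, velocities = velocities,
                 masses = system$masses, time = time,
                 epot = pot_eval$energy, forces = pot_eval$forces,
                 periodic = any(system$pbc)),
            class = "md_state")
}

.accel <- function(state) {
  ff_constants$accel_unit * state$forces / state$masses
}

.check_finite_state <- function(state, step) {
  if (!all(is.finite(state$positions)) || !all(is.finite(state$velocities)) ||
      !all(is.finite(state$forces)))
    stop("MD integration became non-finite at step ", step)
  invisible(state)
}

#' One velocity-Verlet step
#'
#' Standard symplectic update; exactly one new force evaluation per step
#' (forces are carried in the state and reused).
#'
#' @param state an `md_state`.
#' @param potential an `ff_potential`.
#' @param dt time step, fs.
#' @export
verlet_step <- function(state, potential, dt) {
  if (dt <= 0) stop("dt must be positive")
  a <- .accel(state)
  v_half <- state$velocities + 0.5 * dt * a
  state$positions <- state$positions + dt * v_half
  new <- potential$ef(state$positions)
  state$epot <- new$energy
  state$forces <- new$forces
  state$velocities <- v_half + 0.5 * dt * .accel(state)
  state$time <- state$time + dt
  state
}

#' One Langevin (BAOAB) step
#'
#' Stochastic thermostat targeting temperature `T`, friction `gamma` (1/fs).
#' With `gamma = 0` the update reduces exactly to [verlet_step].
#'
#' @param state an `md_state`.
#' @param potential an `ff_potential`.
#' @param dt time step, fs.
#' @param T target temperature, K.
#' @param gamma friction coefficient, 1/fs.
#' @export
langevin_step <- function(state, potential, dt, T, gamma) {
  if (gamma < 0) stop("gamma must be >= 0")
  v <- state$velocities + 0.5 * dt * .accel(state)          # B
  state$positions <- state$positions + 0.5 * dt * v          # A
  if (gamma > 0) {                                           # O
    c1 <- exp(-gamma * dt)
    sd_v <- sqrt(ff_constants$k_B * T * ff_constants$accel_unit / state$masses)
    xi <- matrix(stats::rnorm(length(v)), nrow(v), 3)
    v <- c1 * v + sqrt(1 - c1^2) * sd_v * xi
  }
  state$positions <- state$positions + 0.5 * dt * v          # A
  new <- potential$ef(state$positions)
  state$epot <- new$energy
  state$forces <- new$forces
  state$velocities <- v + 0.5 * dt * .accel(state)           # B
  state$time <- state$time + dt
  state
}

#' One Nose-Hoover step (single thermostat)
#'
#' Deterministic thermostat in relaxation-time form,
#' \eqn{\dot\xi = (T_{inst}/T_0 - 1)/\tau^2}, integrated with a
#' semi-implicit velocity-Verlet splitting. The thermostat variable `xi` and
#' its integral `s_int` live on the state; the conserved extended energy is
#' \eqn{E + KE + \frac{1}{2} N_{dof} k_B T_0 \tau^2 \xi^2 +
#' N_{dof} k_B T_0 \int \xi dt}. As `tau` grows, the trajectory approaches
#' the NVE one.
#'
#' @param state an `md_state` (fields `xi`, `s_int` are created on first use).
#' @param potential an `ff_potential`.
#' @param dt time step, fs.
#' @param T target temperature, K.
#' @param tau coupling time, fs.
#' @export
nose_hoover_step <- function(state, potential, dt, T, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (is.null(state$xi)) { state$xi <- 0; state$s_int <- 0 }
  G <- function(v) {
    Tin <- temperature(list(velocities = v, masses = state$masses,
                            periodic = state$periodic))
    (Tin / T - 1) / tau^2
  }
  # time-reversible splitting: thermostat half-updates sandwich a velocity
  # Verlet core, velocities scaled by exp(-xi dt/2) on each side
  state$xi <- state$xi + 0.5 * dt * G(state$velocities)
  state$s_int <- state$s_int + 0.5 * dt * state$xi
  v <- state$velocities * exp(-state$xi * dt / 2)
  v <- v + 0.5 * dt * .accel(state)
  state$positions <- state$positions + dt * v
  new <- potential$ef(state$positions)
  state$epot <- new$energy
  state$forces <- new$forces
  v <- v + 0.5 * dt * .accel(state)
  v <- v * exp(-state$xi * dt / 2)
  state$s_int <- state$s_int + 0.5 * dt * state$xi
  state$xi <- state$xi + 0.5 * dt * G(v)
  state$velocities <- v
  state$time <- state$time + dt
  state
}

# conserved quantity of the Nose-Hoover dynamics (for drift diagnostics)
nose_hoover_energy <- function(state, T, tau) {
  ndof <- .n_dof(nrow(state$velocities), state$periodic)
  state$epot + kinetic_energy(state$velocities, state$masses) +
    0.5 * ndof * ff_constants$k_B * T * tau^2 * state$xi^2 +
    ndof * ff_constants$k_B * T * state$s_int
}

#' Run a molecular-dynamics trajectory
#'
#' Drives one of the integrators for a fixed number of steps, sampling
#' frames (positions, velocities, energies, temperature) at a stride.
#' Deterministic given the seed. If the integration becomes non-finite the
#' run terminates early and the returned trajectory records the failing
#' step (`failed_step`) for the stability diagnostics.
#'
#' @param system starting [atomic_system].
#' @param potential an `ff_potential`.
#' @param integrator one of `"verlet"`, `"langevin"`, `"nose_hoover"`.
#' @param dt time step, fs.
#' @param steps number of MD steps.
#' @param stride frames are stored every `stride` steps (plus the initial
#'   frame), giving `floor(steps/stride) + 1` frames.
#' @param seed RNG seed (velocity draw and Langevin noise).
#' @param T_target thermostat / velocity-initialization temperature, K.
#' @param gamma Langevin friction, 1/fs.
#' @param tau Nose-Hoover coupling time, fs (default `100 * dt`).
#' @param velocities optional initial velocities; drawn with
#'   [init_velocities] (`boltzmann_2T` for NVE, `rescale_exact` otherwise)
#'   when absent.
#' @return object of class `md_trajectory`.
#' @export
run_md <- function(system, potential, integrator = c("verlet", "langevin",
                                                     "nose_hoover"),
                   dt = 0.5, steps = 1000, stride = 10, seed = 1,
                   T_target = 300, gamma = 1e-3, tau = NULL,
                   velocities = NULL) {
  integrator <- match.arg(integrator)
  if (is.null(tau)) tau <- 100 * dt
  if (is.null(velocities)) {
    mode <- if (integrator == "verlet") "boltzmann_2T" else "rescale_exact"
    velocities <- if (T_target > 0) init_velocities(system, T_target, mode, seed)
                  else matrix(0, nrow(system$positions), 3)
  }
  set.seed(seed + 1L)  # stream for the thermostat noise
  state <- .md_state(system, velocities, potential$ef(system$positions))
  frames <- vector("list", steps %/% stride + 1L)
  frames[[1]] <- state[c("positions", "velocities", "time", "epot")]
  nf <- 1L
  failed_step <- NA_integer_
  for (s in seq_len(steps)) {
    ok <- tryCatch({
      state <- switch(integrator,
        verlet = verlet_step(state, potential, dt),
        langevin = langevin_step(state, potential, dt, T_target, gamma),
        nose_hoover = nose_hoover_step(state, potential, dt, T_target, tau))
      .check_finite_state(state, s)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) { failed_step <- s; break }
    if (s %% stride == 0) {
      nf <- nf + 1L
      frames[[nf]] <- state[c("positions", "velocities", "time", "epot")]
    }
  }
  frames <- frames[seq_len(nf)]
  epot <- vapply(frames, function(fr) fr$epot, numeric(1))
  ekin <- vapply(frames, function(fr)
    kinetic_energy(fr$velocities, system$masses), numeric(1))
  temp <- 2 * ekin / (.n_dof(nrow(system$positions), any(system$pbc)) *
                        ff_constants$k_B)
  structure(list(frames = frames, dt = dt, stride = stride, steps = steps,
                 seed = seed, integrator = integrator, T_target = T_target,
                 system = system, epot = epot, ekin = ekin,
                 temperature = temp, failed_step = failed_step,
                 final_state = state),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", x$integrator, ", ", length(x$frames), " frames (dt=",
      x$dt, " fs, stride ", x$stride, ")",
      if (!is.na(x$failed_step)) paste0(" [terminated at step ", x$failed_step, "]"),
      "\n", sep = "")
  invisible(x)
}
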