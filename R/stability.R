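# MD stability diagnostics: failure mode A (non-physical dissociation,
# detected as a strong temperature spike or a non-finite state) and failure
# mode B (a bond length leaving its reasonable distribution), summarized by
# the stability coefficient c_s = n_s / n_tot.

#' Detect covalent bonds of a structure
#'
#' Pairs whose initial distance is below `factor` times the sum of bundled
#' covalent radii are designated bonds; the observed initial distance is the
#' per-bond reference (equilibrium) length.
#'
#' @param system an [atomic_system].
#' @param factor multiplier on the covalent-radii sum (default 1.25).
#' @return object of class `bond_set`: data frame with `i`, `j`, `ref_length`.
#' @export
detect_bonds <- function(system, factor = 1.25) {
  n <- nrow(system$positions)
  radii <- covalent_radius_of(system$atomic_numbers)
  out <- NULL
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    d <- sqrt(rowSums((system$positions[pairs[1, ], , drop = FALSE] -
                         system$positions[pairs[2, ], , drop = FALSE])^2))
    cut <- factor * (radii[pairs[1, ]] + radii[pairs[2, ]])
    keep <- d < cut
    out <- data.frame(i = pairs[1, keep], j = pairs[2, keep],
                      ref_length = d[keep])
  } else {
    out <- data.frame(i = integer(0), j = integer(0), ref_length = numeric(0))
  }
  class(out) <- c("bond_set", "data.frame")
  out
}

#' Stability coefficient
#'
#' \eqn{c_s = n_s / n_{tot}}: the fraction of the planned MD steps completed
#' before the first instability; \eqn{n_s = n_{tot}} (so \eqn{c_s = 1}) when
#' no instability is observed.
#'
#' @param n_s steps until the first instability.
#' @param n_tot total planned steps (> 0).
#' @export
stability_coefficient <- function(n_s, n_tot) {
  if (n_tot <= 0) stop("n_tot must be positive")
  if (n_s < 0 || n_s > n_tot) stop("n_s must lie in [0, n_tot]")
  n_s / n_tot
}

#' Check the stability of an MD trajectory
#'
#' Scans the frames for the two failure modes: (A) an instantaneous
#' temperature exceeding `spike_factor` times the target temperature (or a
#' non-finite / early-terminated state) -- the signature of a non-physical
#' "explosion"; (B) any designated bond deviating by more than `bond_tol`
#' (default 50%) from its reference length. The earliest failing frame
#' determines `n_s`; a denser frame stride can only move the detection to
#' the same or an earlier physical time.
#'
#' @param traj an `md_trajectory` with velocities in its frames.
#' @param bonds a `bond_set` from [detect_bonds].
#' @param T_target target temperature, K.
#' @param spike_factor temperature-spike multiplier for criterion A.
#' @param bond_tol maximal relative bond-length deviation for criterion B.
#' @return object of class `stability_report`: list with `c_s`, `n_s`,
#'   `n_tot`, `failure_mode` (`"none"`, `"A_dissociation"`, `"B_bond"`),
#'   `failing_step`, `failing_bond`.
#' @export
check_stability <- function(traj, bonds, T_target, spike_factor = 100,
                            bond_tol = 0.5) {
  if (!length(traj$frames)) stop("empty trajectory")
  n_tot <- traj$steps
  fail_step <- NA_integer_
  mode <- "none"
  failing_bond <- NULL
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    step <- round(fr$time / traj$dt)
    bad_state <- !all(is.finite(fr$positions)) || !all(is.finite(fr$velocities))
    Tk <- traj$temperature[k]
    if (bad_state || !is.finite(Tk) || Tk > spike_factor * T_target) {
      fail_step <- step; mode <- "A_dissociation"; break
    }
    if (nrow(bonds)) {
      d <- sqrt(rowSums((fr$positions[bonds$j, , drop = FALSE] -
                           fr$positions[bonds$i, , drop = FALSE])^2))
      dev <- abs(d - bonds$ref_length) / bonds$ref_length
      if (any(dev > bond_tol)) {
        fail_step <- step
        mode <- "B_bond"
        b <- which.max(dev)
        failing_bond <- c(i = bonds$i[b], j = bonds$j[b])
        break
      }
    }
  }
  if (mode == "none" && !is.na(traj$failed_step)) {
    fail_step <- traj$failed_step
    mode <- "A_dissociation"
  }
  n_s <- if (mode == "none") n_tot else fail_step
  structure(list(c_s = stability_coefficient(n_s, n_tot), n_s = n_s,
                 n_tot = n_tot, failure_mode = mode,
                 failing_step = if (mode == "none") NA_integer_ else fail_step,
                 failing_bond = failing_bond),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> c_s = ", signif(x$c_s, 4), " (", x$failure_mode,
      ")\n", sep = "")
  invisible(x)
}

#' Write a stability report as JSON
#' @param report a `stability_report`.
#' @param path output file.
#' @export
write_stability_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
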