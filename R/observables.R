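# Physical observables computed from trajectories and potentials: radial
# distribution functions, velocity-autocorrelation power spectra, radius of
# gyration, end-to-end distances, torsions, harmonic normal modes and
# zero-point energy.

#' Radial distribution function
#'
#' For periodic systems: shell-normalized pair-distance histogram divided by
#' the ideal-gas expectation, so g(r) -> 1 for uncorrelated particles. For
#' isolated systems there is no bulk density to normalize against; the
#' function then returns the normalized pair-distance density (integrates
#' to 1 over the histogram range), which is the standard molecular analogue.
#'
#' @param traj an `md_trajectory` (or a list of [atomic_system] frames).
#' @param r_max histogram range, Angstrom; must not exceed the half-cell for
#'   periodic systems.
#' @param n_bins number of bins.
#' @param pairs optional 2-column matrix restricting the atom pairs.
#' @return data frame with bin centers `r` and `g`.
#' @export
rdf <- function(traj, r_max, n_bins = 100, pairs = NULL) {
  if (inherits(traj, "md_trajectory")) {
    system <- traj$system
    frames <- lapply(traj$frames, function(fr) fr$positions)
  } else {
    system <- traj[[1]]
    frames <- lapply(traj, function(s) s$positions)
  }
  n <- nrow(frames[[1]])
  periodic <- any(system$pbc)
  if (periodic && r_max > min(.cell_heights(system$cell)) / 2)
    stop("r_max exceeds half the minimal cell height")
  if (is.null(pairs)) {
    if (n < 2) stop("need at least two atoms")
    pairs <- t(utils::combn(n, 2))
  }
  if (!nrow(pairs)) stop("empty pair selection")
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  inv <- if (periodic) solve(system$cell)
  for (pos in frames) {
    d <- pos[pairs[, 2], , drop = FALSE] - pos[pairs[, 1], , drop = FALSE]
    if (periodic) {
      frac <- d %*% inv
      d <- d - round(frac) %*% system$cell
    }
    r <- sqrt(rowSums(d * d))
    h <- graphics::hist(r[r < r_max], breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dr <- diff(breaks)[1]
  if (periodic) {
    vol <- abs(det(system$cell))
    # ideal-gas pairs expected in each shell, per frame
    rho_pairs <- nrow(pairs) / vol
    ideal <- rho_pairs * 4 * pi * centers^2 * dr
    g <- counts / (length(frames) * ideal)
  } else {
    g <- counts / (sum(counts) * dr)   # probability density of pair distances
  }
  data.frame(r = centers, g = g)
}

#' Vibrational power spectrum from the velocity autocorrelation function
#'
#' Computes \eqn{C(t) = \langle v(0) \cdot v(t) \rangle} averaged over atoms
#' and time origins (FFT-based), applies a Hann window, zero-pads to the
#' next power of two and returns the one-sided Fourier intensity on a
#' wavenumber axis in 1/cm.
#'
#' @param traj an `md_trajectory` with uniformly sampled velocities.
#' @param mass_weighted weight each atom's VACF by its mass.
#' @return object of class `vib_spectrum`: data frame with `wavenumber`
#'   (1/cm) and `intensity`, plus attributes `dt_frame` (fs) and `n_pad`.
#' @export
vacf_spectrum <- function(traj, mass_weighted = FALSE) {
  nf <- length(traj$frames)
  if (nf < 2) stop("need at least two frames")
  n <- nrow(traj$frames[[1]]$velocities)
  dt_frame <- traj$dt * traj$stride
  # dof x time matrix
  V <- vapply(traj$frames, function(fr) as.vector(fr$velocities),
              numeric(3 * n))
  if (mass_weighted) {
    wts <- sqrt(rep(traj$system$masses, 3))
    V <- V * wts
  }
  # FFT-based autocorrelation, averaged over time origins and dofs
  npad2 <- 2^ceiling(log2(2 * nf))
  acf_sum <- numeric(nf)
  for (d in seq_len(nrow(V))) {
    v <- c(V[d, ], rep(0, npad2 - nf))
    fv <- stats::fft(v)
    ac <- Re(stats::fft(fv * Conj(fv), inverse = TRUE))[1:nf] / npad2
    acf_sum <- acf_sum + ac / (nf:1)     # unbiased origin average
  }
  C <- acf_sum / (3 * n)
  # Hann window + zero padding
  w <- 0.5 * (1 + cos(pi * (0:(nf - 1)) / (nf - 1)))
  Cw <- C * w
  n_pad <- 2^ceiling(log2(2 * nf))
  spec <- Mod(stats::fft(c(Cw, rep(0, n_pad - nf))))[1:(n_pad %/% 2)]
  freq <- (0:(n_pad %/% 2 - 1)) / (n_pad * dt_frame)     # cycles / fs
  out <- data.frame(wavenumber = freq / ff_constants$c_cm_fs,
                    intensity = spec)
  attr(out, "dt_frame") <- dt_frame
  attr(out, "n_pad") <- n_pad
  class(out) <- c("vib_spectrum", "data.frame")
  out
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from their center
#' of mass.
#' @param frame an [atomic_system] or md frame with `positions`; masses are
#'   taken from the frame if present, else from `masses`.
#' @param masses optional masses (amu).
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  pos <- frame$positions
  if (is.null(masses)) masses <- frame$masses
  if (is.null(masses)) stop("masses are required")
  com <- colSums(masses * pos) / sum(masses)
  dx <- pos - matrix(com, nrow(pos), 3, byrow = TRUE)
  sqrt(sum(masses * rowSums(dx^2)) / sum(masses))
}

#' End-to-end distance between two designated atoms
#' @param frame an object with `positions`.
#' @param i,j 1-based atom indices.
#' @export
end_to_end_distance <- function(frame, i, j) {
  pos <- frame$positions
  if (any(c(i, j) < 1) || any(c(i, j) > nrow(pos))) stop("index out of range")
  sqrt(sum((pos[j, ] - pos[i, ])^2))
}

#' Signed dihedral (torsion) angle
#'
#' IUPAC sign convention: looking down the b->c axis, the angle from the
#' a-b bond to the c-d bond, positive clockwise; cis = 0, trans = 180.
#'
#' @param frame an object with `positions`.
#' @param a,b,c,d four distinct 1-based atom indices.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(frame, a, b, c, d) {
  idx <- c(a, b, c, d)
  pos <- frame$positions
  if (length(unique(idx)) != 4) stop("indices must be distinct")
  if (any(idx < 1) || any(idx > nrow(pos))) stop("index out of range")
  b1 <- pos[b, ] - pos[a, ]
  b2 <- pos[c, ] - pos[b, ]
  b3 <- pos[d, ] - pos[c, ]
  cr <- function(p, q) c(p[2]*q[3] - p[3]*q[2], p[3]*q[1] - p[1]*q[3],
                         p[1]*q[2] - p[2]*q[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 * nb2 || sqrt(sum(n2^2)) < 1e-10 * nb2)
    stop("collinear atoms: torsion undefined")
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Harmonic normal modes and zero-point energy
#'
#' Builds the Hessian by central finite differences of the analytic forces,
#' mass-weights it, projects out the six rigid-body translations/rotations,
#' and diagonalizes. Frequencies are returned in 1/cm, the zero-point
#' energy as \eqn{\frac{1}{2}\hbar\sum\omega} over the vibrational modes.
#' Negative-curvature directions beyond tolerance are reported separately
#' as imaginary frequencies, flagging a non-minimum input.
#'
#' @param system a relaxed [atomic_system].
#' @param potential an `ff_potential`.
#' @param displacement finite-difference step, Angstrom.
#' @param tol_negative eigenvalue tolerance (relative to the largest) below
#'   which a negative direction flags a saddle.
#' @return object of class `normal_modes`: list with `frequencies` (1/cm,
#'   sorted), `imaginary_frequencies`, `modes` (mass-weighted eigenvectors),
#'   `zpe` (eV), `omega` (1/fs).
#' @export
normal_modes <- function(system, potential, displacement = 1e-3,
                         tol_negative = 1e-6) {
  pos <- system$positions
  n <- nrow(pos)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + displacement
    pm <- pos; pm[i, k] <- pm[i, k] - displacement
    dF <- (potential$ef(pp)$forces - potential$ef(pm)$forces) /
      (2 * displacement)
    H[, (i - 1) * 3 + k] <- -as.vector(t(dF))   # rows ordered x1,y1,z1,x2,...
  }
  H <- (H + t(H)) / 2
  m3 <- rep(system$masses, each = 3)
  Hm <- H / sqrt(outer(m3, m3))
  # rigid-body basis in mass-weighted coordinates
  com <- colSums(system$masses * pos) / sum(system$masses)
  dx <- pos - matrix(com, n, 3, byrow = TRUE)
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- sqrt(system$masses)
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(n), function(i) {
      v <- c(axes[k, 2] * dx[i, 3] - axes[k, 3] * dx[i, 2],
             axes[k, 3] * dx[i, 1] - axes[k, 1] * dx[i, 3],
             axes[k, 1] * dx[i, 2] - axes[k, 2] * dx[i, 1])
      v * sqrt(system$masses[i])
    }, numeric(3)))
    B[, 3 + k] <- as.vector(t(rot))
  }
  qrB <- qr(B)
  Bq <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
  P <- diag(3 * n) - Bq %*% t(Bq)
  Hp <- P %*% Hm %*% P
  eig <- eigen(Hp, symmetric = TRUE)
  lam <- eig$values
  scale <- max(abs(lam))
  # drop the projected rigid-body space (near-zero eigenvalues)
  n_rigid <- qrB$rank
  ord <- order(abs(lam))
  rigid_idx <- ord[seq_len(n_rigid)]
  keep <- setdiff(seq_along(lam), rigid_idx)
  lam_v <- lam[keep]
  vec_v <- eig$vectors[, keep, drop = FALSE]
  neg <- lam_v < -tol_negative * scale
  omega <- sqrt(pmax(lam_v[!neg], 0) * ff_constants$accel_unit)   # 1/fs
  ordv <- order(omega)
  omega <- omega[ordv]
  freq <- omega / (2 * pi * ff_constants$c_cm_fs)
  imag_freq <- sqrt(-lam_v[neg] * ff_constants$accel_unit) /
    (2 * pi * ff_constants$c_cm_fs)
  structure(list(frequencies = freq, omega = omega,
                 imaginary_frequencies = sort(imag_freq, decreasing = TRUE),
                 modes = vec_v[, ordv, drop = FALSE],
                 zpe = 0.5 * ff_constants$hbar * sum(omega),
                 is_minimum = !any(neg)),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes> ", length(x$frequencies), " vibrational modes, ZPE = ",
      signif(x$zpe, 6), " eV",
      if (!x$is_minimum) paste0(" [", length(x$imaginary_frequencies),
                                " imaginary]"),
      "\n", sep = "")
  invisible(x)
}

#' Temperature equivalent of a zero-point energy
#'
#' Distributes the ZPE over the \eqn{3n - 6} vibrational degrees of freedom
#' of a nonlinear molecule: \eqn{T = E_{ZPE} / ((3n-6) k_B)}.
#'
#' @param E_zpe zero-point energy, eV.
#' @param n_atoms number of atoms (>= 3; nonlinear assumed).
#' @export
zpe_temperature <- function(E_zpe, n_atoms) {
  if (n_atoms < 3) stop("n_atoms must be >= 3 (nonlinear molecule assumed)")
  E_zpe / ((3 * n_atoms - 6) * ff_constants$k_B)
}

#' Write a two-column table (spectrum or distribution) as plain text
#' @param x data frame with two columns.
#' @param path output file.
#' @export
write_table2 <- function(x, path) {
  utils::write.table(x, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
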