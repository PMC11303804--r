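# Physical constants and element tables. Internal unit system: Angstrom,
# femtosecond, electron-volt, atomic mass unit (amu), Kelvin.

#' Physical constants used throughout the package
#'
#' A named list with the constants of the internal unit system
#' (Angstrom / femtosecond / eV / amu / Kelvin):
#' \describe{
#'   \item{k_B}{Boltzmann constant, eV/K.}
#'   \item{hbar}{Reduced Planck constant, eV fs.}
#'   \item{accel_unit}{Conversion so that acceleration in Angstrom/fs^2 equals
#'     `accel_unit * force[eV/Angstrom] / mass[amu]` (value
#'     0.009648533212, 10 significant digits).}
#'   \item{c_cm_fs}{Speed of light in cm/fs (for wavenumber axes).}
#'   \item{ev_per_kcal_mol}{1 kcal/mol in eV; its inverse 23.0609 kcal/mol
#'     per eV is used for unit conversion of datasets.}
#' }
#' @export
ff_constants <- list(
  k_B          = 8.617333262e-5,
  hbar         = 0.6582119569,
  accel_unit   = 0.009648533212,
  c_cm_fs      = 2.99792458e-5,
  ev_per_kcal_mol = 1 / 23.0609
)

# Standard atomic weights (amu), indexed by atomic number. NA where the
# package has no bundled value; callers may override per system.
.atomic_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
  145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
  174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
  204.38, 207.2, 208.98, 209, 210, 222
)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

# Covalent radii in Angstrom (single-bond values, Cordero et al. compilation)
# for Z = 1..86; used by bond detection.
.covalent_radii <- c(
  0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
  1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
  1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22,
  1.22, 1.20, 1.19, 1.20, 1.20, 1.16, 2.20, 1.95, 1.90, 1.75,
  1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39,
  1.39, 1.38, 1.39, 1.40, 2.44, 2.15, 2.07, 2.04, 2.03, 2.01,
  1.99, 1.98, 1.98, 1.96, 1.94, 1.92, 1.92, 1.89, 1.90, 1.87,
  1.87, 1.75, 1.70, 1.62, 1.51, 1.44, 1.41, 1.36, 1.36, 1.32,
  1.45, 1.46, 1.48, 1.40, 1.50, 1.50
)

atomic_mass_of <- function(z) {
  m <- rep(NA_real_, length(z))
  ok <- z >= 1 & z <= length(.atomic_masses)
  m[ok] <- .atomic_masses[z[ok]]
  if (anyNA(m)) {
    stop("no bundled atomic mass for atomic number(s) ",
         paste(unique(z[is.na(m)]), collapse = ", "),
         "; supply masses explicitly")
  }
  m
}

covalent_radius_of <- function(z) {
  r <- rep(NA_real_, length(z))
  ok <- z >= 1 & z <= length(.covalent_radii)
  r[ok] <- .covalent_radii[z[ok]]
  if (anyNA(r)) {
    stop("no bundled covalent radius for atomic number(s) ",
         paste(unique(z[is.na(r)]), collapse = ", "))
  }
  r
}

element_symbol_of <- function(z) {
  s <- rep(NA_character_, length(z))
  ok <- z >= 1 & z <= length(.element_symbols)
  s[ok] <- .element_symbols[z[ok]]
  s[is.na(s)] <- paste0("Z", z[is.na(s)])
  s
}

atomic_number_of <- function(sym) {
  z <- match(sym, .element_symbols)
  # also accept plain atomic numbers written as text
  num <- suppressWarnings(as.integer(sym))
  z[is.na(z) & !is.na(num)] <- num[is.na(z) & !is.na(num)]
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  z
}
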