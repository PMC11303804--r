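# Atomic systems, neighbor lists and displacement geometry.

#' Create an atomic system
#'
#' The basic container consumed by every stage: atomic numbers, Cartesian
#' coordinates in Angstrom, an optional periodic cell, and per-atom masses
#' (amu) derived from a bundled standard-atomic-weight table unless
#' overridden.
#'
#' @param atomic_numbers positive integer vector, length n.
#' @param positions n x 3 numeric matrix, Angstrom.
#' @param cell optional 3 x 3 lattice matrix (rows are lattice vectors),
#'   Angstrom; required when any `pbc` flag is set.
#' @param pbc logical length-3 (or length-1, recycled) periodic flags.
#' @param masses optional amu vector overriding the bundled table.
#' @return object of class `atomic_system`.
#' @export
atomic_system <- function(atomic_numbers, positions, cell = NULL,
                          pbc = FALSE, masses = NULL) {
  z <- as.integer(atomic_numbers)
  if (length(z) < 1 || any(z < 1)) stop("atomic numbers must be positive integers")
  positions <- as.matrix(positions)
  if (is.vector(positions)) positions <- matrix(positions, ncol = 3)
  if (ncol(positions) != 3 || nrow(positions) != length(z))
    stop("positions must be an n x 3 matrix matching atomic_numbers")
  if (!all(is.finite(positions))) stop("positions must be finite")
  pbc <- rep_len(as.logical(pbc), 3)
  if (any(pbc) && is.null(cell))
    stop("a cell is required when any periodic flag is set")
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    if (any(dim(cell) != c(3, 3)) || !all(is.finite(cell)))
      stop("cell must be a finite 3 x 3 matrix")
  }
  if (is.null(masses)) masses <- atomic_mass_of(z)
  if (length(masses) != length(z) || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and match the atom count")
  structure(list(atomic_numbers = z, positions = unname(positions),
                 cell = cell, pbc = pbc, masses = as.numeric(masses)),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat("<atomic_system> ", length(x$atomic_numbers), " atoms (",
      paste(unique(element_symbol_of(x$atomic_numbers)), collapse = ", "),
      ")", if (any(x$pbc)) " periodic" else "", "\n", sep = "")
  invisible(x)
}

# heights of the cell (distance between opposite faces), used for the
# minimum-image validity check
.cell_heights <- function(cell) {
  v <- abs(det(cell))
  a <- cell[1, ]; b <- cell[2, ]; c <- cell[3, ]
  cr <- function(p, q) c(p[2]*q[3] - p[3]*q[2], p[3]*q[1] - p[1]*q[3],
                         p[1]*q[2] - p[2]*q[1])
  areas <- c(sqrt(sum(cr(b, c)^2)), sqrt(sum(cr(c, a)^2)), sqrt(sum(cr(a, b)^2)))
  v / areas
}

#' Build a neighbor list within a radial cutoff
#'
#' Exact cutoff-sphere neighborhoods as directed edges (each unordered pair
#' contributes both (i,j) and (j,i), as the message-passing update requires),
#' with minimum-image displacements for periodic systems. Edges are ordered
#' lexicographically by (i, j).
#'
#' @param system an [atomic_system].
#' @param r_cut cutoff radius, Angstrom. For periodic systems it must be
#'   smaller than half the minimal cell height, otherwise an error names the
#'   violated axis.
#' @return object of class `neighbor_list`: list with integer vectors `i`,
#'   `j`, displacement matrix `d` (rows \eqn{\vec r_{ij} = \vec r_j - \vec
#'   r_i}), distances `r` and unit vectors `u`.
#' @export
build_neighbors <- function(system, r_cut) {
  stopifnot(inherits(system, "atomic_system"))
  if (!is.finite(r_cut) || r_cut <= 0) stop("r_cut must be positive")
  pos <- system$positions
  n <- nrow(pos)
  periodic <- any(system$pbc)
  if (periodic) {
    h <- .cell_heights(system$cell)
    bad <- which(system$pbc & r_cut >= h / 2)
    if (length(bad))
      stop("r_cut = ", r_cut, " A violates the minimum-image convention on ",
           "cell axis ", paste(bad, collapse = ", "),
           " (half height ", paste(signif(h[bad] / 2, 6), collapse = ", "), " A)")
  }
  if (n == 1) {
    return(structure(list(i = integer(0), j = integer(0),
                          d = matrix(0, 0, 3), r = numeric(0),
                          u = matrix(0, 0, 3), n_atoms = n, r_cut = r_cut),
                     class = "neighbor_list"))
  }
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  d <- pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE]
  if (periodic) {
    # minimum image: wrap fractional displacements to [-1/2, 1/2)
    inv <- solve(system$cell)
    frac <- d %*% inv
    wrap <- round(frac)
    wrap[, !system$pbc] <- 0
    d <- d - wrap %*% system$cell
  }
  r <- sqrt(rowSums(d^2))
  keep <- r <= r_cut & r > 0
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep, , drop = FALSE]; r <- r[keep]
  ord <- order(ii, jj)
  ii <- ii[ord]; jj <- jj[ord]; d <- d[ord, , drop = FALSE]; r <- r[ord]
  # Cartesian periodic-image shifts so that d can be recomputed from new
  # positions with the same topology: d = pos[j,] - pos[i,] + shift_cart
  shift_cart <- d - (pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE])
  if (!periodic) shift_cart <- NULL
  structure(list(i = ii, j = jj, d = d, r = r, u = d / r,
                 shift_cart = shift_cart, n_atoms = n, r_cut = r_cut),
            class = "neighbor_list")
}

#' Mean directed-neighbor count over a dataset
#'
#' Dataset-global average \eqn{\langle N \rangle} = (total directed edges) /
#' (total atoms), the rescaling constant of the Euclidean-variable
#' initialization. Computed on the training set and stored in the model
#' configuration so inference reuses the same constant.
#'
#' @param systems a list of [atomic_system] objects (or a single one).
#' @param r_cut cutoff radius, Angstrom.
#' @export
mean_neighbor_count <- function(systems, r_cut) {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  if (length(systems) == 0) stop("empty dataset")
  edges <- 0; atoms <- 0
  for (s in systems) {
    nl <- build_neighbors(s, r_cut)
    edges <- edges + length(nl$i)
    atoms <- atoms + length(s$atomic_numbers)
  }
  edges / atoms
}
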