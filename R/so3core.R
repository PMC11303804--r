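# Real spherical harmonics, Clebsch-Gordan machinery, Wigner-D rotation
# matrices and the per-degree invariant contraction.
#
# Conventions (fixed for the whole package):
#  * real, orthonormal spherical harmonics over the unit sphere;
#  * component ordering is degree-major, order m = -l..l within a degree;
#  * the associated Legendre functions carry no Condon-Shortley phase (it is
#    kept in the complex harmonics used internally for the basis change).

# P_l^m(x) for scalar l, m >= 0; x may be a vector. No Condon-Shortley phase.
.assoc_legendre <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) { pmm <- pmm * fact * somx2; fact <- fact + 2 }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1; pmmp1 <- pll
  }
  pmmp1
}

.sh_norm <- function(l, m) {
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
}

#' Real orthonormal spherical harmonics
#'
#' Evaluates all real spherical harmonics \eqn{Y_{lm}} with \eqn{l \le l_{max}}
#' at a unit direction. Components are ordered degree-major with
#' \eqn{m = -l, \dots, l}; negative orders carry the \eqn{\sin(|m|\phi)}
#' dependence, positive orders the \eqn{\cos(m\phi)} dependence.
#'
#' @param u numeric length-3 unit vector (checked to 1e-8).
#' @param l_max maximal degree, integer \eqn{\ge 0}.
#' @return numeric vector of length \eqn{(l_{max}+1)^2} of class
#'   `spherical_tensor` with attribute `degrees = 0:l_max`.
#' @examples
#' real_sph_harm(c(0, 0, 1), 1)
#' @export
real_sph_harm <- function(u, l_max) {
  if (length(u) != 3 || !all(is.finite(u)))
    stop("invalid geometry: direction must be a finite length-3 vector")
  nu <- sqrt(sum(u^2))
  if (abs(nu - 1) > 1e-8)
    stop("invalid geometry: direction must be a unit vector (|u| = ",
         format(nu), ")")
  if (l_max < 0) stop("l_max must be >= 0")
  u <- u / nu
  z <- u[3]; phi <- atan2(u[2], u[1])
  out <- numeric((l_max + 1)^2)
  idx <- 1L
  for (l in 0:l_max) {
    for (m in (-l):l) {
      am <- abs(m)
      v <- .sh_norm(l, am) * .assoc_legendre(l, am, z)
      if (m > 0) v <- sqrt(2) * v * cos(m * phi)
      if (m < 0) v <- sqrt(2) * v * sin(am * phi)
      out[idx] <- v
      idx <- idx + 1L
    }
  }
  spherical_tensor(out, degrees = 0:l_max)
}

#' Construct a spherical tensor
#'
#' A flat real vector holding one block of length \eqn{2l+1} per degree
#' \eqn{l} in `degrees`, ordered degree-major, \eqn{m = -l..l}.
#'
#' @param values numeric vector of length `sum(2*degrees + 1)`.
#' @param degrees increasing integer vector of degrees.
#' @export
spherical_tensor <- function(values, degrees) {
  degrees <- as.integer(degrees)
  if (is.unsorted(degrees, strictly = TRUE)) stop("degrees must be strictly increasing")
  if (length(values) != sum(2L * degrees + 1L))
    stop("values length ", length(values), " does not match degrees (need ",
         sum(2L * degrees + 1L), ")")
  structure(as.numeric(values), degrees = degrees, class = "spherical_tensor")
}

# index helper: rows of (l, offset) for each degree block inside the flat vector
.degree_blocks <- function(degrees) {
  len <- 2L * degrees + 1L
  end <- cumsum(len)
  data.frame(l = degrees, from = end - len + 1L, to = end)
}

#' Per-degree invariant contraction of a spherical tensor
#'
#' Projects \eqn{x \otimes x} onto total degree \eqn{L=0}, degree by degree.
#' In the real orthonormal basis this reduces to the per-degree trace
#' \eqn{\sum_m x_{lm}^2}; the package fixes the per-degree constant so that the
#' returned invariant is \eqn{\sum_m x_{lm}^2 / \sqrt{2l+1}}. The full
#' Clebsch-Gordan projection equals this up to the degree-wise constant
#' \eqn{(-1)^l} (see [cg_table]).
#'
#' @param x a `spherical_tensor`, or a plain numeric vector with `degrees`
#'   given.
#' @param degrees degrees of `x` when it is a plain vector.
#' @return numeric vector with one rotation-invariant entry per degree.
#' @export
degree_contraction <- function(x, degrees = attr(x, "degrees")) {
  if (is.null(degrees)) stop("degrees must be supplied for plain vectors")
  blk <- .degree_blocks(as.integer(degrees))
  vapply(seq_len(nrow(blk)), function(k) {
    sum(x[blk$from[k]:blk$to[k]]^2) / sqrt(2 * blk$l[k] + 1)
  }, numeric(1))
}

# ---- Clebsch-Gordan machinery (test/oracle path, not on the hot path) ----

#' Wigner 3-j symbol
#'
#' Racah's closed form with log-factorials; exact to double precision for the
#' small angular momenta used here.
#' @param j1,j2,j3,m1,m2,m3 integer (or half-integer) angular momentum labels.
#' @export
wigner_3j <- function(j1, j2, j3, m1, m2, m3) {
  if (m1 + m2 + m3 != 0) return(0)
  if (j3 < abs(j1 - j2) || j3 > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3) return(0)
  lf <- function(n) lgamma(n + 1)
  delta <- 0.5 * (lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
                    lf(j1 + j2 + j3 + 1))
  pre <- delta + 0.5 * (lf(j1 + m1) + lf(j1 - m1) + lf(j2 + m2) + lf(j2 - m2) +
                          lf(j3 + m3) + lf(j3 - m3))
  kmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  kmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  s <- 0
  for (k in kmin:kmax) {
    lt <- lf(k) + lf(j1 + j2 - j3 - k) + lf(j1 - m1 - k) + lf(j2 + m2 - k) +
      lf(j3 - j2 + m1 + k) + lf(j3 - j1 - m2 + k)
    s <- s + (-1)^k * exp(pre - lt)
  }
  (-1)^(j1 - j2 - m3) * s
}

# complex Clebsch-Gordan <l1 m1 l2 m2 | L M>
.cg_complex <- function(l1, m1, l2, m2, L, M) {
  if (m1 + m2 != M) return(0)
  (-1)^(-l1 + l2 - M) * sqrt(2 * L + 1) * wigner_3j(l1, l2, L, m1, m2, -M)
}

# unitary change of basis per degree: Y_real = U %*% Y_complex
.u_real_complex <- function(l) {
  n <- 2 * l + 1
  U <- matrix(0i, n, n)
  for (m in (-l):l) {
    i <- m + l + 1
    if (m == 0) {
      U[i, i] <- 1
    } else if (m > 0) {
      U[i, -m + l + 1] <- 1 / sqrt(2)
      U[i, m + l + 1] <- (-1)^m / sqrt(2)
    } else {
      am <- -m
      U[i, m + l + 1] <- 1i / sqrt(2)
      U[i, am + l + 1] <- -1i * (-1)^am / sqrt(2)
    }
  }
  U
}

#' Clebsch-Gordan coefficients in the real spherical-harmonic basis
#'
#' Builds the coupling table \eqn{C^{m_1 m_2 M}_{l_1 l_2 L}} for all degrees up
#' to `l_max`, transformed to the same real basis as [real_sph_harm]. Entries
#' vanish outside the selection rule \eqn{|l_1-l_2| \le L \le l_1+l_2}. The
#' \eqn{L=0} blocks are diagonal, \eqn{(-1)^l \delta_{m_1 m_2}/\sqrt{2l+1}},
#' which is what makes the cheap per-degree trace of [degree_contraction]
#' possible. The table is used by tests and oracles, not by the network
#' forward pass; results are cached per `l_max`.
#'
#' @param l_max maximal degree.
#' @return object of class `cg_table`: a list with `l_max` and `get(l1, l2, L)`
#'   returning the real coefficient array of dimension
#'   `(2*l1+1) x (2*l2+1) x (2*L+1)`.
#' @export
cg_table <- function(l_max) {
  if (l_max < 0) stop("l_max must be >= 0")
  key <- as.character(l_max)
  if (!is.null(.cg_cache[[key]])) return(.cg_cache[[key]])
  Us <- lapply(0:l_max, .u_real_complex)
  blocks <- list()
  for (l1 in 0:l_max) for (l2 in 0:l_max) for (L in 0:l_max) {
    arr <- array(0, c(2 * l1 + 1, 2 * l2 + 1, 2 * L + 1))
    if (L >= abs(l1 - l2) && L <= l1 + l2) {
      U1 <- Us[[l1 + 1]]; U2 <- Us[[l2 + 1]]; UL <- Us[[L + 1]]
      for (M1 in (-l1):l1) for (M2 in (-l2):l2) for (M in (-L):L) {
        s <- 0i
        for (m1 in (-l1):l1) {
          m2r <- (-l2):l2
          for (m2 in m2r) {
            Mc <- m1 + m2
            if (abs(Mc) > L) next
            cg <- .cg_complex(l1, m1, l2, m2, L, Mc)
            if (cg == 0) next
            s <- s + U1[M1 + l1 + 1, m1 + l1 + 1] *
              U2[M2 + l2 + 1, m2 + l2 + 1] *
              Conj(UL[M + L + 1, Mc + L + 1]) * cg
          }
        }
        arr[M1 + l1 + 1, M2 + l2 + 1, M + L + 1] <- Re(s)
      }
    }
    blocks[[paste(l1, l2, L, sep = ",")]] <- arr
  }
  out <- structure(list(
    l_max = l_max,
    get = function(l1, l2, L) blocks[[paste(l1, l2, L, sep = ",")]]
  ), class = "cg_table")
  .cg_cache[[key]] <- out
  out
}

.cg_cache <- new.env(parent = emptyenv())

# ---- Wigner-D rotation matrices in the real basis ----

.check_rotation <- function(R) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || !all(is.finite(R)))
    stop("R must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("R is not orthogonal")
  if (det(R) < 0)
    stop("R is an improper rotation (det < 0)")
  invisible(R)
}

# ZYZ Euler angles of a proper rotation
.euler_zyz <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(R[3, 3]) > 1 - 1e-12) {
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

# Wigner small-d matrix d^l_{m'm}(beta)
.small_d <- function(l, beta) {
  n <- 2 * l + 1
  d <- matrix(0, n, n)
  lf <- function(x) lgamma(x + 1)
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  for (mp in (-l):l) for (m in (-l):l) {
    kmin <- max(0, m - mp); kmax <- min(l + m, l - mp)
    if (kmin > kmax) next
    s <- 0
    for (k in kmin:kmax) {
      num <- 0.5 * (lf(l + mp) + lf(l - mp) + lf(l + m) + lf(l - m))
      den <- lf(l + m - k) + lf(k) + lf(mp - m + k) + lf(l - mp - k)
      p1 <- 2 * l - mp + m - 2 * k
      p2 <- mp - m + 2 * k
      term <- exp(num - den) *
        (if (p1 == 0) 1 else cb^p1) * (if (p2 == 0) 1 else sb^p2)
      s <- s + (-1)^(mp - m + k) * term
    }
    d[mp + l + 1, m + l + 1] <- s
  }
  d
}

#' Degree-l rotation matrix in the real spherical-harmonic basis
#'
#' Returns the \eqn{(2l+1)\times(2l+1)} matrix \eqn{D^l(R)} satisfying
#' `real_sph_harm(R %*% u, l) == D %*% real_sph_harm(u, l)` degree-wise, built
#' from the ZYZ Euler decomposition, the Wigner small-d matrix and the
#' complex-to-real basis change. Spherical-tensor blocks rotate with exactly
#' these matrices; the function is primarily a test utility.
#'
#' @param R proper rotation matrix (orthogonal, det +1, checked to 1e-8).
#' @param l degree.
#' @export
wigner_d <- function(R, l) {
  .check_rotation(R)
  if (l < 0) stop("l must be >= 0")
  if (l == 0) return(matrix(1, 1, 1))
  ang <- .euler_zyz(R)
  d <- .small_d(l, ang["beta"])
  ms <- (-l):l
  Dc <- exp(1i * outer(ms, rep(1, 2 * l + 1)) * ang["alpha"]) * d *
    exp(1i * outer(rep(1, 2 * l + 1), ms) * ang["gamma"])
  U <- .u_real_complex(l)
  Dr <- U %*% Dc %*% Conj(t(U))
  Re(Dr)
}

# Block-diagonal rotation of a full spherical tensor (all listed degrees).
rotate_spherical_tensor <- function(x, R, degrees = attr(x, "degrees")) {
  blk <- .degree_blocks(as.integer(degrees))
  out <- as.numeric(x)
  for (k in seq_len(nrow(blk))) {
    D <- wigner_d(R, blk$l[k])
    out[blk$from[k]:blk$to[k]] <- D %*% x[blk$from[k]:blk$to[k]]
  }
  spherical_tensor(out, degrees)
}
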