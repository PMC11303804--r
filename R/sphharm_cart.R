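# Vectorized Cartesian-polynomial real spherical harmonics for the network
# hot path, degrees l <= 3, together with analytic gradients with respect to
# the (un-normalized) displacement vector. All expressions are polynomial in
# the unit-vector components and therefore valid for complex inputs, which
# the complex-step training gradients rely on. Cross-checked against the
# recursion-based real_sph_harm() in the tests.

.MAX_NETWORK_DEGREE <- 3L

# per-degree component count and slice positions inside cbind-ed output
.sh_const <- list(
  c00 = 0.28209479177387814,
  c1  = 0.4886025119029199,
  c2a = 1.0925484305920792,   # xy, yz, xz
  c20 = 0.31539156525252005,
  c22 = 0.5462742152960396,
  c33 = 0.5900435899266435,   # y(3x^2-y^2), x(x^2-3y^2)
  c32 = 2.890611442640554,    # xyz
  c31 = 0.4570457994644658,   # y(5z^2-1), x(5z^2-1)
  c30 = 0.3731763325901154,   # z(5z^2-3)
  c3b = 1.445305721320277     # z(x^2-y^2)
)

# E x L matrix of Y_lm(u) for unit rows u (real or complex), degrees a subset
# of 0:3, ordered degree-major, m = -l..l
sph_harm_rows <- function(u, degrees) {
  if (max(degrees) > .MAX_NETWORK_DEGREE)
    stop("network harmonics are implemented for degrees <= ", .MAX_NETWORK_DEGREE)
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  k <- .sh_const
  one <- rep(1, length(x)) + 0 * x  # keeps complex type when u is complex
  cols <- list()
  for (l in degrees) {
    cols[[length(cols) + 1]] <- switch(as.character(l),
      "0" = cbind(k$c00 * one),
      "1" = cbind(k$c1 * y, k$c1 * z, k$c1 * x),
      "2" = cbind(k$c2a * x * y, k$c2a * y * z, k$c20 * (3 * z^2 - 1),
                  k$c2a * x * z, k$c22 * (x^2 - y^2)),
      "3" = cbind(k$c33 * y * (3 * x^2 - y^2), k$c32 * x * y * z,
                  k$c31 * y * (5 * z^2 - 1), k$c30 * z * (5 * z^2 - 3),
                  k$c31 * x * (5 * z^2 - 1), k$c3b * z * (x^2 - y^2),
                  k$c33 * x * (x^2 - 3 * y^2)))
  }
  do.call(cbind, cols)
}

# gradients dY/du (per unit-vector component), same layout; list of three
# E x L matrices
.sph_harm_rows_du <- function(u, degrees) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  k <- .sh_const
  zero <- 0 * x
  one <- 1 + zero
  gx <- list(); gy <- list(); gz <- list()
  for (l in degrees) {
    if (l == 0) {
      gx <- c(gx, list(cbind(zero))); gy <- c(gy, list(cbind(zero)))
      gz <- c(gz, list(cbind(zero)))
    } else if (l == 1) {
      gx <- c(gx, list(cbind(zero, zero, k$c1 * one)))
      gy <- c(gy, list(cbind(k$c1 * one, zero, zero)))
      gz <- c(gz, list(cbind(zero, k$c1 * one, zero)))
    } else if (l == 2) {
      gx <- c(gx, list(cbind(k$c2a * y, zero, zero, k$c2a * z, k$c22 * 2 * x)))
      gy <- c(gy, list(cbind(k$c2a * x, k$c2a * z, zero, zero, -k$c22 * 2 * y)))
      gz <- c(gz, list(cbind(zero, k$c2a * y, k$c20 * 6 * z, k$c2a * x, zero)))
    } else {
      gx <- c(gx, list(cbind(k$c33 * 6 * x * y, k$c32 * y * z, zero, zero,
                             k$c31 * (5 * z^2 - 1), k$c3b * 2 * x * z,
                             k$c33 * 3 * (x^2 - y^2))))
      gy <- c(gy, list(cbind(k$c33 * 3 * (x^2 - y^2), k$c32 * x * z,
                             k$c31 * (5 * z^2 - 1), zero, zero,
                             -k$c3b * 2 * y * z, -k$c33 * 6 * x * y)))
      gz <- c(gz, list(cbind(zero, k$c32 * x * y, k$c31 * 10 * y * z,
                             k$c30 * (15 * z^2 - 3), k$c31 * 10 * x * z,
                             k$c3b * (x^2 - y^2), zero)))
    }
  }
  list(do.call(cbind, gx), do.call(cbind, gy), do.call(cbind, gz))
}

# Y and dY/dd for displacement rows d with norms r (u = d / r). The chain
# rule through the normalization projects out the radial component:
#   dY/dd_b = (dY/du_b - u_b * sum_a u_a dY/du_a) / r
sph_harm_rows_grad <- function(u, r, degrees) {
  Y <- sph_harm_rows(u, degrees)
  G <- .sph_harm_rows_du(u, degrees)
  radial <- u[, 1] * G[[1]] + u[, 2] * G[[2]] + u[, 3] * G[[3]]
  dY <- lapply(1:3, function(b) (G[[b]] - u[, b] * radial) / r)
  list(Y = Y, dY = dY)
}
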