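# Forward pass and hand-written reverse-mode gradients of the Euclidean
# transformer. Every operation here is written to be valid for complex
# inputs as well: training uses complex-step directional derivatives through
# this very code to obtain exact force-loss gradients, so no op may call
# abs(), pmax() or branch on a possibly-complex value directly.

silu <- function(z) z / (1 + exp(-z))
silu_grad <- function(z) {
  s <- 1 / (1 + exp(-z))
  s * (1 + z * (1 - s))
}

# group-sum rows of M by index (length nrow(M)) into an n-row matrix
scatter_rows <- function(M, idx, n) {
  if (is.complex(M)) {
    return(scatter_rows(Re(M), idx, n) + 1i * scatter_rows(Im(M), idx, n))
  }
  out <- matrix(0, n, ncol(M))
  if (length(idx)) {
    rs <- rowsum(M, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# expand an E x nslice coefficient matrix to E x F by repeating each slice
# over its contiguous feature columns
.expand_slices <- function(A, width) {
  A[, rep(seq_len(ncol(A)), each = width), drop = FALSE]
}

# per-degree trace sum: rows of X (E x L) -> E x nd, block k divided by
# sqrt(2 l_k + 1); complex-safe (squares, not moduli)
.contract_rows <- function(X, blk) {
  if (nrow(X) == 0) return(matrix(0, 0, nrow(blk)))
  out <- NULL
  for (k in seq_len(nrow(blk))) {
    v <- X[, blk$from[k]:blk$to[k], drop = FALSE]
    s <- rowSums(v * v) / sqrt(2 * blk$l[k] + 1)
    out <- cbind(out, s)
  }
  out
}

#' Smooth cosine cutoff
#'
#' \eqn{\phi(r) = (\cos(\pi r / r_{cut}) + 1)/2} for \eqn{r \le r_{cut}},
#' zero beyond; guarantees that pairwise interactions decay smoothly to zero
#' at the cutoff sphere.
#' @param r distances, Angstrom (vector ok).
#' @param r_cut cutoff, Angstrom.
#' @export
cutoff <- function(r, r_cut) {
  out <- 0.5 * (cos(pi * r / r_cut) + 1)
  out[Re(r) >= r_cut] <- 0
  out
}

#' Radial basis expansion of an interatomic distance
#'
#' \eqn{g_k(r) = \exp(-\gamma (\exp(-r) - \mu_k)^2)} with centers and width
#' taken from the configuration (see [model_config]).
#' @param r distance(s), Angstrom.
#' @param config a [model_config].
#' @return matrix `length(r) x K`.
#' @export
rbf <- function(r, config) {
  K <- config$n_rbf
  if (!length(r)) return(matrix(0, 0, K))
  er <- exp(-r / config$rbf_length_scale)
  E <- length(er)
  dev <- matrix(er, E, K) - matrix(config$rbf_centers, E, K, byrow = TRUE)
  exp(-config$rbf_gamma * dev * dev)
}

# edge geometry from (possibly complex) positions and a fixed edge topology
.edge_geometry <- function(positions, nl, cfg, want_grad = TRUE) {
  d <- positions[nl$j, , drop = FALSE] - positions[nl$i, , drop = FALSE]
  if (!is.null(nl$shift_cart)) d <- d + nl$shift_cart
  r <- sqrt(rowSums(d * d))
  u <- d / r
  phi <- cutoff(r, cfg$r_cut)
  g <- rbf(r, cfg)
  geo <- list(d = d, r = r, u = u, phi = phi, g = g)
  if (want_grad) {
    geo$dphi <- { v <- -0.5 * pi / cfg$r_cut * sin(pi * r / cfg$r_cut)
                  v[Re(r) >= cfg$r_cut] <- 0; v }
    er <- exp(-r / cfg$rbf_length_scale)
    E <- length(er)
    if (E > 0) {
      dev <- matrix(er, E, cfg$n_rbf) -
        matrix(cfg$rbf_centers, E, cfg$n_rbf, byrow = TRUE)
      geo$dg <- g * 2 * cfg$rbf_gamma * dev * er / cfg$rbf_length_scale
    } else {
      geo$dg <- matrix(0, 0, cfg$n_rbf)
    }
    sg <- sph_harm_rows_grad(u, r, cfg$degrees)
    geo$Y <- sg$Y; geo$dY <- sg$dY
  } else {
    geo$Y <- sph_harm_rows(u, cfg$degrees)
  }
  geo
}

# full forward pass; returns energy, per-atom energies and (optionally) a
# cache of intermediates for the reverse pass
net_forward <- function(positions, z, nl, params, cfg, save = FALSE) {
  n <- length(z)
  blk <- .degree_blocks(cfg$degrees)
  nd <- nrow(blk)
  F <- cfg$feature_dim
  h <- cfg$heads
  dh <- F %/% h
  dd <- F %/% nd
  if (any(z < 1 | z > cfg$max_atomic_number))
    stop("atomic number outside the embedding table: ",
         paste(unique(z[z < 1 | z > cfg$max_atomic_number]), collapse = ", "))
  geo <- .edge_geometry(positions, nl, cfg, want_grad = save)
  i_idx <- nl$i; j_idx <- nl$j
  cmplx <- is.complex(positions)

  f <- params$emb[z, , drop = FALSE]
  if (cmplx) f <- f + 0i
  if (cfg$ev_init == "neighborhood") {
    if (cfg$mean_neighbors <= 0)
      stop("neighborhood EV initialization requires mean_neighbors > 0")
    x <- scatter_rows(geo$phi * geo$Y, i_idx, n) / cfg$mean_neighbors
  } else {
    x <- matrix(if (cmplx) 0i else 0, n, cfg$ev_dim)
  }

  cache <- if (save) list(geo = geo, z = z, n = n, blocks = vector("list", cfg$n_blocks))

  for (t in seq_len(cfg$n_blocks)) {
    P <- params$blocks[[t]]
    xij <- x[j_idx, , drop = FALSE] - x[i_idx, , drop = FALSE]
    uinv <- .contract_rows(xij, blk)
    Z1u <- uinv %*% P$W1u + rep(P$b1u, each = nrow(uinv))
    H1u <- silu(Z1u)
    Z1g <- geo$g %*% P$W1g + rep(P$b1g, each = nrow(geo$g))
    H1g <- silu(Z1g)
    w <- (H1u %*% P$W2u + rep(P$b2u, each = nrow(H1u))) +
         (H1g %*% P$W2g + rep(P$b2g, each = nrow(H1g)))
    q <- f %*% P$Q; k <- f %*% P$K; v <- f %*% P$V
    qi <- q[i_idx, , drop = FALSE]
    wk <- w * k[j_idx, , drop = FALSE]
    prod <- qi * wk
    nE <- nrow(prod)
    alphaH <- matrix(if (cmplx) 0i else 0, nE, h)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      alphaH[, hh] <- rowSums(prod[, cols, drop = FALSE]) / sqrt(dh)
    }
    alphaL <- matrix(if (cmplx) 0i else 0, nE, nd)
    for (kk in seq_len(nd)) {
      cols <- ((kk - 1) * dd + 1):(kk * dd)
      alphaL[, kk] <- rowSums(prod[, cols, drop = FALSE]) / sqrt(dd)
    }
    msgF <- geo$phi * .expand_slices(alphaH, dh) * v[j_idx, , drop = FALSE]
    fATT <- f + scatter_rows(msgF, i_idx, n)
    aLl <- alphaL[, rep(seq_len(nd), times = 2 * blk$l + 1), drop = FALSE]
    msgX <- geo$phi * aLl * geo$Y
    xATT <- x + scatter_rows(msgX, i_idx, n)
    uatt <- .contract_rows(xATT, blk)
    cat_in <- cbind(fATT, uatt)
    Zi <- cat_in %*% P$Wi + rep(P$bi, each = n)
    ab <- silu(Zi)
    a <- ab[, seq_len(F), drop = FALSE]
    b <- ab[, F + seq_len(nd), drop = FALSE]
    bfull <- b[, rep(seq_len(nd), times = 2 * blk$l + 1), drop = FALSE]
    f_new <- fATT + a
    x_new <- xATT * (1 + bfull)
    if (save) {
      cache$blocks[[t]] <- list(f = f, x = x, xij = xij, uinv = uinv,
                                Z1u = Z1u, H1u = H1u, Z1g = Z1g, H1g = H1g,
                                w = w, q = q, k = k, v = v, qi = qi, wk = wk,
                                alphaH = alphaH, alphaL = alphaL,
                                fATT = fATT, xATT = xATT, uatt = uatt,
                                cat_in = cat_in, Zi = Zi, b = b)
    }
    f <- f_new; x <- x_new
  }

  Z1o <- f %*% params$W1o + rep(params$b1o, each = n)
  H1o <- silu(Z1o)
  eraw <- as.vector(H1o %*% params$W2o) + params$b2o
  e_atom <- eraw * params$scale[z] + params$shift[z]
  E_tot <- sum(e_atom)
  if (save) {
    cache$f_final <- f; cache$Z1o <- Z1o; cache$H1o <- H1o; cache$eraw <- eraw
  }
  list(energy = E_tot, e_atom = e_atom, cache = cache)
}

# reverse pass: gradients of the total energy w.r.t. positions and,
# optionally, w.r.t. all parameters
net_backward <- function(cache, params, cfg, param_grads = FALSE) {
  geo <- cache$geo
  z <- cache$z; n <- cache$n
  blk <- .degree_blocks(cfg$degrees)
  nd <- nrow(blk)
  F <- cfg$feature_dim
  h <- cfg$heads
  dh <- F %/% h
  dd <- F %/% nd
  i_idx <- cache$i_idx; j_idx <- cache$j_idx
  cmplx <- is.complex(cache$f_final)
  zero <- if (cmplx) 0i else 0
  Egd <- length(geo$r)

  gP <- if (param_grads) list(blocks = vector("list", cfg$n_blocks))

  # readout
  scl <- params$scale[z]
  geraw <- scl
  if (param_grads) {
    gP$scale <- scatter_rows(cbind(cache$eraw), z, cfg$max_atomic_number)[, 1]
    gP$shift <- scatter_rows(cbind(rep(1, n)), z, cfg$max_atomic_number)[, 1]
    gP$W2o <- t(cache$H1o) %*% cbind(geraw)
    gP$b2o <- sum(geraw)
  }
  gH1o <- cbind(geraw) %*% t(params$W2o)
  gZ1o <- gH1o * silu_grad(cache$Z1o)
  gf <- gZ1o %*% t(params$W1o)
  if (param_grads) {
    gP$W1o <- t(cache$f_final) %*% gZ1o
    gP$b1o <- colSums(gZ1o)
  }
  gx <- matrix(zero, n, cfg$ev_dim)

  # per-edge geometry adjoints accumulated over blocks
  gphi <- rep(zero, Egd)
  gg <- matrix(zero, Egd, cfg$n_rbf)
  gY <- matrix(zero, Egd, ncol(geo$Y))

  for (t in rev(seq_len(cfg$n_blocks))) {
    P <- params$blocks[[t]]
    C <- cache$blocks[[t]]
    # x_new = xATT * (1 + bfull); f_new = fATT + a
    bfull <- C$b[, rep(seq_len(nd), times = 2 * blk$l + 1), drop = FALSE]
    gxATT <- gx * (1 + bfull)
    gb <- matrix(zero, n, nd)
    for (k in seq_len(nd)) {
      cols <- blk$from[k]:blk$to[k]
      gb[, k] <- rowSums(gx[, cols, drop = FALSE] *
                           C$xATT[, cols, drop = FALSE])
    }
    gab <- cbind(gf, gb)
    gZi <- gab * silu_grad(C$Zi)
    gcat <- gZi %*% t(P$Wi)
    if (param_grads) {
      gP$blocks[[t]]$Wi <- t(C$cat_in) %*% gZi
      gP$blocks[[t]]$bi <- colSums(gZi)
    }
    gfATT <- gf + gcat[, seq_len(F), drop = FALSE]
    guatt <- gcat[, F + seq_len(nd), drop = FALSE]
    # uatt = contraction(xATT)
    for (k in seq_len(nd)) {
      cols <- blk$from[k]:blk$to[k]
      gxATT[, cols] <- gxATT[, cols] +
        2 * C$xATT[, cols, drop = FALSE] * guatt[, k] / sqrt(2 * blk$l[k] + 1)
    }
    # xATT = x + scatter(phi * alphaL * Y)
    gx_in <- gxATT
    gmsgX <- gxATT[i_idx, , drop = FALSE]
    SX <- matrix(zero, Egd, nd)
    for (k in seq_len(nd)) {
      cols <- blk$from[k]:blk$to[k]
      SX[, k] <- rowSums(gmsgX[, cols, drop = FALSE] *
                           geo$Y[, cols, drop = FALSE])
    }
    galphaL <- geo$phi * SX
    gphi <- gphi + rowSums(C$alphaL * SX)
    aLl <- C$alphaL[, rep(seq_len(nd), times = 2 * blk$l + 1), drop = FALSE]
    gY <- gY + geo$phi * aLl * gmsgX
    # fATT = f + scatter(phi * alphaH * v_j)
    gf_in <- gfATT
    gmsgF <- gfATT[i_idx, , drop = FALSE]
    vj <- C$v[j_idx, , drop = FALSE]
    SH <- matrix(zero, Egd, h)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      SH[, hh] <- rowSums(gmsgF[, cols, drop = FALSE] *
                            vj[, cols, drop = FALSE])
    }
    galphaH <- geo$phi * SH
    gphi <- gphi + rowSums(C$alphaH * SH)
    gvj <- geo$phi * .expand_slices(C$alphaH, dh) * gmsgF
    gv <- scatter_rows(gvj, j_idx, n)
    # alpha contributions -> q_i and wk
    gA_H <- .expand_slices(galphaH, dh) / sqrt(dh)
    gA_L <- .expand_slices(galphaL, dd) / sqrt(dd)
    gqi <- (gA_H + gA_L) * C$wk
    gwk <- (gA_H + gA_L) * C$qi
    gq <- scatter_rows(gqi, i_idx, n)
    # wk = w * k_j
    kj <- C$k[j_idx, , drop = FALSE]
    gw <- gwk * kj
    gkj <- gwk * C$w
    gk <- scatter_rows(gkj, j_idx, n)
    # q = f Q etc.
    gf_in <- gf_in + gq %*% t(P$Q) + gk %*% t(P$K) + gv %*% t(P$V)
    if (param_grads) {
      gP$blocks[[t]]$Q <- t(C$f) %*% gq
      gP$blocks[[t]]$K <- t(C$f) %*% gk
      gP$blocks[[t]]$V <- t(C$f) %*% gv
    }
    # filter: w = silu(uinv W1u + b1u) W2u + b2u + silu(g W1g + b1g) W2g + b2g
    gH1u <- gw %*% t(P$W2u)
    gZ1u <- gH1u * silu_grad(C$Z1u)
    guinv <- gZ1u %*% t(P$W1u)
    gH1g <- gw %*% t(P$W2g)
    gZ1g <- gH1g * silu_grad(C$Z1g)
    gg <- gg + gZ1g %*% t(P$W1g)
    if (param_grads) {
      gP$blocks[[t]]$W2u <- t(C$H1u) %*% gw
      gP$blocks[[t]]$b2u <- colSums(gw)
      gP$blocks[[t]]$W1u <- t(C$uinv) %*% gZ1u
      gP$blocks[[t]]$b1u <- colSums(gZ1u)
      gP$blocks[[t]]$W2g <- t(C$H1g) %*% gw
      gP$blocks[[t]]$b2g <- colSums(gw)
      gP$blocks[[t]]$W1g <- t(geo$g) %*% gZ1g
      gP$blocks[[t]]$b1g <- colSums(gZ1g)
    }
    # uinv = contraction(xij); xij = x_j - x_i
    gxij <- matrix(zero, Egd, cfg$ev_dim)
    for (k in seq_len(nd)) {
      cols <- blk$from[k]:blk$to[k]
      gxij[, cols] <- 2 * C$xij[, cols, drop = FALSE] * guinv[, k] /
        sqrt(2 * blk$l[k] + 1)
    }
    gx_in <- gx_in + scatter_rows(gxij, j_idx, n) - scatter_rows(gxij, i_idx, n)
    gf <- gf_in
    gx <- gx_in
  }

  # EV initialization
  if (cfg$ev_init == "neighborhood") {
    gmsg0 <- gx[i_idx, , drop = FALSE] / cfg$mean_neighbors
    gphi <- gphi + rowSums(gmsg0 * geo$Y)
    gY <- gY + geo$phi * gmsg0
  }
  if (param_grads) {
    gP$emb <- scatter_rows(gf, z, cfg$max_atomic_number)
  }

  # geometry -> displacement -> positions
  gr <- gphi * geo$dphi + rowSums(gg * geo$dg)
  gd <- gr * geo$u
  for (bcoord in 1:3) {
    gd[, bcoord] <- gd[, bcoord] + rowSums(gY * geo$dY[[bcoord]])
  }
  gpos <- scatter_rows(gd, j_idx, n) - scatter_rows(gd, i_idx, n)

  list(gpos = gpos, gparams = gP)
}

# convenience wrapper: energy + gradient machinery for one system
.model_eval <- function(model, system, nl = NULL, positions = NULL,
                        gradient = FALSE, param_grads = FALSE) {
  cfg <- model$config
  if (is.null(nl)) nl <- build_neighbors(system, cfg$r_cut)
  if (is.null(positions)) positions <- system$positions
  fw <- net_forward(positions, system$atomic_numbers, nl, model$params, cfg,
                    save = gradient)
  if (!gradient) return(list(energy = fw$energy, e_atom = fw$e_atom))
  fw$cache$i_idx <- nl$i
  fw$cache$j_idx <- nl$j
  bw <- net_backward(fw$cache, model$params, cfg, param_grads = param_grads)
  list(energy = fw$energy, e_atom = fw$e_atom, gpos = bw$gpos,
       gparams = bw$gparams)
}

#' Total potential energy of the network model
#'
#' Runs embedding, EV initialization, `T` transformer blocks and the per-atom
#' energy readout, and sums atomic contributions.
#'
#' @param system an [atomic_system].
#' @param model an [mlff_model].
#' @return list with `energy` (eV) and `e_atom` (per-atom energies).
#' @export
forward_energy <- function(system, model) {
  .model_eval(model, system, gradient = FALSE)
}

#' Analytic atomic forces of the network model
#'
#' Exact reverse-mode gradient \eqn{F_i = -\partial E / \partial \vec r_i} of
#' [forward_energy]; being the gradient of a rotationally invariant energy,
#' the forces are covariant and conservative by construction.
#'
#' @param system an [atomic_system].
#' @param model an [mlff_model].
#' @return list with `energy` (eV) and `forces` (n x 3 matrix, eV/Angstrom).
#' @export
forces <- function(system, model) {
  ev <- .model_eval(model, system, gradient = TRUE)
  list(energy = ev$energy, forces = -ev$gpos)
}
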