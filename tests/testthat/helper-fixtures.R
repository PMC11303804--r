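# shared fixtures and small oracles for the test suite

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rand_system <- function(n, z_pool = c(1, 6, 7, 8), spread = 2) {
  atomic_system(sample(z_pool, n, replace = TRUE),
                matrix(stats::rnorm(3 * n) * spread, n, 3))
}

small_model <- function(degrees = 0:3, F = 32, T = 2, h = 4, r_cut = 5,
                        seed = 1, mean_neighbors = 3,
                        ev_init = "neighborhood") {
  cfg <- model_config(feature_dim = F, heads = h, n_blocks = T,
                      degrees = degrees, r_cut = r_cut,
                      mean_neighbors = mean_neighbors, ev_init = ev_init)
  mlff_model(cfg, seed = seed)
}

# brute-force L = 0 projection of x (x) x through the full real CG table
cg_l0_projection <- function(x, degrees, tab = cg_table(max(degrees))) {
  blk <- data.frame(l = degrees,
                    from = cumsum(2 * degrees + 1) - (2 * degrees + 1) + 1,
                    to = cumsum(2 * degrees + 1))
  vapply(seq_along(degrees), function(k) {
    l <- degrees[k]
    C <- tab$get(l, l, 0)[, , 1]
    xv <- x[blk$from[k]:blk$to[k]]
    as.numeric(t(xv) %*% C %*% xv)
  }, numeric(1))
}

# independent symbolic Wigner-3j oracle (sympy), queried in one batch;
# returns NULL when no python/sympy is available so callers can fall back
sympy_w3j <- function(tuples) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  spec <- paste(apply(tuples, 1, paste, collapse = ","), collapse = ";")
  code <- paste0(
    "from sympy.physics.wigner import wigner_3j\n",
    "for t in '", spec, "'.split(';'):\n",
    "    j1,j2,j3,m1,m2,m3 = [int(x) for x in t.split(',')]\n",
    "    print(float(wigner_3j(j1,j2,j3,m1,m2,m3)))\n")
  out <- tryCatch(system2(py, "-", input = code, stdout = TRUE,
                          stderr = FALSE),
                  warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out) || length(out) != nrow(tuples)) return(NULL)
  as.numeric(out)
}

# analytic LJ dimer quantities
lj_dimer_r_eq <- function(sigma) 2^(1/6) * sigma

# minimal Gauss-Legendre rule on [-1, 1] via the Golub-Welsch eigenproblem
statmod_gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}
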