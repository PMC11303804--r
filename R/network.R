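# Model configuration, parameter initialization and bookkeeping for the
# Euclidean-attention transformer potential.

#' Model configuration
#'
#' Hyperparameters of the Euclidean transformer. `feature_dim` must be
#' divisible both by the number of invariant attention heads `heads` and by
#' the number of degrees carried by the Euclidean variables (EV): the
#' invariant branch splits the feature vector into `heads` slices, the EV
#' branch into one slice per degree.
#'
#' Radial basis centers are equally spaced in `[exp(-r_cut/l), 1]` on the
#' softly-compressed distance axis `exp(-r/l)`, with width parameter
#' `gamma = (2/K * (1 - exp(-r_cut/l)))^-2`. The length scale
#' `rbf_length_scale` (`l`, Angstrom) sets where the exponential axis has
#' resolution; the conventional choice `l = 1` suits covalently bonded
#' molecules, while weakly bound systems with larger interatomic spacings
#' (e.g. rare-gas clusters) need `l` of the order of their typical
#' nearest-neighbor distance.
#'
#' @param feature_dim invariant feature dimension F.
#' @param heads number of invariant attention heads h.
#' @param n_blocks number of transformer blocks T.
#' @param degrees increasing integer degrees carried by the EV (max 3 on the
#'   network path).
#' @param r_cut interaction cutoff, Angstrom.
#' @param n_rbf number of radial basis functions K.
#' @param ev_init `"neighborhood"` (geometry-seeded EV) or `"zeros"`.
#' @param mean_neighbors dataset-average directed neighbor count; set at
#'   training time by [train_mlff] (see [mean_neighbor_count]) and reused at
#'   inference. A value of 1 is a neutral placeholder.
#' @param max_atomic_number extent of the element embedding table.
#' @return object of class `model_config`.
#' @export
model_config <- function(feature_dim = 132, heads = 4, n_blocks = 3,
                         degrees = 0:3, r_cut = 5, n_rbf = 32,
                         rbf_length_scale = 1,
                         ev_init = c("neighborhood", "zeros"),
                         mean_neighbors = 1, max_atomic_number = 118) {
  ev_init <- match.arg(ev_init)
  degrees <- as.integer(degrees)
  if (is.unsorted(degrees, strictly = TRUE) || any(degrees < 0))
    stop("degrees must be strictly increasing and non-negative")
  if (max(degrees) > .MAX_NETWORK_DEGREE)
    stop("network degrees are limited to l <= ", .MAX_NETWORK_DEGREE)
  nd <- length(degrees)
  if (feature_dim %% heads != 0)
    stop("feature_dim must be divisible by heads")
  if (feature_dim %% nd != 0)
    stop("feature_dim must be divisible by the number of degrees (", nd, ")")
  if (n_rbf < 1) stop("n_rbf must be >= 1")
  if (r_cut <= 0) stop("r_cut must be positive")
  if (rbf_length_scale <= 0) stop("rbf_length_scale must be positive")
  mu <- seq(exp(-r_cut / rbf_length_scale), 1, length.out = n_rbf)
  gamma <- (2 / n_rbf * (1 - exp(-r_cut / rbf_length_scale)))^-2
  structure(list(
    feature_dim = as.integer(feature_dim), heads = as.integer(heads),
    n_blocks = as.integer(n_blocks), degrees = degrees, r_cut = r_cut,
    n_rbf = as.integer(n_rbf), rbf_length_scale = rbf_length_scale,
    rbf_centers = mu, rbf_gamma = gamma,
    ev_init = ev_init, mean_neighbors = mean_neighbors,
    max_atomic_number = as.integer(max_atomic_number),
    ev_dim = sum(2L * degrees + 1L)
  ), class = "model_config")
}

.lecun <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
}

#' Initialize model parameters
#'
#' Draws all trainable arrays (embedding table; per-block query/key/value
#' matrices, two-branch filter MLPs and interaction-block affine weights;
#' final two-layer energy readout; per-element energy shift/scale) with
#' scaled-normal weights and zero biases, deterministically for a given seed.
#'
#' @param config a [model_config].
#' @param seed integer RNG seed.
#' @return object of class `mlff_params` (a named list of arrays).
#' @export
init_params <- function(config, seed = 0) {
  set.seed(seed)
  F <- config$feature_dim
  nd <- length(config$degrees)
  K <- config$n_rbf
  F4 <- max(1L, F %/% 4L)
  F2 <- max(1L, F %/% 2L)
  blocks <- lapply(seq_len(config$n_blocks), function(t) list(
    Q = .lecun(F, F), K = .lecun(F, F), V = .lecun(F, F),
    W1u = .lecun(nd, F4), b1u = numeric(F4),
    W2u = .lecun(F4, F), b2u = numeric(F),
    W1g = .lecun(K, F), b1g = numeric(F),
    W2g = .lecun(F, F), b2g = numeric(F),
    Wi = .lecun(F + nd, F + nd), bi = numeric(F + nd)
  ))
  structure(list(
    emb = matrix(stats::rnorm(config$max_atomic_number * F), ncol = F),
    blocks = blocks,
    W1o = .lecun(F, F2), b1o = numeric(F2),
    W2o = .lecun(F2, 1), b2o = numeric(1),
    shift = numeric(config$max_atomic_number),
    scale = rep(1, config$max_atomic_number)
  ), class = "mlff_params")
}

#' Construct a model (configuration + parameters)
#'
#' @param config a [model_config].
#' @param params optional [init_params] result; drawn from `seed` if absent.
#' @param seed RNG seed for parameter initialization.
#' @export
mlff_model <- function(config, params = NULL, seed = 0) {
  if (is.null(params)) params <- init_params(config, seed)
  structure(list(config = config, params = params), class = "mlff_model")
}

#' @export
print.mlff_model <- function(x, ...) {
  cfg <- x$config
  cat("<mlff_model> F=", cfg$feature_dim, " h=", cfg$heads, " T=",
      cfg$n_blocks, " degrees={", paste(cfg$degrees, collapse = ","),
      "} r_cut=", cfg$r_cut, " A, ", count_params(x$params),
      " parameters\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param params an `mlff_params` (or `mlff_model`).
#' @return integer count of scalar trainables.
#' @export
count_params <- function(params) {
  if (inherits(params, "mlff_model")) params <- params$params
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else n <<- n + length(x)
  }
  walk(unclass(params))
  n
}

# ---- flat parameter vector <-> structured list (for the optimizer) ----

params_flatten <- function(params) {
  acc <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in seq_along(x)) walk(x[[nm]], c(path, nm))
    } else acc[[length(acc) + 1]] <<- as.numeric(x)
  }
  walk(unclass(params), integer(0))
  unlist(acc)
}

params_unflatten <- function(template, theta) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (nm in seq_along(x)) x[[nm]] <- walk(x[[nm]])
      x
    } else {
      k <- length(x)
      v <- theta[(pos + 1L):(pos + k)]
      pos <<- pos + k
      if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
    }
  }
  out <- walk(unclass(template))
  if (pos != length(theta)) stop("parameter vector length mismatch")
  class(out) <- "mlff_params"
  out
}
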