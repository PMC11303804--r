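# Small exported views into the network's building blocks, mainly for
# inspection and for the blockwise symmetry tests.

#' Element embedding lookup
#'
#' Initial invariant features: row `z` of the embedding table for each atom.
#' @param z atomic numbers.
#' @param model an [mlff_model].
#' @return n x F matrix.
#' @export
embed_features <- function(z, model) {
  cfg <- model$config
  if (any(z < 1 | z > cfg$max_atomic_number))
    stop("atomic number outside the embedding table: ",
         paste(unique(z[z < 1 | z > cfg$max_atomic_number]), collapse = ", "))
  model$params$emb[z, , drop = FALSE]
}

#' Initial Euclidean variables from the neighborhood geometry
#'
#' \eqn{x_{ilm} = \frac{1}{\langle N \rangle} \sum_{j \in N(i)}
#' \phi(r_{ij}) Y_{lm}(\hat r_{ij})}, or all zeros when the configuration
#' requests zero initialization (the first attention update then populates
#' them).
#'
#' @param system an [atomic_system].
#' @param nl a `neighbor_list` built at the model cutoff.
#' @param config a [model_config].
#' @return n x `ev_dim` matrix (rows are spherical tensors over
#'   `config$degrees`).
#' @export
init_ev <- function(system, nl, config) {
  n <- nrow(system$positions)
  if (config$ev_init == "zeros") return(matrix(0, n, config$ev_dim))
  if (config$mean_neighbors <= 0)
    stop("neighborhood EV initialization requires mean_neighbors > 0")
  if (!length(nl$i)) return(matrix(0, n, config$ev_dim))
  phi <- cutoff(nl$r, config$r_cut)
  Y <- sph_harm_rows(nl$u, config$degrees)
  scatter_rows(phi * Y, nl$i, n) / config$mean_neighbors
}

#' Per-block states of a forward pass
#'
#' Runs the full forward pass and returns the invariant features and
#' Euclidean variables entering and leaving every transformer block,
#' so invariance/equivariance can be verified block by block rather than
#' only end to end.
#'
#' @param system an [atomic_system].
#' @param model an [mlff_model].
#' @return list with `energy`, `f0`, `x0` and `blocks`, each block holding
#'   `f_att`, `x_att` (post-attention) and `f`, `x` (post-interaction).
#' @export
forward_states <- function(system, model) {
  cfg <- model$config
  nl <- build_neighbors(system, cfg$r_cut)
  fw <- net_forward(system$positions, system$atomic_numbers, nl,
                    model$params, cfg, save = TRUE)
  blocks <- lapply(seq_len(cfg$n_blocks), function(t) {
    C <- fw$cache$blocks[[t]]
    nxt <- if (t < cfg$n_blocks) fw$cache$blocks[[t + 1]]
    list(f_att = C$fATT, x_att = C$xATT,
         f = if (is.null(nxt)) fw$cache$f_final else nxt$f,
         x = if (is.null(nxt)) NULL else nxt$x)
  })
  # the final block's outgoing EV is not cached; recover it from the update
  lastC <- fw$cache$blocks[[cfg$n_blocks]]
  blk <- .degree_blocks(cfg$degrees)
  bfull <- lastC$b[, rep(seq_len(nrow(blk)), times = 2 * blk$l + 1),
                   drop = FALSE]
  blocks[[cfg$n_blocks]]$x <- lastC$xATT * (1 + bfull)
  list(energy = fw$energy,
       f0 = fw$cache$blocks[[1]]$f, x0 = fw$cache$blocks[[1]]$x,
       blocks = blocks)
}
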