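# Combined energy/force loss, Adam training loop and evaluation metrics.
#
# Gradient strategy: R has no automatic differentiation, so the package
# carries a hand-written reverse pass (net_backward) producing both position
# and parameter gradients of the energy. The force part of the loss needs
# mixed second derivatives d^2E/(dr dtheta); these are obtained by running
# the same forward+reverse code at complex-shifted positions
# r + i*h*(F - F_ref) and taking Im(.)/h -- a complex-step directional
# derivative, exact to machine precision, at the cost of one extra
# (complex) evaluation per sample.

#' Combined energy/force loss
#'
#' \eqn{L = (1-\beta)(E - \tilde E)^2 + \frac{\beta}{3n}\sum_{k,c}
#' (F_{kc} - \tilde F_{kc})^2}.
#'
#' @param pred list with `energy` and `forces`.
#' @param ref list with `energy` and `forces` (same shapes).
#' @param beta trade-off in `[0, 1]`.
#' @export
loss_ef <- function(pred, ref, beta = 0.99) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (!all(dim(pred$forces) == dim(ref$forces)))
    stop("force shape mismatch")
  n <- nrow(ref$forces)
  (1 - beta) * (pred$energy - ref$energy)^2 +
    beta / (3 * n) * sum((pred$forces - ref$forces)^2)
}

#' Training configuration
#'
#' @param beta energy/force loss trade-off (default 0.99 -- training is
#'   dominated by forces).
#' @param lr0 initial Adam learning rate.
#' @param decay_factor,decay_interval exponential learning-rate schedule:
#'   `lr = lr0 * decay_factor^floor(step / decay_interval)`.
#' @param steps total training steps.
#' @param batch_size `NULL` selects the dataset-size rule: 1 when the
#'   training split has at most 1000 structures, 10 otherwise.
#' @param val_fraction validation fraction (ignored when `n_val` given).
#' @param n_val absolute validation count (overrides `val_fraction`).
#' @param eval_every validation interval (steps) for best-checkpoint
#'   selection.
#' @param seed RNG seed (split, shuffling).
#' @param target_val_loss optional early stop once the validation loss
#'   drops below this value.
#' @export
train_config <- function(beta = 0.99, lr0 = 1e-3, decay_factor = 0.7,
                         decay_interval = 100000, steps = 10000,
                         batch_size = NULL, val_fraction = 0.1, n_val = NULL,
                         eval_every = 1000, seed = 1,
                         target_val_loss = NULL) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (steps <= 0) stop("steps must be positive")
  structure(list(beta = beta, lr0 = lr0, decay_factor = decay_factor,
                 decay_interval = decay_interval, steps = as.integer(steps),
                 batch_size = batch_size, val_fraction = val_fraction,
                 n_val = n_val, eval_every = as.integer(eval_every),
                 seed = as.integer(seed), target_val_loss = target_val_loss),
            class = "train_config")
}

# learning rate at a given 0-based step
.lr_at <- function(cfg, step) {
  cfg$lr0 * cfg$decay_factor^(step %/% cfg$decay_interval)
}

# batch-size rule keyed on the training-split size
.batch_size_rule <- function(n_train) if (n_train <= 1000) 1L else 10L

# least-squares per-element energy shifts + a global per-atom scale from
# the label spread; initializes the readout statistics before training
.fit_energy_stats <- function(params, cfg, dataset) {
  zs <- sort(unique(unlist(lapply(dataset$systems, `[[`, "atomic_numbers"))))
  counts <- t(vapply(dataset$systems, function(s)
    vapply(zs, function(z) sum(s$atomic_numbers == z), numeric(1)),
    numeric(length(zs))))
  counts <- matrix(counts, ncol = length(zs))
  fit <- stats::lm.fit(counts, dataset$energies)
  shift <- fit$coefficients
  shift[is.na(shift)] <- 0
  params$shift[zs] <- shift
  f_rms <- sqrt(mean(unlist(lapply(dataset$forces, function(f) f^2))))
  params$scale[] <- max(f_rms, 1e-3)
  params
}

# align a gradient list produced by net_backward with the parameter layout
.grads_align <- function(gP, template) {
  out <- template
  out$emb <- gP$emb
  for (t in seq_along(template$blocks)) {
    for (nm in names(template$blocks[[t]]))
      out$blocks[[t]][[nm]] <- gP$blocks[[t]][[nm]]
  }
  for (nm in c("W1o", "b1o", "W2o", "b2o", "shift", "scale"))
    out[[nm]] <- gP[[nm]]
  out
}

params_flatten_any <- function(params) {
  acc <- list()
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el)
    else acc[[length(acc) + 1]] <<- as.vector(x)
  }
  walk(unclass(params))
  unlist(acc)
}

# loss gradient for one labeled structure, as a flat parameter vector
.sample_grad <- function(model, sample, beta, h_step = 1e-10) {
  sys <- sample$system
  nl <- build_neighbors(sys, model$config$r_cut)
  ev <- .model_eval(model, sys, nl = nl, gradient = TRUE, param_grads = TRUE)
  E <- ev$energy
  Fp <- -ev$gpos
  n <- nrow(Fp)
  dE <- E - sample$energy
  dF <- Fp - sample$forces
  gE <- params_flatten_any(.grads_align(ev$gparams, model$params))
  # complex-step directional derivative of grad_theta E along dF in r
  pos_c <- sys$positions + 1i * h_step * dF
  evc <- .model_eval(model, sys, nl = nl, positions = pos_c,
                     gradient = TRUE, param_grads = TRUE)
  gS <- Im(params_flatten_any(.grads_align(evc$gparams, model$params))) / h_step
  g <- 2 * (1 - beta) * dE * gE - (2 * beta / (3 * n)) * gS
  loss <- (1 - beta) * dE^2 + beta / (3 * n) * sum(dF^2)
  list(grad = g, loss = loss, e_err = abs(dE), f_mae = mean(abs(dF)))
}

.dataset_loss <- function(model, dataset, beta) {
  tot <- 0
  for (s in seq_along(dataset$systems)) {
    pred <- forces(dataset$systems[[s]], model)
    tot <- tot + loss_ef(pred, list(energy = dataset$energies[s],
                                    forces = dataset$forces[[s]]), beta)
  }
  tot / length(dataset$systems)
}

#' Train the network potential
#'
#' Adam with an exponentially decayed learning rate on the combined
#' energy/force loss. The dataset is split into training and validation
#' parts with the configuration seed before training; the mean neighbor
#' count and per-element energy statistics are fitted on the training split
#' and frozen into the model. Validation loss is evaluated every
#' `eval_every` steps and the best-validation parameters are returned.
#' Bit-reproducible for a fixed seed in a single-threaded session.
#'
#' @param model an [mlff_model] (its `mean_neighbors` is overwritten by the
#'   training-split statistics).
#' @param dataset a [labeled_dataset] (converted to eV internally).
#' @param config a [train_config].
#' @return list with `model` (best validation), `history` (data frame of
#'   step, lr, train loss, validation loss), `val_indices`.
#' @export
train_mlff <- function(model, dataset, config = train_config()) {
  if (!length(dataset$systems)) stop("empty dataset")
  dataset <- convert_units(dataset, "eV")
  N <- length(dataset$systems)
  set.seed(config$seed)
  n_val <- if (!is.null(config$n_val)) config$n_val
           else max(1L, round(config$val_fraction * N))
  if (n_val >= N) stop("validation split leaves no training data")
  val_idx <- sort(sample.int(N, n_val))
  tr_idx <- setdiff(seq_len(N), val_idx)
  sub <- function(idx) labeled_dataset(dataset$systems[idx],
                                       dataset$energies[idx],
                                       dataset$forces[idx], dataset$units)
  d_tr <- sub(tr_idx); d_val <- sub(val_idx)
  bs <- if (is.null(config$batch_size)) .batch_size_rule(length(tr_idx))
        else config$batch_size

  model$config$mean_neighbors <- mean_neighbor_count(d_tr$systems,
                                                     model$config$r_cut)
  model$params <- .fit_energy_stats(model$params, model$config, d_tr)

  theta <- params_flatten_any(model$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_val <- Inf
  best_theta <- theta
  hist <- list()
  order_pool <- integer(0)
  for (step in seq_len(config$steps)) {
    if (length(order_pool) < bs)
      order_pool <- c(order_pool, sample(length(tr_idx)))
    take <- order_pool[seq_len(bs)]
    order_pool <- order_pool[-seq_len(bs)]
    g <- numeric(length(theta)); batch_loss <- 0
    for (ii in take) {
      sm <- list(system = d_tr$systems[[ii]], energy = d_tr$energies[ii],
                 forces = d_tr$forces[[ii]])
      sg <- .sample_grad(model, sm, config$beta)
      if (!all(is.finite(sg$grad)) || !is.finite(sg$loss))
        stop("non-finite loss/gradient at step ", step,
             " (structure ", tr_idx[ii], "); lr = ",
             .lr_at(config, step - 1L))
      g <- g + sg$grad / bs
      batch_loss <- batch_loss + sg$loss / bs
    }
    lr <- .lr_at(config, step - 1L)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^step)
    vh <- v / (1 - b2^step)
    theta <- theta - lr * mh / (sqrt(vh) + eps)
    model$params <- params_unflatten(model$params, theta)
    if (step %% config$eval_every == 0 || step == config$steps) {
      vl <- .dataset_loss(model, d_val, config$beta)
      hist[[length(hist) + 1]] <- data.frame(step = step, lr = lr,
                                             train_loss = batch_loss,
                                             val_loss = vl)
      if (vl < best_val) { best_val <- vl; best_theta <- theta }
      if (!is.null(config$target_val_loss) && vl < config$target_val_loss)
        break
    }
  }
  model$params <- params_unflatten(model$params, best_theta)
  list(model = model, history = do.call(rbind, hist),
       best_val_loss = best_val, val_indices = val_idx)
}

#' Evaluate a model on a labeled dataset
#'
#' Energy and force mean absolute errors, plus the per-atom force-error
#' norms \eqn{\epsilon_i = \lVert \hat F_i - \tilde F_i \rVert_2} and their
#' per-structure means.
#'
#' @param model an [mlff_model].
#' @param dataset a [labeled_dataset].
#' @param units `"eV"` or `"kcal/mol"` for the reported metrics.
#' @return list with `energy_mae`, `force_mae` (mean |component error|),
#'   `force_norm_mae` (mean \eqn{\epsilon_i}), `per_structure` (data frame),
#'   `eps_atom` (list of per-atom error norms).
#' @export
evaluate_mlff <- function(model, dataset, units = c("eV", "kcal/mol")) {
  units <- match.arg(units)
  dataset <- convert_units(dataset, "eV")
  fac <- if (units == "kcal/mol") 23.0609 else 1
  e_err <- numeric(length(dataset$systems))
  f_err <- numeric(length(dataset$systems))
  eps_list <- vector("list", length(dataset$systems))
  for (s in seq_along(dataset$systems)) {
    pred <- forces(dataset$systems[[s]], model)
    e_err[s] <- abs(pred$energy - dataset$energies[s])
    dF <- pred$forces - dataset$forces[[s]]
    f_err[s] <- mean(abs(dF))
    eps_list[[s]] <- sqrt(rowSums(dF^2))
  }
  list(energy_mae = mean(e_err) * fac,
       force_mae = mean(f_err) * fac,
       force_norm_mae = mean(unlist(eps_list)) * fac,
       per_structure = data.frame(
         structure = seq_along(eps_list),
         energy_abs_err = e_err * fac,
         force_norm_mean = vapply(eps_list, mean, numeric(1)) * fac),
       eps_atom = lapply(eps_list, function(e) e * fac),
       units = units)
}
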