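# File formats, checkpoints and the command-line interface.
#
# Extended XYZ is the lingua franca for frames: a per-frame comment line of
# key=value fields (Lattice, Properties, energy, pbc, time) and per-atom
# columns declared by the Properties descriptor. Atom indices are 1-based
# throughout the user-facing surface.

.fmt_num <- function(x) sprintf("%.12g", x)

#' Write frames as extended XYZ
#'
#' @param frames a list of frames, each a list with `system`
#'   ([atomic_system]) and optional `energy`, `forces`, `velocities`,
#'   `time`; or a single [atomic_system]; or an `md_trajectory`; or a
#'   [labeled_dataset].
#' @param path output file.
#' @export
write_extxyz <- function(frames, path) {
  frames <- .as_frame_list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    sys <- fr$system
    n <- nrow(sys$positions)
    props <- "species:S:1:pos:R:3"
    cols <- cbind(element_symbol_of(sys$atomic_numbers),
                  matrix(.fmt_num(sys$positions), n, 3))
    if (!is.null(fr$forces)) {
      props <- paste0(props, ":forces:R:3")
      cols <- cbind(cols, matrix(.fmt_num(fr$forces), n, 3))
    }
    if (!is.null(fr$velocities)) {
      props <- paste0(props, ":vel:R:3")
      cols <- cbind(cols, matrix(.fmt_num(fr$velocities), n, 3))
    }
    comment <- paste0("Properties=", props)
    if (!is.null(sys$cell))
      comment <- paste0("Lattice=\"",
                        paste(.fmt_num(t(sys$cell)), collapse = " "),
                        "\" ", comment)
    if (any(sys$pbc))
      comment <- paste0(comment, " pbc=\"",
                        paste(ifelse(sys$pbc, "T", "F"), collapse = " "), "\"")
    if (!is.null(fr$energy))
      comment <- paste0(comment, " energy=", .fmt_num(fr$energy))
    if (!is.null(fr$time))
      comment <- paste0(comment, " time=", .fmt_num(fr$time))
    writeLines(c(as.character(n), comment,
                 apply(cols, 1, paste, collapse = " ")), con)
  }
  invisible(path)
}

.as_frame_list <- function(frames) {
  if (inherits(frames, "atomic_system")) return(list(list(system = frames)))
  if (inherits(frames, "md_trajectory")) {
    sys <- frames$system
    return(lapply(frames$frames, function(fr) {
      s <- sys; s$positions <- fr$positions
      list(system = s, energy = fr$epot, velocities = fr$velocities,
           time = fr$time)
    }))
  }
  if (inherits(frames, "labeled_dataset")) {
    return(lapply(seq_along(frames$systems), function(k)
      list(system = frames$systems[[k]], energy = frames$energies[k],
           forces = frames$forces[[k]])))
  }
  frames
}

# parse one comment line into a named list of strings
.parse_kv <- function(line) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)', line)[[1]]
  if (m[1] == -1) return(list())
  toks <- regmatches(line, gregexpr('([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)',
                                    line))[[1]]
  out <- list()
  for (tk in toks) {
    eq <- regexpr("=", tk)
    key <- substr(tk, 1, eq - 1)
    val <- substr(tk, eq + 1, nchar(tk))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Read frames from an extended XYZ file
#'
#' @param path input file.
#' @return list of frames: each a list with `system` and, when present in
#'   the file, `energy`, `forces`, `velocities`, `time`.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1)
      stop("malformed atom count at line ", ln, " of ", path)
    if (ln + 1L + n > length(lines))
      stop("truncated frame starting at line ", ln, " of ", path)
    kv <- .parse_kv(lines[ln + 1L])
    props <- kv$Properties
    if (is.null(props)) props <- "species:S:1:pos:R:3"
    pr <- strsplit(props, ":")[[1]]
    fields <- matrix(pr, nrow = 3)
    widths <- as.integer(fields[3, ])
    names_f <- fields[1, ]
    body <- lines[(ln + 2L):(ln + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncols <- sum(widths)
    bad <- which(vapply(toks, length, integer(1)) != ncols)
    if (length(bad))
      stop("column mismatch at line ", ln + 1L + bad[1], " of ", path,
           " (expected ", ncols, " fields)")
    tab <- do.call(rbind, toks)
    colstart <- cumsum(c(1, widths))[seq_along(widths)]
    getf <- function(nm) {
      k <- match(nm, names_f)
      if (is.na(k)) return(NULL)
      tab[, colstart[k]:(colstart[k] + widths[k] - 1), drop = FALSE]
    }
    species <- getf("species")[, 1]
    pos <- matrix(as.numeric(getf("pos")), n, 3)
    cell <- NULL; pbc <- FALSE
    if (!is.null(kv$Lattice)) {
      cell <- matrix(as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]]),
                     3, 3, byrow = TRUE)
      pbc <- TRUE
    }
    if (!is.null(kv$pbc)) pbc <- strsplit(trimws(kv$pbc), "\\s+")[[1]] %in% c("T", "True", "true")
    sys <- atomic_system(atomic_number_of(species), pos, cell = cell, pbc = pbc)
    fr <- list(system = sys)
    if (!is.null(kv$energy)) fr$energy <- as.numeric(kv$energy)
    if (!is.null(kv$time)) fr$time <- as.numeric(kv$time)
    fmat <- getf("forces")
    if (!is.null(fmat)) fr$forces <- matrix(as.numeric(fmat), n, 3)
    vmat <- getf("vel")
    if (!is.null(vmat)) fr$velocities <- matrix(as.numeric(vmat), n, 3)
    frames[[length(frames) + 1]] <- fr
    ln <- ln + 2L + n
  }
  frames
}

#' Rebuild a trajectory object from frames (e.g. read from disk)
#'
#' @param frames list of frames with `system`, `velocities`, optionally
#'   `energy`/`time`.
#' @param dt MD time step, fs.
#' @param stride frame stride in steps.
#' @export
trajectory_from_frames <- function(frames, dt, stride = 1) {
  sys <- frames[[1]]$system
  fl <- lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    list(positions = fr$system$positions,
         velocities = if (!is.null(fr$velocities)) fr$velocities
                      else matrix(0, nrow(fr$system$positions), 3),
         time = if (!is.null(fr$time)) fr$time else (k - 1) * dt * stride,
         epot = if (!is.null(fr$energy)) fr$energy else NA_real_)
  })
  epot <- vapply(fl, `[[`, numeric(1), "epot")
  ekin <- vapply(fl, function(fr) kinetic_energy(fr$velocities, sys$masses),
                 numeric(1))
  ndof <- .n_dof(nrow(sys$positions), any(sys$pbc))
  structure(list(frames = fl, dt = dt, stride = stride,
                 steps = (length(fl) - 1L) * stride, seed = NA,
                 integrator = "unknown", T_target = NA, system = sys,
                 epot = epot, ekin = ekin,
                 temperature = 2 * ekin / (ndof * ff_constants$k_B),
                 failed_step = NA_integer_),
            class = "md_trajectory")
}

#' Read a labeled dataset from extended XYZ
#'
#' Frames must carry `energy` fields and `forces` columns.
#' @param path input file.
#' @param units units of the stored labels.
#' @export
read_dataset_extxyz <- function(path, units = c("eV", "kcal/mol")) {
  units <- match.arg(units)
  frames <- read_extxyz(path)
  if (any(vapply(frames, function(f) is.null(f$energy) || is.null(f$forces),
                 logical(1))))
    stop("dataset frames must carry energy and forces")
  labeled_dataset(lapply(frames, `[[`, "system"),
                  vapply(frames, `[[`, numeric(1), "energy"),
                  lapply(frames, `[[`, "forces"), units = units)
}

# ---- checkpoints ----

.CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Versioned JSON container with the configuration and all parameter
#' arrays at full double precision; [load_checkpoint] reproduces the
#' model's energies bit for bit.
#'
#' @param model an [mlff_model].
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "euclidff-checkpoint",
    version = .CHECKPOINT_VERSION,
    config = unclass(model$config),
    params = unclass(model$params)
  )
  json <- jsonlite::serializeJSON(payload, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file produced by [save_checkpoint].
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(jsonlite::unserializeJSON(paste(readLines(path),
                                                      collapse = "\n")),
                      error = function(e)
                        stop("corrupted or unreadable checkpoint: ",
                             conditionMessage(e)))
  if (!identical(payload$format, "euclidff-checkpoint"))
    stop("not a model checkpoint: ", path)
  if (payload$version != .CHECKPOINT_VERSION)
    stop("checkpoint version ", payload$version,
         " needs migration; this build reads version ", .CHECKPOINT_VERSION)
  cfg <- payload$config
  class(cfg) <- "model_config"
  prm <- payload$params
  class(prm) <- "mlff_params"
  mlff_model(cfg, prm)
}

# ---- command-line interface ----

.cli_usage <- function() {
  paste(
    "usage: euclidff <task> [--key value ...]",
    "tasks:",
    "  relax     --xyz in.xyz --potential lj|double_well|--checkpoint m.json",
    "            [--fmax 1e-4] --out relaxed.xyz",
    "  md        --xyz in.xyz --potential ... [--integrator verlet|langevin|",
    "            nose_hoover] [--steps N] [--dt fs] [--stride N]",
    "            [--temperature K] [--seed N] --out traj.xyz",
    "  stability --traj traj.xyz --dt fs [--stride N] --temperature K",
    "            --out report.json",
    "  spectrum  --traj traj.xyz --dt fs [--stride N] --out spec.tsv",
    "  rog       --traj traj.xyz [--dt fs] --out rog.tsv",
    "  rdf       --traj traj.xyz [--dt fs] --rmax A [--bins N] --out rdf.tsv",
    "  minhop    --xyz in.xyz --potential ... [--max-minima N] [--trials N]",
    "            [--t0 K] [--ediff eV] [--seed N] --out-prefix run",
    "  train     --dataset data.xyz [--steps N] [--seed N] [--f F] [--t T]",
    "            --out model.json",
    "  eval      --dataset data.xyz --checkpoint model.json --out metrics.json",
    sep = "\n")
}

.cli_parse <- function(args) {
  opts <- list()
  k <- 1L
  while (k <= length(args)) {
    a <- args[k]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (k + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[k + 1L]
    k <- k + 2L
  }
  opts
}

.cli_potential <- function(opts, system) {
  if (!is.null(opts$checkpoint)) {
    model <- load_checkpoint(opts$checkpoint)
    return(model_potential(model, system))
  }
  spec <- opts$potential
  if (is.null(spec)) stop("a --potential or --checkpoint is required")
  if (spec == "lj") {
    base <- lj_potential(nrow(system$positions))
    return(make_potential(system, base$ef, label = base$label,
                          check_forces = FALSE))
  }
  if (spec == "double_well") {
    base <- double_well_molecule()
    return(make_potential(system, base$ef, label = base$label,
                          check_forces = FALSE))
  }
  stop("unknown potential: ", spec)
}

.opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see the usage text for the
#' subcommands. Returns an exit code (0 success, 2 usage error, 1 failure)
#' rather than calling `quit()`, so it is scriptable and testable.
#'
#' @param args character vector of command-line arguments.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    message(.cli_usage())
    return(if (length(args)) 0L else 2L)
  }
  task <- args[1]
  out <- tryCatch({
    opts <- .cli_parse(args[-1])
    switch(task,
      relax = {
        sys <- read_extxyz(opts$xyz)[[1]]$system
        pot <- .cli_potential(opts, sys)
        res <- relax(sys, pot, f_max = .opt_num(opts, "fmax", 1e-4))
        write_extxyz(list(list(system = res$system, energy = res$energy)),
                     opts$out)
        message("relaxed: E = ", res$energy, " eV, max|F| = ",
                res$f_max_final, " eV/A")
        0L
      },
      md = {
        sys <- read_extxyz(opts$xyz)[[1]]$system
        pot <- .cli_potential(opts, sys)
        traj <- run_md(sys, pot,
                       integrator = if (is.null(opts$integrator)) "verlet"
                                    else opts$integrator,
                       dt = .opt_num(opts, "dt", 0.5),
                       steps = .opt_num(opts, "steps", 1000),
                       stride = .opt_num(opts, "stride", 10),
                       seed = .opt_num(opts, "seed", 1),
                       T_target = .opt_num(opts, "temperature", 300))
        write_extxyz(traj, opts$out)
        message("wrote ", length(traj$frames), " frames to ", opts$out)
        0L
      },
      stability = {
        frames <- read_extxyz(opts$traj)
        traj <- trajectory_from_frames(frames, dt = .opt_num(opts, "dt", 0.5),
                                       stride = .opt_num(opts, "stride", 1))
        bonds <- detect_bonds(traj$system)
        rep <- check_stability(traj, bonds,
                               T_target = .opt_num(opts, "temperature", 300))
        write_stability_report(rep, opts$out)
        message("c_s = ", rep$c_s, " (", rep$failure_mode, ")")
        0L
      },
      spectrum = {
        frames <- read_extxyz(opts$traj)
        traj <- trajectory_from_frames(frames, dt = .opt_num(opts, "dt", 0.5),
                                       stride = .opt_num(opts, "stride", 1))
        spec <- vacf_spectrum(traj)
        write_table2(spec, opts$out)
        0L
      },
      rog = {
        frames <- read_extxyz(opts$traj)
        sys <- frames[[1]]$system
        vals <- vapply(frames, function(fr)
          radius_of_gyration(fr$system, masses = sys$masses), numeric(1))
        write_table2(data.frame(frame = seq_along(vals), rog = vals),
                     opts$out)
        0L
      },
      rdf = {
        frames <- read_extxyz(opts$traj)
        traj <- trajectory_from_frames(frames, dt = .opt_num(opts, "dt", 0.5))
        tab <- rdf(traj, r_max = .opt_num(opts, "rmax", 6),
                   n_bins = .opt_num(opts, "bins", 100))
        write_table2(tab, opts$out)
        0L
      },
      minhop = {
        sys <- read_extxyz(opts$xyz)[[1]]$system
        pot <- .cli_potential(opts, sys)
        hist <- minima_hop(sys, pot,
                           T0 = .opt_num(opts, "t0", 1000),
                           E_diff = .opt_num(opts, "ediff", 2),
                           max_minima = .opt_num(opts, "max-minima", 10),
                           max_trials = .opt_num(opts, "trials", 50),
                           escape_fs = .opt_num(opts, "escape-fs", 1000),
                           seed = .opt_num(opts, "seed", 1))
        prefix <- if (is.null(opts[["out-prefix"]])) "minhop" else opts[["out-prefix"]]
        write_extxyz(lapply(seq_along(hist$minima), function(k)
          list(system = hist$minima[[k]]$system,
               energy = hist$energies[k])), paste0(prefix, "_minima.xyz"))
        utils::write.table(
          data.frame(id = seq_along(hist$energies), energy = hist$energies,
                     visits = hist$visits, discovered = hist$discovered),
          paste0(prefix, "_index.tsv"), row.names = FALSE, quote = FALSE,
          sep = "\t")
        write_disconnectivity(disconnectivity(hist),
                              paste0(prefix, "_tree.txt"))
        message(length(hist$minima), " minima in ", hist$trials, " trials")
        0L
      },
      train = {
        ds <- read_dataset_extxyz(opts$dataset)
        cfg <- model_config(feature_dim = .opt_num(opts, "f", 32),
                            heads = .opt_num(opts, "heads", 4),
                            n_blocks = .opt_num(opts, "t", 2),
                            degrees = 1:2,
                            r_cut = .opt_num(opts, "rcut", 5))
        model <- mlff_model(cfg, seed = .opt_num(opts, "seed", 1))
        res <- train_mlff(model, ds, train_config(
          steps = .opt_num(opts, "steps", 2000),
          seed = .opt_num(opts, "seed", 1)))
        save_checkpoint(res$model, opts$out)
        message("best validation loss: ", res$best_val_loss)
        0L
      },
      eval = {
        ds <- read_dataset_extxyz(opts$dataset)
        model <- load_checkpoint(opts$checkpoint)
        met <- evaluate_mlff(model, ds)
        jsonlite::write_json(met[c("energy_mae", "force_mae",
                                   "force_norm_mae", "units")],
                             opts$out, auto_unbox = TRUE, digits = NA)
        message("energy MAE = ", met$energy_mae, " eV; force MAE = ",
                met$force_mae, " eV/A")
        0L
      },
      {
        message("unknown task: ", task, "\n", .cli_usage())
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  out
}
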