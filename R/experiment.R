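#' Define an experiment grid
#'
#' Every argument may be a vector; the grid is the Cartesian product of all
#' of them, one `fgm_config` per cell. Seeds are derived deterministically
#' from `(base_seed, cell, replicate)` with [derive_seed()], so any cell can
#' be re-run in isolation and reproduce its rows from a full-grid run.
#'
#' @param regime Regimes to run.
#' @param lag_load,omega,mean_size,mut_dist,f,kappa,r,pop_size1,pop_size2
#'   Scenario parameters (see [scenario_config()]).
#' @param n_iterations,burn_in,n_replicates Run lengths (scalar).
#' @param base_seed Integer base seed (scalar).
#' @param z_init Initial trait value (scalar).
#' @return A data.frame of class `fgm_grid`, one row per cell, with a
#'   `cell` index column.
#' @examples
#' g <- experiment_grid(regime = "conflict", f = c(1, 2, 4),
#'                      n_iterations = 100, n_replicates = 2)
#' nrow(g)
#' @export
experiment_grid <- function(regime = "conflict", lag_load = 0.2,
                            omega = 1/2, mean_size = 0.1,
                            mut_dist = "normal", f = 1, kappa = 1, r = 1,
                            pop_size1 = Inf, pop_size2 = Inf,
                            n_iterations = 5000L, burn_in = NULL,
                            n_replicates = 200L, base_seed = 1L,
                            z_init = 0) {
  stopifnot(length(n_iterations) == 1L, length(n_replicates) == 1L,
            length(base_seed) == 1L, length(z_init) == 1L)
  cells <- expand.grid(regime = regime, lag_load = lag_load, omega = omega,
                       mean_size = mean_size, mut_dist = mut_dist, f = f,
                       kappa = kappa, r = r, pop_size1 = pop_size1,
                       pop_size2 = pop_size2, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells$n_iterations <- as.integer(n_iterations)
  cells$burn_in <- if (is.null(burn_in)) NA_integer_ else as.integer(burn_in)
  cells$n_replicates <- as.integer(n_replicates)
  cells$base_seed <- as.integer(base_seed)
  cells$z_init <- z_init
  cells <- cbind(cell = seq_len(nrow(cells)), cells)
  # validate every cell up front so a bad grid fails in one pass
  for (i in seq_len(nrow(cells))) cell_config(cells[i, ])
  class(cells) <- c("fgm_grid", "data.frame")
  cells
}

# one grid row -> fgm_config
cell_config <- function(row) {
  validate_config(list(
    regime = row$regime, lag_load = row$lag_load, omega = row$omega,
    mean_size = row$mean_size, mut_dist = row$mut_dist, f = row$f,
    kappa = row$kappa, r = row$r, pop_size1 = row$pop_size1,
    pop_size2 = row$pop_size2, n_iterations = row$n_iterations,
    burn_in = if (is.na(row$burn_in)) NULL else row$burn_in,
    n_replicates = row$n_replicates, seed = row$base_seed,
    z_init = row$z_init))
}

param_cols <- c("regime", "lag_load", "omega", "mean_size", "mut_dist", "f",
                "kappa", "r", "pop_size1", "pop_size2", "n_replicates")

# result -> long rows tagged with the cell's parameters
cell_summary_rows <- function(row, res) {
  agg <- res$aggregate
  if (!is.null(res$power_aggregate)) {
    pa <- res$power_aggregate
    pa$party <- NA_integer_
    agg <- rbind(agg, pa[, names(agg)])
  }
  cbind(row[rep(1L, nrow(agg)), c("cell", param_cols)], agg,
        row.names = NULL)
}

#' Run an experiment grid and write its outputs
#'
#' Executes every cell of the grid, writing per-cell aggregated summaries,
#' the first replicate's event log per cell, a combined long-format summary
#' table, and a plain-text manifest capturing the full configuration, the
#' seed-derivation rule and the package version. Re-running with the same
#' grid reproduces byte-identical outputs.
#'
#' @param grid An [experiment_grid()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit per-cell progress messages.
#' @return The combined long-format summary data.frame, invisibly.
#' @export
run_experiment <- function(grid, out_dir, verbose = TRUE) {
  stopifnot(inherits(grid, "fgm_grid"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  all_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    cfg <- cell_config(row)
    t0 <- Sys.time()
    res <- run_scenario(cfg, cell = row$cell, keep_first_log = TRUE)
    rows <- cell_summary_rows(row, res)
    all_rows[[i]] <- rows
    write_tsv(rows, file.path(out_dir, sprintf("cell-%03d-summary.tsv",
                                               row$cell)))
    write_event_log(res$first_log,
                    file.path(out_dir, sprintf("cell-%03d-events-rep1.tsv",
                                               row$cell)))
    if (verbose)
      message(sprintf("[cell %d/%d] %s done in %.1fs", i, nrow(grid),
                      cfg$regime,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  combined <- do.call(rbind, all_rows)
  write_tsv(combined, file.path(out_dir, "summary.tsv"))
  write_manifest(grid, out_dir)
  invisible(combined)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 15)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(grid, out_dir) {
  path <- file.path(out_dir, "manifest.txt")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "fgmconflict run manifest",
    paste0("package_version = ", as.character(packageVersion("fgmconflict"))),
    "seed_rule = derive_seed(base_seed, cell, replicate)",
    paste0("n_cells = ", nrow(grid)),
    ""), con)
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    fields <- vapply(names(row), function(k) {
      sprintf("%s=%s", k, format(row[[k]], digits = 17))
    }, character(1))
    writeLines(paste0("cell ", row$cell, ": ",
                      paste(fields, collapse = " ")), con)
  }
  invisible(path)
}

preset_names <- c("trajectories", "equilibrium-surface", "power-selection",
                  "power-input", "power-mutsize")

#' Run a named reduced-scale experiment preset
#'
#' Presets reproduce the package's headline experiments at desk scale
#' (200 replicates by default):
#' * `trajectories`: per-iteration mean fitness for the standard walk, a
#'   conflict walk started at the origin, a conflict walk started at party
#'   1's optimum, and the paired abiotic control, at baseline parameters;
#' * `equilibrium-surface`: equilibrium summaries for all three regimes on
#'   a lag-load x mutation-size grid;
#' * `power-selection`: fitness power across relative selection strengths
#'   `f` in 1..8;
#' * `power-input`: fitness power across mutational-input ratios `r`;
#' * `power-mutsize`: fitness power across relative mutation sizes `kappa`.
#'
#' @param name Preset name (see above).
#' @param out_dir Output directory.
#' @param replicates Replicates per condition.
#' @param iterations Equilibrium-window length (trajectories: total length;
#'   `NULL` = preset default).
#' @param seed Base seed.
#' @param mut_dist Mutation-effect distribution.
#' @param verbose Emit progress messages.
#' @return The preset's main table (trajectory table or combined summary),
#'   invisibly.
#' @export
run_preset <- function(name, out_dir, replicates = 200L, iterations = NULL,
                       seed = 1L, mut_dist = "normal", verbose = TRUE) {
  name <- match.arg(name, preset_names)
  if (name == "trajectories") {
    return(invisible(preset_trajectories(out_dir, replicates,
                                         iterations %||% 1500L, seed,
                                         mut_dist, verbose)))
  }
  iters <- iterations %||% 5000L
  grid <- switch(name,
    "equilibrium-surface" = experiment_grid(
      regime = c("standard", "conflict", "abiotic_matched"),
      lag_load = c(0.05, 0.2, 0.4), mean_size = c(0.02, 0.1, 0.3),
      mut_dist = mut_dist, n_iterations = iters, n_replicates = replicates,
      base_seed = seed),
    "power-selection" = experiment_grid(
      regime = "conflict", f = c(1, 2, 4, 8), mut_dist = mut_dist,
      n_iterations = iters, n_replicates = replicates, base_seed = seed),
    "power-input" = experiment_grid(
      regime = "conflict", r = c(1, 2, 4, 8), mut_dist = mut_dist,
      n_iterations = iters, n_replicates = replicates, base_seed = seed),
    "power-mutsize" = experiment_grid(
      regime = "conflict", kappa = c(0.25, 0.5, 1, 2, 4),
      mut_dist = mut_dist, n_iterations = iters, n_replicates = replicates,
      base_seed = seed)
  )
  invisible(run_experiment(grid, out_dir, verbose = verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean-fitness trajectories for standard / conflict (two starts) / abiotic
preset_trajectories <- function(out_dir, replicates, iterations, seed,
                                mut_dist, verbose) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- list(lag_load = 0.2, omega = 1/2, mean_size = 0.1,
               mut_dist = mut_dist, n_iterations = iterations, burn_in = 0L,
               n_replicates = replicates, seed = seed)
  o1 <- optimum_from_lagload(0.8, 1/2, +1)
  variants <- list(
    standard = c(base, list(regime = "standard", z_init = 0)),
    conflict_origin = c(base, list(regime = "conflict", z_init = 0)),
    conflict_optimum = c(base, list(regime = "conflict", z_init = o1)),
    abiotic = c(base, list(regime = "abiotic_matched", z_init = 0))
  )
  out <- list()
  for (vi in seq_along(variants)) {
    cfg <- validate_config(variants[[vi]])
    acc <- numeric(iterations)
    for (rep in seq_len(replicates)) {
      set.seed(derive_seed(seed, vi, rep))
      log <- switch(cfg$regime,
        standard = run_standard(cfg),
        conflict = run_conflict(cfg),
        abiotic_matched = run_abiotic_matched(run_conflict(cfg), cfg))
      last <- log[!duplicated(log$iteration, fromLast = TRUE), ]
      acc <- acc + last$w1_after
    }
    out[[vi]] <- data.frame(variant = names(variants)[vi],
                            iteration = seq_len(iterations),
                            mean_fitness = acc / replicates)
    if (verbose)
      message(sprintf("[trajectories] %s done", names(variants)[vi]))
  }
  traj <- do.call(rbind, out)
  write_tsv(traj, file.path(out_dir, "trajectories.tsv"))
  traj
}
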