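#' Build a simulation scenario
#'
#' Bundles everything needed to run one simulation condition: the regime, the
#' conflict geometry, the two parties' asymmetry parameters, and run lengths.
#' Defaults are the baseline condition used throughout: shape
#' \eqn{\omega = 1/2}, lag load 0.2, mean mutation size 0.1, infinite
#' populations, fully symmetric parties.
#'
#' Asymmetries follow the convention that party 1 is the (potentially)
#' advantaged side: `f` multiplies party 1's selection strength
#' (\eqn{\omega_1 = f \omega_2}, with `omega` giving the baseline
#' \eqn{\omega_2}),
#' `kappa` multiplies party 1's mean mutation size
#' (\eqn{\bar m_1 = \kappa \bar m_2}, with `mean_size` giving
#' \eqn{\bar m_2}), and `r` gives party 1 `r` mutation proposals per
#' iteration against party 2's one.
#'
#' @param regime One of `"standard"` (single party, fixed optimum),
#'   `"conflict"` (two parties, joint phenotype) or `"abiotic_matched"`
#'   (single party whose optimum moves by the magnitudes of the opponent's
#'   changes in a paired conflict run).
#' @param lag_load Shared lag load \eqn{1 - w_0} at the fitness-curve
#'   intersection, in (0, 1); the conflict intensity.
#' @param omega Baseline fitness-curve shape: party 2's \eqn{\omega_2}
#'   (party 1's is \eqn{\omega_1 = f\,\omega_2}; both equal `omega` in the
#'   symmetric case f = 1).
#' @param mean_size Party 2's mean absolute mutation size \eqn{\bar m_2}
#'   (party 1's equals `kappa * mean_size`).
#' @param mut_dist Mutation-effect distribution for both parties.
#' @param f Relative selection strength, \eqn{\omega_1 = f\omega_2}.
#' @param kappa Relative mutation size, \eqn{\bar m_1 = \kappa \bar m_2}.
#' @param r Relative mutational input (positive integer).
#' @param pop_size1,pop_size2 Population sizes (`Inf` = drift-free).
#' @param n_iterations Length of the post-burn-in equilibrium window.
#' @param burn_in Iterations discarded as the initial adaptation period;
#'   default `ceiling(250 / min(omega1, omega2))`.
#' @param n_replicates Number of replicate walks.
#' @param seed Base random seed; per-replicate seeds are derived with
#'   [derive_seed()].
#' @param z_init Initial joint-trait value (0 = the origin where the fitness
#'   curves intersect; set to party 1's optimum to start adapted).
#' @return An object of class `fgm_config`.
#' @examples
#' cfg <- scenario_config("conflict", n_iterations = 200, n_replicates = 3)
#' cfg
#' @export
scenario_config <- function(regime = c("standard", "conflict",
                                       "abiotic_matched"),
                            lag_load = 0.2, omega = 1/2, mean_size = 0.1,
                            mut_dist = "normal", f = 1, kappa = 1, r = 1L,
                            pop_size1 = Inf, pop_size2 = Inf,
                            n_iterations = 5000L, burn_in = NULL,
                            n_replicates = 200L, seed = 1L, z_init = 0) {
  regime <- match.arg(regime)
  validate_config(list(
    regime = regime, lag_load = lag_load, omega = omega,
    mean_size = mean_size, mut_dist = mut_dist, f = f, kappa = kappa, r = r,
    pop_size1 = pop_size1, pop_size2 = pop_size2,
    n_iterations = n_iterations, burn_in = burn_in,
    n_replicates = n_replicates, seed = seed, z_init = z_init))
}

#' Validate a raw configuration, collecting all problems at once
#'
#' Range-checks every field of a raw (list) configuration, fills defaults
#' for missing fields, and either returns a complete `fgm_config` or raises
#' one error naming every offending field, so that all of a configuration
#' file's problems surface in a single pass.
#'
#' @param raw A named list of configuration values (any subset of the
#'   arguments of [scenario_config()]).
#' @return An `fgm_config` object, or an error listing every violation.
#' @examples
#' cfg <- validate_config(list(regime = "standard", n_replicates = 5))
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) stop("`raw` must be a list", call. = FALSE)
  defaults <- list(regime = "standard", lag_load = 0.2, omega = 1/2,
                   mean_size = 0.1, mut_dist = "normal", f = 1, kappa = 1,
                   r = 1L, pop_size1 = Inf, pop_size2 = Inf,
                   n_iterations = 5000L, burn_in = NULL,
                   n_replicates = 200L, seed = 1L, z_init = 0)
  unknown <- setdiff(names(raw), names(defaults))
  cfg <- modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(is.character(cfg$regime) &&
        cfg$regime %in% c("standard", "conflict", "abiotic_matched"),
      "regime: must be one of standard, conflict, abiotic_matched")
  chk(num1(cfg$lag_load) && cfg$lag_load > 0 && cfg$lag_load < 1,
      "lag_load: must be in (0, 1)")
  chk(num1(cfg$omega) && cfg$omega > 0, "omega: must be positive")
  chk(num1(cfg$mean_size) && cfg$mean_size > 0, "mean_size: must be positive")
  chk(is.character(cfg$mut_dist) &&
        cfg$mut_dist %in% c("normal", "uniform", "exponential"),
      "mut_dist: must be normal, uniform or exponential")
  chk(num1(cfg$f) && cfg$f > 0, "f: must be positive")
  chk(num1(cfg$kappa) && cfg$kappa > 0, "kappa: must be positive")
  chk(num1(cfg$r) && cfg$r >= 1 && cfg$r == round(cfg$r),
      "r: mutational-input multiplier must be a positive integer")
  for (fld in c("pop_size1", "pop_size2")) {
    v <- cfg[[fld]]
    chk(is.numeric(v) && length(v) == 1L && !is.na(v) &&
          (is.infinite(v) || (v >= 2 && v == round(v))),
        paste0(fld, ": must be Inf or an integer >= 2"))
  }
  chk(num1(cfg$n_iterations) && cfg$n_iterations >= 0 &&
        cfg$n_iterations == round(cfg$n_iterations),
      "n_iterations: must be a nonnegative integer")
  if (!is.null(cfg$burn_in))
    chk(num1(cfg$burn_in) && cfg$burn_in >= 0 &&
          cfg$burn_in == round(cfg$burn_in),
        "burn_in: must be a nonnegative integer")
  chk(num1(cfg$n_replicates) && cfg$n_replicates >= 1 &&
        cfg$n_replicates == round(cfg$n_replicates),
      "n_replicates: must be a positive integer")
  chk(num1(cfg$seed) && cfg$seed == round(cfg$seed), "seed: must be an integer")
  chk(num1(cfg$z_init), "z_init: must be a finite number")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(cfg$burn_in)) {
    # the slower-adapting (wider-curve) party sets the adaptation timescale
    omega1 <- cfg$omega * cfg$f
    cfg$burn_in <- as.integer(ceiling(250 / min(omega1, cfg$omega)))
  }
  cfg$r <- as.integer(cfg$r)
  cfg$n_iterations <- as.integer(cfg$n_iterations)
  cfg$burn_in <- as.integer(cfg$burn_in)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "fgm_config")
}

#' @export
print.fgm_config <- function(x, ...) {
  cat(sprintf("<fgm_config> regime = %s\n", x$regime))
  cat(sprintf("  lag load %.3g (w0 = %.3g), omega = %.3g, mean size %.3g (%s)\n",
              x$lag_load, 1 - x$lag_load, x$omega, x$mean_size, x$mut_dist))
  cat(sprintf("  asymmetry: f = %.3g, kappa = %.3g, r = %d; N = (%s, %s)\n",
              x$f, x$kappa, x$r,
              if (is.finite(x$pop_size1)) format(x$pop_size1) else "Inf",
              if (is.finite(x$pop_size2)) format(x$pop_size2) else "Inf"))
  cat(sprintf("  %d burn-in + %d window iterations x %d replicates, seed %d, z_init %.3g\n",
              x$burn_in, x$n_iterations, x$n_replicates, x$seed, x$z_init))
  invisible(x)
}

#' Parties implied by a scenario configuration
#'
#' Expands a configuration into concrete [party()] objects: party 1 with the
#' positive optimum and the `f`, `kappa`, `r` advantages; party 2 with the
#' negative optimum. Both optima are placed so that the two fitness curves
#' intersect at the origin with the configured shared lag load.
#'
#' @param config An `fgm_config`.
#' @return A list with elements `party1` and `party2` (`party2` is `NULL`
#'   only conceptually for single-party regimes: it is always constructed,
#'   since the abiotic control is paired to a conflict run).
#' @export
build_parties <- function(config) {
  stopifnot(inherits(config, "fgm_config"))
  w0 <- 1 - config$lag_load
  omega1 <- config$omega * config$f
  omega2 <- config$omega
  p1 <- party(omega = omega1,
              optimum = optimum_from_lagload(w0, omega1, +1),
              mean_size = config$kappa * config$mean_size,
              pop_size = config$pop_size1, mut_input = config$r,
              mut_dist = config$mut_dist, index = 1L)
  p2 <- party(omega = omega2,
              optimum = optimum_from_lagload(w0, omega2, -1),
              mean_size = config$mean_size,
              pop_size = config$pop_size2, mut_input = 1L,
              mut_dist = config$mut_dist, index = 2L)
  list(party1 = p1, party2 = p2)
}

#' Deterministically derive a replicate seed
#'
#' A pure function of (base seed, cell index, replicate index) built from
#' three multiplicative-congruential steps modulo \eqn{2^{31} - 1}, so any
#' grid cell or replicate can be re-run in isolation and reproduce the rows
#' of a full-grid run.
#'
#' @param base_seed Integer base seed.
#' @param cell Nonnegative cell index (1 for standalone scenarios).
#' @param replicate Replicate index.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @examples
#' derive_seed(1, 1, 1)
#' @export
derive_seed <- function(base_seed, cell, replicate) {
  m <- 2147483647 # 2^31 - 1
  h <- abs(as.double(base_seed)) %% m
  step <- function(h, k) ((h + k) %% m * 48271) %% m
  h <- step(h, 0)
  h <- step(h, as.double(cell))
  h <- step(h, as.double(replicate))
  as.integer(h %% (m - 1) + 1)
}
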