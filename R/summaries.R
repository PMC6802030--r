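#' Equilibrium summary statistics over a window of an event log
#'
#' Computes, per party, the statistics used to characterize equilibrium:
#' mean distance to the optimum, mean fitness, fixation fraction, mean size
#' of fixed mutations, and mean lag load. The state (distance, fitness) is
#' sampled once per iteration, at the end of the iteration, so regimes with
#' different numbers of proposal rounds per iteration are sampled
#' comparably. Fixation statistics use each party's own proposals within
#' the window; the mean fixation size is `NA` (missing, not zero) when that
#' party fixed nothing in the window.
#'
#' @param log An `fgm_log` event log.
#' @param burn_in Iterations to discard from the start (defaults to the
#'   log's configuration).
#' @param window Number of equilibrium iterations to summarize (defaults to
#'   the log's configuration); statistics cover iterations
#'   `(burn_in, burn_in + window]`.
#' @return A data.frame with one row per party present in the log:
#'   `party`, `mean_distance`, `mean_fitness`, `fixation_fraction`,
#'   `mean_fixation_size`, `mean_lag_load`, `n_proposals`, `n_fixed`.
#' @examples
#' cfg <- scenario_config("conflict", n_iterations = 100, burn_in = 50)
#' set.seed(1)
#' summarize_window(run_conflict(cfg))
#' @export
summarize_window <- function(log, burn_in = NULL, window = NULL) {
  stopifnot(inherits(log, "fgm_log"))
  config <- attr(log, "config")
  parties <- attr(log, "parties")
  if (is.null(burn_in)) burn_in <- config$burn_in
  if (is.null(window)) window <- config$n_iterations
  n_iter <- max(log$iteration)
  if (burn_in + window > n_iter)
    stop(sprintf("window [%d, %d] exceeds log length %d",
                 burn_in + 1L, burn_in + window, n_iter), call. = FALSE)
  in_win <- log$iteration > burn_in & log$iteration <= burn_in + window
  win <- log[in_win, , drop = FALSE]
  # end-of-iteration state: last record of each iteration in the window
  last <- win[!duplicated(win$iteration, fromLast = TRUE), , drop = FALSE]
  present <- sort(unique(win$party))
  out <- do.call(rbind, lapply(present, function(i) {
    p <- if (i == 1L) parties$party1 else parties$party2
    o_i <- if (i == 1L) last$o1_after else p$optimum
    w_i <- if (i == 1L) last$w1_after else last$w2_after
    mine <- win[win$party == i, , drop = FALSE]
    n_fixed <- sum(mine$fixed)
    data.frame(
      party = i,
      mean_distance = mean(abs(last$z_after - o_i)),
      mean_fitness = mean(w_i),
      fixation_fraction = n_fixed / nrow(mine),
      mean_fixation_size = if (n_fixed > 0) mean(abs(mine$effect[mine$fixed]))
                           else NA_real_,
      mean_lag_load = 1 - mean(w_i),
      n_proposals = nrow(mine),
      n_fixed = n_fixed
    )
  }))
  rownames(out) <- NULL
  out
}

#' Fitness power of party 1
#'
#' \eqn{P_{w1} = 1 - L_1 / (L_1 + L_2)}, where \eqn{L_i} is party i's mean
#' lag load over the equilibrium window. Power ranges from 0 to 1: values
#' above 0.5 mean party 1 is winning (holding the joint trait nearer its
#' own optimum), 0.5 means equal lag loads, below 0.5 party 2 is winning.
#'
#' @param summaries A per-party summary data.frame from
#'   [summarize_window()] containing both parties over the same window.
#' @return A list with `power_party1`, `mean_L1`, `mean_L2`. Power is `NA`
#'   when both lag loads are zero (both parties at maximal fitness).
#' @examples
#' s <- data.frame(party = 1:2, mean_lag_load = c(0.1, 0.3))
#' fitness_power(s)$power_party1 # 0.75
#' @export
fitness_power <- function(summaries) {
  stopifnot(is.data.frame(summaries), all(c(1, 2) %in% summaries$party))
  L1 <- summaries$mean_lag_load[summaries$party == 1][1]
  L2 <- summaries$mean_lag_load[summaries$party == 2][1]
  p <- if (L1 + L2 == 0) NA_real_ else 1 - L1 / (L1 + L2)
  list(power_party1 = p, mean_L1 = L1, mean_L2 = L2)
}

#' Aggregate per-replicate summaries into means and standard errors
#'
#' @param per_replicate A data.frame of per-replicate values with a
#'   `replicate` column, an optional `party` column, and one column per
#'   statistic. Missing values (for example a replicate with no fixations)
#'   are dropped per statistic, with the contributing count recorded.
#' @return A long data.frame: `party` (if present), `statistic`, `mean`,
#'   `se`, `n`. `se` is `NA` for a single contributing replicate.
#' @examples
#' pr <- data.frame(replicate = 1:3, party = 1, mean_fitness = c(.9, .8, .85))
#' aggregate_replicates(pr)
#' @export
aggregate_replicates <- function(per_replicate) {
  stopifnot(is.data.frame(per_replicate), nrow(per_replicate) >= 1)
  stat_cols <- setdiff(names(per_replicate), c("replicate", "party"))
  groups <- if ("party" %in% names(per_replicate)) {
    split(per_replicate, per_replicate$party)
  } else {
    list(per_replicate)
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(stat_cols, function(col) {
      x <- g[[col]][!is.na(g[[col]])]
      n <- length(x)
      data.frame(
        party = if ("party" %in% names(g)) g$party[1] else NA_integer_,
        statistic = col,
        mean = if (n > 0) mean(x) else NA_real_,
        se = if (n > 1) sd(x) / sqrt(n) else NA_real_,
        n = n
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Run a scenario: replicates, summaries, power
#'
#' Executes `n_replicates` independent walks of the configured scenario,
#' each seeded with [derive_seed()], summarizes each over the equilibrium
#' window, and aggregates across replicates. For the conflict regime,
#' fitness power is computed per replicate from that replicate's mean lag
#' loads and then averaged across replicates. For the abiotic regime each
#' replicate first runs its paired conflict walk (same parameters and
#' replicate stream), extracts party 2's per-iteration displacement
#' magnitudes, and then runs the moving-optimum walk; the paired conflict
#' summaries are returned alongside.
#'
#' @param config An `fgm_config`.
#' @param cell Cell index used in seed derivation (1 for standalone runs).
#' @param keep_first_log If `TRUE`, the first replicate's event log is kept
#'   in the result (for inspection or serialization).
#' @return An `fgm_result`: list with `config`, `per_replicate`,
#'   `aggregate`, and for two-party scenarios `power` (per replicate),
#'   `power_aggregate`, and for the abiotic regime `paired_conflict` (the
#'   corresponding conflict-result object).
#' @examples
#' cfg <- scenario_config("standard", n_iterations = 200, burn_in = 100,
#'                        n_replicates = 5)
#' res <- run_scenario(cfg)
#' res$aggregate
#' @export
run_scenario <- function(config, cell = 1L, keep_first_log = FALSE) {
  stopifnot(inherits(config, "fgm_config"))
  reps <- seq_len(config$n_replicates)
  per <- vector("list", length(reps))
  per_paired <- vector("list", length(reps))
  pow <- vector("list", length(reps))
  pow_paired <- vector("list", length(reps))
  first_log <- NULL
  for (rep in reps) {
    set.seed(derive_seed(config$seed, cell, rep))
    if (config$regime == "standard") {
      log <- run_standard(config)
      s <- summarize_window(log)
    } else if (config$regime == "conflict") {
      log <- run_conflict(config)
      s <- summarize_window(log)
      pw <- fitness_power(s)
      pow[[rep]] <- data.frame(replicate = rep,
                               power_party1 = pw$power_party1,
                               mean_L1 = pw$mean_L1, mean_L2 = pw$mean_L2)
    } else { # abiotic_matched: paired conflict first, then moving optimum
      clog <- run_conflict(config)
      cs <- summarize_window(clog)
      cpw <- fitness_power(cs)
      per_paired[[rep]] <- cbind(replicate = rep, cs)
      pow_paired[[rep]] <- data.frame(replicate = rep,
                                      power_party1 = cpw$power_party1,
                                      mean_L1 = cpw$mean_L1,
                                      mean_L2 = cpw$mean_L2)
      log <- run_abiotic_matched(clog, config)
      s <- summarize_window(log)
    }
    per[[rep]] <- cbind(replicate = rep, s)
    if (keep_first_log && rep == 1L) first_log <- log
  }
  per <- do.call(rbind, per)
  drop_cols <- c("n_proposals", "n_fixed")
  res <- list(
    config = config,
    per_replicate = per,
    aggregate = aggregate_replicates(per[, setdiff(names(per), drop_cols)]),
    first_log = first_log
  )
  if (config$regime == "conflict") {
    res$power <- do.call(rbind, pow)
    res$power_aggregate <- aggregate_replicates(
      res$power[, c("replicate", "power_party1", "mean_L1", "mean_L2")])
  }
  if (config$regime == "abiotic_matched") {
    paired_per <- do.call(rbind, per_paired)
    paired_pow <- do.call(rbind, pow_paired)
    res$paired_conflict <- list(
      per_replicate = paired_per,
      aggregate = aggregate_replicates(
        paired_per[, setdiff(names(paired_per), drop_cols)]),
      power = paired_pow,
      power_aggregate = aggregate_replicates(paired_pow)
    )
  }
  class(res) <- "fgm_result"
  res
}

#' @export
print.fgm_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fgm_result> %s regime, %d replicates x (%d + %d) iterations\n",
              cfg$regime, cfg$n_replicates, cfg$burn_in, cfg$n_iterations))
  agg <- x$aggregate
  p1 <- agg[agg$party == 1 &
              agg$statistic %in% c("mean_distance", "mean_fitness",
                                   "fixation_fraction", "mean_fixation_size"), ]
  for (i in seq_len(nrow(p1))) {
    cat(sprintf("  party 1 %-20s %8.4f (se %.4f, n %d)\n",
                p1$statistic[i], p1$mean[i], p1$se[i], p1$n[i]))
  }
  if (!is.null(x$power_aggregate)) {
    pa <- x$power_aggregate
    row <- pa[pa$statistic == "power_party1", ]
    cat(sprintf("  fitness power (party 1): %.4f (se %.4f)\n",
                row$mean, row$se))
  }
  invisible(x)
}
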