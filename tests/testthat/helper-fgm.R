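# shared helpers for the fgmconflict test suite

# pull one aggregated statistic (mean, se, n) from an fgm_result aggregate
agg_stat <- function(agg, stat, party = 1L) {
  row <- agg[agg$statistic == stat &
               (is.na(party) | agg$party %in% party), ][1, ]
  c(mean = row$mean, se = row$se, n = row$n)
}

power_of <- function(res) {
  pa <- res$power_aggregate
  c(mean = pa$mean[pa$statistic == "power_party1"],
    se = pa$se[pa$statistic == "power_party1"])
}

# small scenario for fast structural tests
quick_cfg <- function(regime = "conflict", n_iterations = 50L, burn_in = 0L,
                      n_replicates = 2L, r = 1L, ...) {
  scenario_config(regime, n_iterations = n_iterations, burn_in = burn_in,
                  n_replicates = n_replicates, r = r, ...)
}

# hand-assembled single-party event log with known content (party optimum 1,
# omega 1/2 => lag_load = 1 - exp(-0.5))
hand_log <- function() {
  cfg <- scenario_config("standard", lag_load = 1 - exp(-0.5), omega = 0.5,
                         n_iterations = 2L, burn_in = 1L, n_replicates = 1L)
  parties <- build_parties(cfg)
  stopifnot(abs(parties$party1$optimum - 1) < 1e-12)
  df <- data.frame(
    iteration = 1:3,
    party = 1L,
    effect = c(0.5, 0.3, -0.1),
    s = NA_real_,
    fixed = c(TRUE, TRUE, FALSE),
    z_after = c(0.5, 0.8, 0.8),
    o1_after = 1,
    w1_after = exp(-0.5 * (1 - c(0.5, 0.8, 0.8))^2),
    w2_after = NA_real_
  )
  attr(df, "config") <- cfg
  attr(df, "parties") <- parties
  attr(df, "o1_init") <- 1
  class(df) <- c("fgm_log", "data.frame")
  df
}
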