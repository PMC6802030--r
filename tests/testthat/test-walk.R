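test_that("C++ and pure-R engines produce bit-identical walks", {
  for (dist in c("normal", "uniform", "exponential")) {
    cfg_s <- quick_cfg("standard", mut_dist = dist)
    set.seed(42)
    a <- run_standard(cfg_s, engine = "cpp")
    set.seed(42)
    b <- run_standard(cfg_s, engine = "r")
    expect_equal(as.data.frame(a), as.data.frame(b))

    cfg_c <- quick_cfg("conflict", mut_dist = dist, r = 2L, f = 2,
                       kappa = 0.5, pop_size2 = 100)
    set.seed(43)
    a <- run_conflict(cfg_c, engine = "cpp")
    set.seed(43)
    b <- run_conflict(cfg_c, engine = "r")
    expect_equal(as.data.frame(a), as.data.frame(b))

    cfg_a <- quick_cfg("abiotic_matched", mut_dist = dist, r = 2L)
    set.seed(44)
    pc <- run_conflict(cfg_a, engine = "cpp")
    aa <- run_abiotic_matched(pc, cfg_a, engine = "cpp")
    set.seed(44)
    pr <- run_conflict(cfg_a, engine = "r")
    ab <- run_abiotic_matched(pr, cfg_a, engine = "r")
    expect_equal(as.data.frame(aa), as.data.frame(ab))
  }
})

test_that("summing fixed effects replays the final trait value exactly", {
  cfg <- quick_cfg("conflict", n_iterations = 300L, z_init = 0.25)
  set.seed(7)
  log <- run_conflict(cfg)
  # accumulate in event order, as the walk itself does
  replayed <- Reduce(`+`, log$effect[log$fixed], accumulate = FALSE,
                     init = 0.25)
  expect_identical(replayed, log$z_after[nrow(log)])
  # unfixed proposals leave z untouched
  z_before <- c(0.25, log$z_after[-nrow(log)])
  expect_identical(log$z_after[!log$fixed], z_before[!log$fixed])
  expect_equal(log$z_after[log$fixed] - z_before[log$fixed],
               log$effect[log$fixed])
})

test_that("identical configurations and seeds give identical event logs", {
  cfg <- quick_cfg("conflict", n_iterations = 100L, r = 3L)
  set.seed(123)
  a <- run_conflict(cfg)
  set.seed(123)
  b <- run_conflict(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("zero iterations yield an empty log", {
  cfg <- quick_cfg("standard", n_iterations = 0L, n_replicates = 1L)
  set.seed(1)
  log <- run_standard(cfg)
  expect_identical(nrow(log), 0L)
})

test_that("a walk started at the optimum fixes nothing under infinite N", {
  o1 <- optimum_from_lagload(0.8, 0.5, +1)
  cfg <- scenario_config("standard", n_iterations = 2000L, burn_in = 0L,
                         z_init = o1)
  set.seed(9)
  log <- run_standard(cfg)
  expect_identical(sum(log$fixed), 0L)
  expect_true(all(log$z_after == o1))
  expect_true(all(log$s <= 0))
})

test_that("conflict iterations hold (r+1) rounds with a contiguous party-1 block", {
  cfg <- quick_cfg("conflict", n_iterations = 200L, r = 3L)
  set.seed(5)
  log <- run_conflict(cfg)
  expect_identical(nrow(log), 200L * 4L)
  by_iter <- split(log$party, log$iteration)
  pats <- vapply(by_iter, paste, character(1), collapse = "")
  expect_true(all(pats %in% c("1112", "2111")))
  expect_true(all(c("1112", "2111") %in% pats)) # the coin picks both orders
})

test_that("a conflict against a mutationally inert party reduces to standard adaptation", {
  # party 2's mutations are ~1e-12: it never fixes, and party 1 should walk
  # to its optimum and stay, as in the standard model
  n_rep <- 30L
  cfg_c <- scenario_config("conflict", mean_size = 1e-12, kappa = 1e11,
                           n_iterations = 1000L, burn_in = 500L,
                           n_replicates = n_rep, seed = 21L)
  cfg_s <- scenario_config("standard", mean_size = 0.1,
                           n_iterations = 1000L, burn_in = 500L,
                           n_replicates = n_rep, seed = 22L)
  res_c <- run_scenario(cfg_c)
  res_s <- run_scenario(cfg_s)
  fit_c <- agg_stat(res_c$aggregate, "mean_fitness", 1L)
  fit_s <- agg_stat(res_s$aggregate, "mean_fitness", 1L)
  se <- sqrt(fit_c["se"]^2 + fit_s["se"]^2)
  expect_lt(abs(fit_c["mean"] - fit_s["mean"]), 4 * se + 1e-4)
  expect_gt(fit_c["mean"], 0.99)
})

test_that("abiotic optimum displacements conserve the paired magnitudes exactly", {
  cfg <- quick_cfg("abiotic_matched", n_iterations = 400L,
                   n_replicates = 1L)
  set.seed(31)
  clog <- run_conflict(cfg)
  alog <- run_abiotic_matched(clog, cfg)
  delta <- party2_displacements(clog)
  o_series <- alog$o1_after[!duplicated(alog$iteration)]
  o_prev <- c(attr(alog, "o1_init"), o_series[-length(o_series)])
  expect_equal(abs(o_series - o_prev), delta)
})

test_that("an abiotic run paired to a fixation-free opponent equals the standard walk", {
  # conflict in which party 2 (sigma ~ 1e-12) never fixes -> all
  # displacements zero -> the abiotic walk consumes the stream exactly as
  # the standard walk does
  cfg_a <- scenario_config("abiotic_matched", mean_size = 1e-12,
                           kappa = 1e11, n_iterations = 500L, burn_in = 0L)
  set.seed(61)
  clog <- run_conflict(cfg_a)
  expect_identical(sum(clog$fixed[clog$party == 2L]), 0L)
  expect_true(all(party2_displacements(clog) == 0))
  set.seed(77)
  alog <- run_abiotic_matched(clog, cfg_a)
  cfg_s <- scenario_config("standard", mean_size = 0.1,
                           n_iterations = 500L, burn_in = 0L)
  set.seed(77)
  slog <- run_standard(cfg_s)
  expect_true(all(alog$o1_after == attr(alog, "o1_init")))
  for (col in c("effect", "s", "fixed", "z_after", "w1_after")) {
    expect_identical(alog[[col]], slog[[col]])
  }
})

test_that("paired logs of the wrong length are rejected", {
  cfg <- quick_cfg("abiotic_matched", n_iterations = 50L)
  set.seed(1)
  clog <- run_conflict(cfg)
  cfg_long <- quick_cfg("abiotic_matched", n_iterations = 60L)
  expect_error(run_abiotic_matched(clog, cfg_long), "50 iterations")
})

test_that("single proposals resolve consistently with the closed-form pieces", {
  p <- party(omega = 0.5, optimum = optimum_from_lagload(0.8, 0.5, +1),
             mean_size = 0.1)
  set.seed(12)
  st <- walk_state(0)
  for (i in 1:50) {
    out <- propose_and_resolve(st, p)
    ev <- out$event
    # selection coefficient recomputes from the fitness ratio
    expect_equal(ev$s, fitness(st$z + ev$effect, p) / fitness(st$z, p) - 1)
    if (ev$fixed) {
      expect_identical(ev$z_after, st$z + ev$effect)
      expect_gt(ev$s, 0) # infinite N: only beneficial mutations fix
    } else {
      expect_identical(ev$z_after, st$z)
    }
    st <- out$state
  }
  # from the optimum every mutation is deleterious and none fix
  at_opt <- walk_state(p$optimum)
  for (i in 1:25) {
    ev <- propose_and_resolve(at_opt, p)$event
    expect_lt(ev$s, 0)
    expect_false(ev$fixed)
  }
})

test_that("conflict keeps the joint phenotype between the optima, still fixing mutations", {
  cfg <- scenario_config("conflict", n_iterations = 2000L, burn_in = 500L,
                         n_replicates = 20L, seed = 17L)
  parties <- build_parties(cfg)
  res <- run_scenario(cfg)
  d1 <- agg_stat(res$aggregate, "mean_distance", 1L)["mean"]
  # mean |z - o1| < o1 - o2 and > 0 places time-averaged z inside the gap
  gap <- parties$party1$optimum - parties$party2$optimum
  expect_gt(d1, 0)
  expect_lt(d1, gap)
  # Sisyphean signature: both conflict parties keep fixing at equilibrium,
  # while the standard model has essentially stopped
  ff1 <- agg_stat(res$aggregate, "fixation_fraction", 1L)["mean"]
  ff2 <- agg_stat(res$aggregate, "fixation_fraction", 2L)["mean"]
  expect_gt(ff1, 0.01)
  expect_gt(ff2, 0.01)
  cfg_s <- scenario_config("standard", n_iterations = 2000L, burn_in = 500L,
                           n_replicates = 20L, seed = 18L)
  ff_s <- agg_stat(run_scenario(cfg_s)$aggregate, "fixation_fraction", 1L)["mean"]
  expect_lt(ff_s, 0.005)
})
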