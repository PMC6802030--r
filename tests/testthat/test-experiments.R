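test_that("validate_config fills the baseline defaults", {
  cfg <- validate_config(list())
  expect_identical(cfg$regime, "standard")
  expect_equal(cfg$omega, 1/2)
  expect_equal(cfg$lag_load, 0.2)
  expect_equal(cfg$mean_size, 0.1)
  expect_identical(cfg$mut_dist, "normal")
  expect_equal(c(cfg$f, cfg$kappa, cfg$r), c(1, 1, 1))
  expect_identical(c(cfg$pop_size1, cfg$pop_size2), c(Inf, Inf))
  expect_identical(cfg$burn_in, 500L) # 250 / omega at omega = 1/2
})

test_that("validate_config collects every violation in one pass", {
  err <- tryCatch(
    validate_config(list(lag_load = 1.3, r = 2.5, omega = -1)),
    error = conditionMessage)
  expect_match(err, "lag_load.*\\(0, 1\\)")
  expect_match(err, "r: mutational-input multiplier must be a positive integer")
  expect_match(err, "omega")
  expect_error(validate_config(list(bogus = 1)), "unknown field")
})

test_that("burn-in scales with the slower party's adaptation timescale", {
  expect_identical(validate_config(list(omega = 1/8))$burn_in, 2000L)
  # with f > 1 party 2 keeps the wide curve: burn-in unchanged
  expect_identical(validate_config(list(f = 4))$burn_in, 500L)
  # f < 1 makes party 1 the slower party
  expect_identical(validate_config(list(f = 1/2))$burn_in, 1000L)
})

test_that("seed derivation is pure, bounded and collision-averse", {
  s1 <- derive_seed(1L, 1L, 1L)
  expect_identical(s1, derive_seed(1L, 1L, 1L))
  grid <- expand.grid(base = c(1L, 2L), cell = 1:5, rep = 1:50)
  seeds <- mapply(derive_seed, grid$base, grid$cell, grid$rep)
  expect_true(all(seeds >= 1 & seeds < 2^31 - 1))
  expect_identical(anyDuplicated(seeds), 0L)
})

test_that("a one-cell grid run writes summaries, events and a manifest", {
  out <- tempfile("exp-")
  grid <- experiment_grid(regime = "conflict", n_iterations = 10L,
                          burn_in = 0L, n_replicates = 2L, base_seed = 5L)
  expect_identical(nrow(grid), 1L)
  res <- suppressMessages(run_experiment(grid, out))
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, "cell-001-summary.tsv")))
  expect_true(file.exists(file.path(out, "cell-001-events-rep1.tsv")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(all(res$n <= 2))
  # power rows ride along for two-party cells
  expect_true("power_party1" %in% res$statistic)
})

test_that("re-running a grid reproduces byte-identical outputs", {
  grid <- experiment_grid(regime = c("standard", "conflict"),
                          n_iterations = 20L, burn_in = 5L,
                          n_replicates = 2L, base_seed = 9L)
  out1 <- tempfile("exp-")
  out2 <- tempfile("exp-")
  suppressMessages(run_experiment(grid, out1))
  suppressMessages(run_experiment(grid, out2))
  for (f in c("summary.tsv", "manifest.txt")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("a cell re-run in isolation reproduces its full-grid rows", {
  grid <- experiment_grid(regime = "conflict", f = c(1, 2),
                          n_iterations = 100L, burn_in = 20L,
                          n_replicates = 3L, base_seed = 77L)
  out <- tempfile("exp-")
  full <- suppressMessages(run_experiment(grid, out))
  cfg2 <- validate_config(list(regime = "conflict", f = 2,
                               n_iterations = 100L, burn_in = 20L,
                               n_replicates = 3L, seed = 77L))
  alone <- run_scenario(cfg2, cell = 2L)
  full_fit <- full[full$cell == 2 & full$statistic == "mean_fitness" &
                     full$party %in% 1, "mean"]
  lone_fit <- agg_stat(alone$aggregate, "mean_fitness", 1L)[["mean"]]
  expect_equal(full_fit, lone_fit)
})

test_that("event logs round-trip through delimited text", {
  cfg <- quick_cfg("conflict", n_iterations = 25L)
  set.seed(2)
  log <- run_conflict(cfg)
  f <- tempfile(fileext = ".tsv")
  write_event_log(log, f)
  log2 <- read_event_log(f)
  expect_equal(as.data.frame(log)[, c("iteration", "party", "fixed")],
               as.data.frame(log2)[, c("iteration", "party", "fixed")])
  expect_equal(log$z_after, log2$z_after, tolerance = 1e-14)
  cfg2 <- attr(log2, "config")
  expect_identical(cfg2$regime, "conflict")
  expect_equal(cfg2$lag_load, cfg$lag_load)
  # re-summarize from disk
  s_disk <- summarize_window(log2, burn_in = 5L, window = 20L)
  s_mem <- summarize_window(log, burn_in = 5L, window = 20L)
  expect_equal(s_disk$mean_fitness, s_mem$mean_fitness, tolerance = 1e-14)
})

test_that("flat grid-configuration files parse into grid arguments", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "regime = conflict",
               "f = 1, 2, 4", "mean_size = 0.1",
               "n_iterations = 50", "n_replicates = 2"), f)
  args <- read_grid_config(f)
  expect_identical(args$regime, "conflict")
  expect_equal(args$f, c(1, 2, 4))
  grid <- do.call(experiment_grid, args)
  expect_identical(nrow(grid), 3L)
  writeLines("not a key value pair", f)
  expect_error(read_grid_config(f), "malformed")
})

test_that("the command-line driver runs a tiny simulation end to end", {
  script <- system.file("scripts", "fgmconflict.R", package = "fgmconflict")
  expect_true(nzchar(script))
  out <- tempfile("cli-")
  status <- system2("Rscript",
                    c(script, "simulate", "--regime", "conflict",
                      "--iterations", "10", "--burn-in", "0",
                      "--replicates", "2", "--seed", "4", "--out", out,
                      "--log-level", "QUIET"),
                    stdout = TRUE, stderr = TRUE)
  expect_identical(attr(status, "status"), NULL) # exit code 0
  expect_true(file.exists(file.path(out, "summary.tsv")))
})

test_that("trajectory preset produces the three-regime fitness curves", {
  out <- tempfile("preset-")
  traj <- suppressMessages(
    run_preset("trajectories", out, replicates = 5L, iterations = 120L,
               seed = 2L))
  expect_true(file.exists(file.path(out, "trajectories.tsv")))
  expect_setequal(unique(traj$variant),
                  c("standard", "conflict_origin", "conflict_optimum",
                    "abiotic"))
  # the standard walk climbs toward maximal fitness
  std <- traj[traj$variant == "standard", ]
  expect_gt(std$mean_fitness[120], 0.95)
  expect_gt(std$mean_fitness[120], std$mean_fitness[1])
})
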