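#' Walk state
#'
#' The mutable state of an adaptive walk: the current joint-trait value, the
#' iteration counter, and (optionally) the current optima.
#'
#' @param z Current joint-phenotype value.
#' @param iteration Nonnegative iteration index.
#' @param optima Optional named numeric vector of current optimum positions.
#' @return A list of class `fgm_state`.
#' @export
walk_state <- function(z, iteration = 0L, optima = NULL) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z), iteration >= 0)
  structure(list(z = z, iteration = as.integer(iteration), optima = optima),
            class = "fgm_state")
}

#' Propose one mutation and resolve its fate
#'
#' One elementary step of the walk under strong-selection/weak-mutation
#' dynamics: draw a single mutation effect for the proposing party, compute
#' the selection coefficient from the party's fitness before and after the
#' additive shift, and fix it with the Kimura probability (infinite- or
#' finite-population form depending on `party$pop_size`). Exactly one
#' mutation is under selection at a time.
#'
#' The function is functional: it returns the event and the updated state
#' rather than mutating its arguments. One effect draw and one uniform are
#' always consumed, whether or not the mutation can fix.
#'
#' @param state A [walk_state()].
#' @param party The proposing [party()].
#' @return A list with `event` (iteration, party_index, effect, s, fixed,
#'   z_after, w_after) and `state` (the updated [walk_state()]).
#' @examples
#' p <- party(omega = 1/2, optimum = 0.668, mean_size = 0.1)
#' set.seed(1)
#' step <- propose_and_resolve(walk_state(0), p)
#' step$event$s
#' @export
propose_and_resolve <- function(state, party) {
  stopifnot(inherits(state, "fgm_state"), inherits(party, "fgm_party"))
  w <- fitness(state$z, party)
  d <- draw_effect(party)
  wm <- fitness(state$z + d$effect, party)
  s <- selection_coefficient(wm, w)
  pi_fix <- if (is.finite(party$pop_size)) {
    fixation_prob_finite(s, party$pop_size)
  } else {
    fixation_prob_infinite(s)
  }
  fixed <- runif(1) < pi_fix
  z_new <- if (fixed) state$z + d$effect else state$z
  list(
    event = list(iteration = state$iteration + 1L,
                 party_index = party$index, effect = d$effect, s = s,
                 fixed = fixed, z_after = z_new,
                 w_after = if (fixed) wm else w),
    state = walk_state(z_new, state$iteration + 1L, state$optima)
  )
}

# N encoding shared with the C++ engine: -1 means infinite
encode_N <- function(pop_size) if (is.finite(pop_size)) as.double(pop_size) else -1

# Assemble the standard event-log data.frame with the common column set
make_log <- function(df, config, parties, o1_init) {
  rownames(df) <- NULL
  attr(df, "config") <- config
  attr(df, "parties") <- parties
  attr(df, "o1_init") <- o1_init
  class(df) <- c("fgm_log", "data.frame")
  df
}

#' Run a standard (single-optimum) adaptive walk
#'
#' One party adapts toward a fixed optimum placed at
#' \eqn{o_1 = \sqrt{-\ln w_0 / \omega_1}}, one mutation proposal per
#' iteration. This is the no-conflict control, parameterized identically to
#' party 1 of the corresponding conflict scenario.
#'
#' @param config An `fgm_config` (regime `"standard"`).
#' @param engine `"cpp"` (default) or `"r"`; both consume the random-number
#'   stream in the same order and produce identical logs.
#' @return An event-log data.frame of class `fgm_log` with columns
#'   `iteration`, `party`, `effect`, `s`, `fixed`, `z_after`, `o1_after`,
#'   `w1_after`, `w2_after`, covering `burn_in + n_iterations` iterations.
#' @examples
#' cfg <- scenario_config("standard", n_iterations = 50, burn_in = 0)
#' set.seed(1)
#' log <- run_standard(cfg)
#' sum(log$fixed)
#' @export
run_standard <- function(config, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "fgm_config"))
  if (config$regime != "standard")
    stop("`config$regime` must be \"standard\"", call. = FALSE)
  engine <- match.arg(engine)
  parties <- build_parties(config)
  p1 <- parties$party1
  n_total <- config$burn_in + config$n_iterations
  raw <- if (engine == "cpp") {
    cpp_walk_standard(n_total, config$z_init, p1$optimum, p1$omega, p1$sigma,
                      dist_code(p1$mut_dist), encode_N(p1$pop_size))
  } else {
    walk_standard_r(n_total, config$z_init, p1)
  }
  n <- length(raw$iteration)
  df <- data.frame(iteration = raw$iteration, party = rep(1L, n),
                   effect = raw$effect, s = raw$s, fixed = raw$fixed,
                   z_after = raw$z_after, o1_after = rep(p1$optimum, n),
                   w1_after = raw$w1_after, w2_after = rep(NA_real_, n))
  make_log(df, config, parties, p1$optimum)
}

#' Run a two-party conflict walk over a joint phenotype
#'
#' Both parties act on the shared trait value z. Each iteration a fair coin
#' picks the first mover; party 1 then performs its block of `r` contiguous
#' proposal-resolution rounds and party 2 its single round (in coin order).
#' Every fixation shifts z additively and changes both parties' fitness.
#'
#' @inheritParams run_standard
#' @param config An `fgm_config` with regime `"conflict"` or
#'   `"abiotic_matched"` (the latter because the abiotic control is paired to
#'   a conflict run with the same parameters).
#' @return An `fgm_log` with `(r + 1)` rows per iteration.
#' @examples
#' cfg <- scenario_config("conflict", n_iterations = 20, burn_in = 0)
#' set.seed(1)
#' log <- run_conflict(cfg)
#' table(log$party)
#' @export
run_conflict <- function(config, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "fgm_config"))
  if (!config$regime %in% c("conflict", "abiotic_matched"))
    stop("`config$regime` must be \"conflict\" or \"abiotic_matched\"",
         call. = FALSE)
  engine <- match.arg(engine)
  parties <- build_parties(config)
  p1 <- parties$party1
  p2 <- parties$party2
  n_total <- config$burn_in + config$n_iterations
  raw <- if (engine == "cpp") {
    cpp_walk_conflict(n_total, config$z_init, p1$optimum, p2$optimum,
                      p1$omega, p2$omega, p1$sigma, p2$sigma,
                      dist_code(p1$mut_dist), encode_N(p1$pop_size),
                      encode_N(p2$pop_size), config$r)
  } else {
    walk_conflict_r(n_total, config$z_init, p1, p2, config$r)
  }
  df <- data.frame(iteration = raw$iteration, party = raw$party,
                   effect = raw$effect, s = raw$s, fixed = raw$fixed,
                   z_after = raw$z_after,
                   o1_after = rep(p1$optimum, length(raw$iteration)),
                   w1_after = raw$w1_after, w2_after = raw$w2_after)
  make_log(df, config, parties, p1$optimum)
}

#' Per-iteration displacement magnitudes caused by party 2
#'
#' Extracts, from a conflict event log, the absolute net change in z caused
#' by party 2's fixations in each iteration (zero in iterations where party
#' 2 fixed nothing). These magnitudes define the optimum displacements of
#' the paired abiotic control.
#'
#' @param conflict_log An `fgm_log` from [run_conflict()].
#' @return A numeric vector, one nonnegative magnitude per iteration.
#' @export
party2_displacements <- function(conflict_log) {
  stopifnot(inherits(conflict_log, "fgm_log"))
  if (!any(conflict_log$party == 2L))
    stop("`conflict_log` contains no party-2 events; not a conflict log",
         call. = FALSE)
  n_iter <- max(conflict_log$iteration)
  contrib <- conflict_log$effect * conflict_log$fixed *
    (conflict_log$party == 2L)
  delta <- vapply(split(contrib, factor(conflict_log$iteration,
                                        levels = seq_len(n_iter))),
                  sum, numeric(1))
  unname(abs(delta))
}

#' Run the magnitude-matched abiotic (moving-optimum) control
#'
#' A single party, a copy of party 1, adapts while its optimum is displaced
#' at the start of each iteration by the magnitude of party 2's net change
#' to z in the same iteration of a paired conflict run, in a direction
#' chosen by fair coin (no displacement, and no coin, when party 2 fixed
#' nothing). The party then performs its own `r` proposal rounds. This
#' matches the abiotic environmental change to the biotic change in
#' magnitude while randomizing its direction.
#'
#' @param conflict_log The paired conflict run's event log.
#' @inheritParams run_standard
#' @return An `fgm_log` with `r` rows per iteration; `o1_after` records the
#'   moving optimum.
#' @examples
#' cfg <- scenario_config("abiotic_matched", n_iterations = 20, burn_in = 0)
#' set.seed(1)
#' clog <- run_conflict(cfg)
#' alog <- run_abiotic_matched(clog, cfg)
#' range(alog$o1_after)
#' @export
run_abiotic_matched <- function(conflict_log, config, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "fgm_config"))
  if (config$regime != "abiotic_matched")
    stop("`config$regime` must be \"abiotic_matched\"", call. = FALSE)
  engine <- match.arg(engine)
  parties <- build_parties(config)
  p1 <- parties$party1
  n_total <- config$burn_in + config$n_iterations
  delta <- party2_displacements(conflict_log)
  if (length(delta) != n_total)
    stop(sprintf(
      "paired conflict log covers %d iterations but config needs %d",
      length(delta), n_total), call. = FALSE)
  raw <- if (engine == "cpp") {
    cpp_walk_abiotic(n_total, config$z_init, p1$optimum, p1$omega, p1$sigma,
                     dist_code(p1$mut_dist), encode_N(p1$pop_size),
                     config$r, delta)
  } else {
    walk_abiotic_r(n_total, config$z_init, p1, config$r, delta)
  }
  df <- data.frame(iteration = raw$iteration,
                   party = rep(1L, length(raw$iteration)),
                   effect = raw$effect, s = raw$s, fixed = raw$fixed,
                   z_after = raw$z_after, o1_after = raw$o1_after,
                   w1_after = raw$w1_after,
                   w2_after = rep(NA_real_, length(raw$iteration)))
  make_log(df, config, parties, p1$optimum)
}

# ---- pure-R reference engines -----------------------------------------
# These mirror the C++ engine exactly, including the order in which the
# random-number stream is consumed (effect draw(s), then one uniform per
# proposal; one coin per conflict iteration; one coin per nonzero abiotic
# displacement), so identical seeds give bit-identical logs.

fix_prob_for <- function(s, party) {
  if (is.finite(party$pop_size)) fixation_prob_finite(s, party$pop_size)
  else fixation_prob_infinite(s)
}

round_r <- function(z, w, party) {
  if (w <= 0)
    stop("current fitness underflowed to zero; selection coefficient undefined",
         call. = FALSE)
  m <- draw_effect(party)$effect
  wm <- exp(-party$omega * (party$optimum - (z + m))^2)
  s <- wm / w - 1
  fixed <- runif(1) < fix_prob_for(s, party)
  if (fixed) {
    z <- z + m
    w <- wm
  }
  list(z = z, w = w, effect = m, s = s, fixed = fixed)
}

walk_standard_r <- function(n_iter, z0, p1) {
  out <- data.frame(iteration = seq_len(n_iter), effect = numeric(n_iter),
                    s = numeric(n_iter), fixed = logical(n_iter),
                    z_after = numeric(n_iter), w1_after = numeric(n_iter))
  z <- z0
  w <- exp(-p1$omega * (p1$optimum - z)^2)
  for (t in seq_len(n_iter)) {
    st <- round_r(z, w, p1)
    z <- st$z; w <- st$w
    out$effect[t] <- st$effect; out$s[t] <- st$s; out$fixed[t] <- st$fixed
    out$z_after[t] <- z; out$w1_after[t] <- w
  }
  out
}

walk_conflict_r <- function(n_iter, z0, p1, p2, r) {
  n <- n_iter * (r + 1L)
  out <- data.frame(iteration = integer(n), party = integer(n),
                    effect = numeric(n), s = numeric(n), fixed = logical(n),
                    z_after = numeric(n), w1_after = numeric(n),
                    w2_after = numeric(n))
  z <- z0
  w1 <- exp(-p1$omega * (p1$optimum - z)^2)
  w2 <- exp(-p2$omega * (p2$optimum - z)^2)
  k <- 0L
  for (t in seq_len(n_iter)) {
    party1_first <- runif(1) < 0.5
    for (block in 1:2) {
      p1_block <- if (block == 1L) party1_first else !party1_first
      rounds <- if (p1_block) r else 1L
      for (j in seq_len(rounds)) {
        if (p1_block) {
          st <- round_r(z, w1, p1)
          z <- st$z; w1 <- st$w
          w2 <- exp(-p2$omega * (p2$optimum - z)^2)
        } else {
          st <- round_r(z, w2, p2)
          z <- st$z; w2 <- st$w
          w1 <- exp(-p1$omega * (p1$optimum - z)^2)
        }
        k <- k + 1L
        out$iteration[k] <- t
        out$party[k] <- if (p1_block) 1L else 2L
        out$effect[k] <- st$effect; out$s[k] <- st$s; out$fixed[k] <- st$fixed
        out$z_after[k] <- z; out$w1_after[k] <- w1; out$w2_after[k] <- w2
      }
    }
  }
  out
}

walk_abiotic_r <- function(n_iter, z0, p1, r, delta) {
  stopifnot(length(delta) == n_iter, all(delta >= 0))
  n <- n_iter * r
  out <- data.frame(iteration = integer(n), effect = numeric(n),
                    s = numeric(n), fixed = logical(n), z_after = numeric(n),
                    o1_after = numeric(n), w1_after = numeric(n))
  z <- z0
  o1 <- p1$optimum
  w <- exp(-p1$omega * (o1 - z)^2)
  k <- 0L
  for (t in seq_len(n_iter)) {
    if (delta[t] > 0) {
      o1 <- o1 + if (runif(1) < 0.5) delta[t] else -delta[t]
      w <- exp(-p1$omega * (o1 - z)^2)
    }
    pt <- p1
    pt$optimum <- o1
    for (j in seq_len(r)) {
      st <- round_r(z, w, pt)
      z <- st$z; w <- st$w
      k <- k + 1L
      out$iteration[k] <- t
      out$effect[k] <- st$effect; out$s[k] <- st$s; out$fixed[k] <- st$fixed
      out$z_after[k] <- z; out$o1_after[k] <- o1; out$w1_after[k] <- w
    }
  }
  out
}
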