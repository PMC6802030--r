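#' Define one party to a conflict
#'
#' A party is one evolving side of the interaction (for example the host, or
#' the pathogen): it has a Gaussian fitness function for the joint trait
#' \eqn{z}, a mutation-effect distribution, and a population size governing
#' drift.
#'
#' Fitness for party \eqn{i} is \eqn{w_i = \exp(-\omega_i (o_i - z)^2)}: it
#' equals 1 at the optimum \eqn{o_i} and falls off in both directions at a
#' rate set by the shape parameter \eqn{\omega_i}.
#'
#' @param omega Positive shape parameter \eqn{\omega} of the fitness curve
#'   (larger = narrower curve, stronger selection).
#' @param optimum Optimal trait value \eqn{o} for this party (phenotype
#'   units).
#' @param sigma Scale of mutation effects. For the normal distribution this
#'   is the standard deviation; for all distributions the mean absolute
#'   effect is \eqn{\bar m = \sigma\sqrt{2/\pi}}. Give either `sigma` or
#'   `mean_size`.
#' @param mean_size Mean absolute mutation effect \eqn{\bar m}; converted to
#'   `sigma` via [sigma_from_mean_size()].
#' @param pop_size Population size \eqn{N} (`Inf` for the effectively
#'   infinite, drift-free case; finite values must be at least 2).
#' @param mut_input Relative mutational input (proposals per iteration are
#'   scaled by this in the conflict regime; must be a positive integer).
#' @param mut_dist Mutation-effect distribution: `"normal"`, `"uniform"` or
#'   `"exponential"`. All are symmetric about zero ("unbiased").
#' @param index Party label, 1 or 2. By convention party 1 holds the positive
#'   optimum in a two-party conflict.
#' @return An object of class `fgm_party`.
#' @examples
#' p <- party(omega = 1/2, optimum = 0.668, mean_size = 0.1)
#' fitness(0, p)
#' @export
party <- function(omega, optimum, sigma = NULL, mean_size = NULL,
                  pop_size = Inf, mut_input = 1L, mut_dist = "normal",
                  index = 1L) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0)
    stop("`omega` must be a single positive number", call. = FALSE)
  if (!is.numeric(optimum) || length(optimum) != 1L || !is.finite(optimum))
    stop("`optimum` must be a single finite number", call. = FALSE)
  if (is.null(sigma) && is.null(mean_size))
    stop("give either `sigma` or `mean_size`", call. = FALSE)
  if (!is.null(sigma) && !is.null(mean_size))
    stop("give only one of `sigma` and `mean_size`", call. = FALSE)
  if (is.null(sigma)) sigma <- sigma_from_mean_size(mean_size)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (length(pop_size) != 1L || is.na(pop_size) || pop_size <= 0)
    stop("`pop_size` must be positive (or Inf)", call. = FALSE)
  if (is.finite(pop_size)) {
    if (pop_size < 2 || pop_size != round(pop_size))
      stop("finite `pop_size` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(mut_input) || length(mut_input) != 1L ||
      mut_input != round(mut_input) || mut_input < 1)
    stop("`mut_input` must be a positive integer", call. = FALSE)
  mut_dist <- match.arg(mut_dist, c("normal", "uniform", "exponential"))
  if (!index %in% c(1L, 2L))
    stop("`index` must be 1 or 2", call. = FALSE)
  structure(
    list(index = as.integer(index), omega = omega, optimum = optimum,
         sigma = sigma, pop_size = pop_size,
         mut_input = as.integer(mut_input), mut_dist = mut_dist),
    class = "fgm_party"
  )
}

#' @export
print.fgm_party <- function(x, ...) {
  n <- if (is.finite(x$pop_size)) format(x$pop_size) else "infinite"
  cat(sprintf(
    "<fgm_party %d> omega = %g, optimum = %g, sigma = %g (mean |m| = %g)\n",
    x$index, x$omega, x$optimum, x$sigma, mean_size_from_sigma(x$sigma)))
  cat(sprintf("  mutation: %s, input x%d; population: %s\n",
              x$mut_dist, x$mut_input, n))
  invisible(x)
}

#' Conflict geometry: intersection fitness and lag load
#'
#' In a two-party conflict the two fitness curves intersect at the origin
#' (z = 0), where both parties have fitness \eqn{w_0} and hence an equal lag
#' load \eqn{1 - w_0}. The shared lag load measures the intensity of
#' conflict: raising it pushes the two optima apart.
#'
#' @param lag_load Shared lag load at the intersection, in (0, 1).
#' @return A list with `w0`, `lag_load`, and the `origin` (always 0).
#' @examples
#' conflict_geometry(0.2)
#' @export
conflict_geometry <- function(lag_load) {
  if (!is.numeric(lag_load) || length(lag_load) != 1L ||
      !is.finite(lag_load) || lag_load <= 0 || lag_load >= 1)
    stop("`lag_load` must be a single number in (0, 1)", call. = FALSE)
  list(w0 = 1 - lag_load, lag_load = lag_load, origin = 0)
}

#' Gaussian fitness of a party at a trait value
#'
#' Computes \eqn{w = \exp(-\omega (o - z)^2)} for the given party.
#'
#' @param z Trait value(s); must be finite.
#' @param party An [party()] object.
#' @return Fitness in (0, 1]; 1 exactly at the optimum.
#' @examples
#' p <- party(omega = 1/2, optimum = 1, sigma = 0.1)
#' fitness(c(0, 0.5, 1), p)
#' @export
fitness <- function(z, party) {
  stopifnot(inherits(party, "fgm_party"))
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("`z` must be finite", call. = FALSE)
  exp(-party$omega * (party$optimum - z)^2)
}

#' Optimum position implied by a shared lag load
#'
#' Solving \eqn{w_0 = \exp(-\omega o^2)} for the optimum gives
#' \eqn{o = \pm\sqrt{-\ln w_0 / \omega}}: the trait value at which a party
#' with shape `omega` has fitness `w0` at the origin. Party 1 takes the
#' positive root, party 2 the negative.
#'
#' @param w0 Intersection fitness, in (0, 1).
#' @param omega Positive fitness-curve shape parameter.
#' @param sign `+1` or `-1`, selecting the root.
#' @return The optimum position.
#' @examples
#' o1 <- optimum_from_lagload(0.8, 1/2, +1)
#' fitness(0, party(omega = 1/2, optimum = o1, sigma = 0.1)) # = 0.8
#' @export
optimum_from_lagload <- function(w0, omega, sign = +1) {
  if (!is.numeric(w0) || length(w0) != 1L || !is.finite(w0) ||
      w0 <= 0 || w0 >= 1)
    stop("`w0` must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("`omega` must be positive", call. = FALSE)
  if (!sign %in% c(-1, 1))
    stop("`sign` must be +1 or -1", call. = FALSE)
  sign * sqrt(-log(w0) / omega)
}

#' Selection coefficient of a proposed mutation
#'
#' \eqn{s = w_m / w - 1}, where \eqn{w_m} is the fitness of the mutant and
#' \eqn{w} the population's current fitness.
#'
#' @param w_mutant Mutant fitness (nonnegative).
#' @param w_current Current fitness (strictly positive).
#' @return The selection coefficient; 0 iff the fitnesses are equal.
#' @examples
#' selection_coefficient(0.9, 0.8) # 0.125
#' @export
selection_coefficient <- function(w_mutant, w_current) {
  if (any(!is.finite(w_current)) || any(w_current <= 0))
    stop("`w_current` must be strictly positive (fitness underflow?)",
         call. = FALSE)
  if (any(!is.finite(w_mutant)) || any(w_mutant < 0))
    stop("`w_mutant` must be finite and nonnegative", call. = FALSE)
  w_mutant / w_current - 1
}

#' Fixation probability in an effectively infinite population
#'
#' Kimura's fixation probability when drift is negligible:
#' \eqn{\Pi = 1 - e^{-2s}} for \eqn{s > 0} and \eqn{\Pi = 0} for
#' \eqn{s \le 0}. A neutral mutation (s = 0) never fixes in an infinite
#' population.
#'
#' @param s Selection coefficient(s); must be finite.
#' @return Fixation probabilities in [0, 1).
#' @examples
#' fixation_prob_infinite(c(-0.05, 0, 0.1))
#' @export
fixation_prob_infinite <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("`s` must be finite", call. = FALSE)
  ifelse(s > 0, -expm1(-2 * s), 0)
}

#' Fixation probability in a finite population
#'
#' Kimura's diffusion result
#' \eqn{\Pi = (1 - e^{-2s}) / (1 - e^{-4Ns})}, valid for beneficial and
#' deleterious mutations alike. The formula is continuous at \eqn{s = 0}
#' with limiting value \eqn{1/(2N)}; the implementation switches to that
#' limit when \eqn{|4Ns| < 10^{-8}} and to an asymptotic form when the
#' deleterious exponent would overflow.
#'
#' @param s Selection coefficient(s); must be finite.
#' @param N Population size, an integer >= 2.
#' @return Fixation probabilities in (0, 1).
#' @examples
#' fixation_prob_finite(0, 10)      # 1/20
#' fixation_prob_finite(-0.01, 10)  # positive: drift can fix deleterious
#' @export
fixation_prob_finite <- function(s, N) {
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("`s` must be finite", call. = FALSE)
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop("`N` must be a single integer >= 2", call. = FALSE)
  vapply(s, function(si) {
    x <- 4 * N * si
    if (abs(x) < 1e-8) return(1 / (2 * N))
    if (si > 0) return(expm1(-2 * si) / expm1(-x))
    a <- -2 * si
    b <- -x
    if (b < 700) return(expm1(a) / expm1(b))
    exp(a - b) * (-expm1(-a))
  }, numeric(1))
}
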