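#' Mean absolute mutation size implied by the scale parameter
#'
#' For unbiased mutation effects the mean absolute effect is
#' \eqn{\bar m = \sigma \sqrt{2/\pi}} (the mean of a half-normal). The same
#' relationship is used to parameterize the uniform and exponential
#' alternatives so that all three distributions are compared at a matched
#' mean size.
#'
#' @param sigma Positive scale parameter.
#' @return The mean absolute effect \eqn{\bar m}.
#' @seealso [sigma_from_mean_size()] for the exact inverse.
#' @examples
#' mean_size_from_sigma(0.1) # ~0.0798
#' @export
mean_size_from_sigma <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive", call. = FALSE)
  sigma * sqrt(2 / pi)
}

#' @rdname mean_size_from_sigma
#' @param mean_size Positive mean absolute effect.
#' @export
sigma_from_mean_size <- function(mean_size) {
  if (!is.numeric(mean_size) || any(!is.finite(mean_size)) ||
      any(mean_size <= 0))
    stop("`mean_size` must be positive", call. = FALSE)
  mean_size / sqrt(2 / pi)
}

# distribution name -> integer code shared with the C++ engine
dist_code <- function(mut_dist) {
  match(mut_dist, c("normal", "uniform", "exponential")) - 1L
}

#' Draw mutation effects for a party
#'
#' Draws signed additive effects on the joint trait from the party's
#' mutation distribution. All three distributions are symmetric about zero
#' and share the mean absolute size \eqn{\bar m = \sigma\sqrt{2/\pi}}:
#' * `normal`: \eqn{m \sim N(0, \sigma^2)};
#' * `uniform`: \eqn{m \sim U(-b, b)} with \eqn{b = 2\bar m}
#'   (so \eqn{E|m| = b/2 = \bar m});
#' * `exponential`: magnitude exponential with mean \eqn{\bar m}, sign a
#'   fair coin (a symmetric Laplace construction).
#'
#' `draw_effects()` is the vectorized generator; [draw_effect()] draws a
#' single proposal in the per-round order used by the walk simulator
#' (magnitude before sign for the exponential case).
#'
#' @param n Number of draws.
#' @param party An [party()] object.
#' @return For `draw_effects()`, a numeric vector of signed effects. For
#'   `draw_effect()`, a list with `effect`, `magnitude` and `party_index`.
#' @examples
#' p <- party(omega = 1/2, optimum = 1, mean_size = 0.1)
#' set.seed(1)
#' mean(abs(draw_effects(1e4, p))) # ~0.1
#' @export
draw_effects <- function(n, party) {
  stopifnot(inherits(party, "fgm_party"))
  mbar <- mean_size_from_sigma(party$sigma)
  switch(party$mut_dist,
    normal = rnorm(n, 0, party$sigma),
    uniform = runif(n, -2 * mbar, 2 * mbar),
    exponential = {
      mag <- rexp(n) * mbar
      sgn <- ifelse(runif(n) < 0.5, 1, -1)
      sgn * mag
    },
    stop("unknown mutation distribution", call. = FALSE)
  )
}

#' @rdname draw_effects
#' @export
draw_effect <- function(party) {
  stopifnot(inherits(party, "fgm_party"))
  mbar <- mean_size_from_sigma(party$sigma)
  effect <- switch(party$mut_dist,
    normal = rnorm(1, 0, party$sigma),
    uniform = runif(1, -2 * mbar, 2 * mbar),
    exponential = {
      mag <- rexp(1) * mbar
      if (runif(1) < 0.5) mag else -mag
    },
    stop("unknown mutation distribution", call. = FALSE)
  )
  list(effect = effect, magnitude = abs(effect), party_index = party$index)
}
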