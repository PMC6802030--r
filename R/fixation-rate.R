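#' Expected per-proposal fixation probability at a frozen trait value
#'
#' Integrates the fixation probability over the mutation-effect
#' distribution, \eqn{\int \Pi(s(m))\, dF(m)}, by adaptive quadrature. This
#' is the closed-form expectation of the per-proposal fixation fraction the
#' walk simulator realizes at a fixed z, and serves as an independent check
#' on the Monte-Carlo machinery.
#'
#' The integrand is piecewise smooth: beneficial mutations lie strictly
#' between 0 and \eqn{2(o - z)}, so the quadrature is split at those
#' breakpoints (under infinite N only that interval contributes).
#'
#' @param z Frozen joint-trait value.
#' @param party An [party()] object.
#' @return The expected fixation probability of a single random proposal.
#' @examples
#' p <- party(omega = 1/2, optimum = 0.668, mean_size = 0.1)
#' expected_fixation_rate(0, p)
#' @export
expected_fixation_rate <- function(z, party) {
  stopifnot(inherits(party, "fgm_party"), is.numeric(z), length(z) == 1L,
            is.finite(z))
  mbar <- mean_size_from_sigma(party$sigma)
  dens <- switch(party$mut_dist,
    normal = function(m) stats::dnorm(m, 0, party$sigma),
    uniform = function(m) stats::dunif(m, -2 * mbar, 2 * mbar),
    exponential = function(m) 0.5 * exp(-abs(m) / mbar) / mbar
  )
  w0 <- fitness(z, party)
  integrand <- function(m) {
    s <- fitness(z + m, party) / w0 - 1
    pi_fix <- if (is.finite(party$pop_size)) {
      fixation_prob_finite(s, party$pop_size)
    } else {
      fixation_prob_infinite(s)
    }
    pi_fix * dens(m)
  }
  edge <- 2 * (party$optimum - z)
  if (is.finite(party$pop_size)) {
    breaks <- sort(unique(c(-Inf, 0, edge, Inf)))
  } else {
    # only the beneficial interval contributes when drift is absent
    if (edge == 0) return(0)
    breaks <- sort(c(0, edge))
  }
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    total <- total + stats::integrate(integrand, breaks[i], breaks[i + 1L],
                                      rel.tol = 1e-9,
                                      stop.on.error = FALSE)$value
  }
  total
}
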