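#' Gamma-variate pharmacological response
#'
#' The drug-induced BOLD response is modelled as a scaled gamma density,
#' \deqn{f(t) = \lambda \, \frac{\beta^\alpha t^{\alpha-1} e^{-\beta t}}{\Gamma(\alpha)},}
#' with shape \eqn{\alpha}, rate \eqn{\beta} (1/min) and scale \eqn{\lambda}
#' (\%BOLD x min). Because the gamma density integrates to one, the area under
#' the curve (total activation) is exactly \eqn{\lambda}, and for
#' \eqn{\alpha > 1} the response peaks at \eqn{t = (\alpha-1)/\beta}.
#'
#' @param t Time since injection in minutes; values < 0 return 0.
#' @param alpha Shape parameter (> 0).
#' @param beta Rate parameter in 1/min (> 0).
#' @param lam Scale factor (area under the curve, \%BOLD x min).
#' @return Response in \%BOLD at each \code{t}.
#' @export
gamma_response <- function(t, alpha, beta, lam = 1) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive")
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- lam * stats::dgamma(t[pos], shape = alpha, rate = beta)
  # t == 0: dgamma is 0 for alpha > 1, beta for alpha == 1, Inf for alpha < 1
  z <- t == 0
  if (any(z)) out[z] <- lam * stats::dgamma(0, shape = alpha, rate = beta)
  out
}

#' Peak time of the gamma-variate response
#' @inheritParams gamma_response
#' @return \eqn{(\alpha - 1)/\beta} in minutes; \code{NA} when
#'   \eqn{\alpha \le 1} (no interior maximum).
#' @export
gamma_peak_time <- function(alpha, beta) {
  ifelse(alpha > 1, (alpha - 1) / beta, NA_real_)
}

#' Peak amplitude of the gamma-variate response
#'
#' Closed form \eqn{\lambda \beta (\alpha-1)^{\alpha-1} e^{-(\alpha-1)} / \Gamma(\alpha)}
#' for \eqn{\alpha > 1} (evaluated on the log scale for stability).
#'
#' @inheritParams gamma_response
#' @return Maximum signal change in \%BOLD.
#' @export
gamma_peak_amplitude <- function(alpha, beta, lam = 1) {
  ifelse(alpha > 1,
         lam * exp(log(beta) + (alpha - 1) * (log(alpha - 1) - 1) - lgamma(alpha)),
         NA_real_)
}
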