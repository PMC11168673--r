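#' Log-density of the somatic prior
#'
#' The soma's intrinsic conductance and reversal potential parametrise a
#' Gaussian prior over the somatic potential with mean `E0` and variance
#' `lambda_e / g0`. Computed in the log domain throughout because lambda_e
#' spans two orders of magnitude across the experiment parameter sets and
#' naive density products underflow.
#'
#' @param u_s Somatic potential(s), mV.
#' @param soma A [soma_state()]; `g0` must be positive.
#'
#' @return Log-density value(s).
#' @export
prior_logdensity <- function(u_s, soma) {
  if (soma$g0 <= 0) {
    stop("improper prior: g0 must be positive for a normalizable prior",
         call. = FALSE)
  }
  s2 <- soma$lambda_e / soma$g0
  -0.5 * log(2 * pi * s2) - (u_s - soma$E0)^2 / (2 * s2)
}

#' Log-likelihood contributed by one dendrite
#'
#' A dendrite's effective reversal potential `E_d` is read as an observation
#' of the somatic potential with precision alpha * g_d / lambda_e, i.e.
#' E_d ~ Normal(u_s, lambda_e / (alpha g_d)). A dendrite with alpha * g_d = 0
#' carries no information: the likelihood is flat in `u_s` and the function
#' returns 0 so it drops out of log-density sums.
#'
#' @param E_d Observed effective reversal potential (mV).
#' @param u_s Somatic potential(s) at which to evaluate (mV).
#' @param g_d Isolated dendritic conductance (nS).
#' @param alpha Coupling attenuation factor.
#' @param lambda_e Exploration constant (nS mV^2).
#'
#' @return Log-density value(s); 0 for an uninformative dendrite.
#' @export
dendrite_loglikelihood <- function(E_d, u_s, g_d, alpha, lambda_e) {
  prec <- alpha * g_d
  if (prec < 0) stop("alpha * g_d must be non-negative", call. = FALSE)
  if (prec == 0) return(rep(0, length(u_s)))
  s2 <- lambda_e / prec
  -0.5 * log(2 * pi * s2) - (E_d - u_s)^2 / (2 * s2)
}

#' Closed-form Gaussian posterior over the somatic potential
#'
#' Under conditional independence of the dendrites given the somatic
#' potential, the product of the Gaussian prior and the Gaussian dendritic
#' likelihoods is Gaussian with mean `E_bar` and variance `lambda_e / g_bar`,
#' exactly the conductance-weighted pooling of [pool_posterior()]. Also
#' exposes the normaliser Z = sqrt(2 pi lambda_e / g_bar).
#'
#' @inheritParams pool_posterior
#'
#' @return A `pooled_posterior` with an additional field `Z`.
#' @export
posterior_closed_form <- function(soma, dendrites = NULL) {
  pooled <- pool_posterior(soma, dendrites)
  pooled$Z <- sqrt(2 * pi * pooled$lambda_e / pooled$g_bar)
  pooled
}

#' Brute-force grid evaluation of the somatic posterior
#'
#' Independent numerical oracle: evaluates exp(log prior + sum of dendritic
#' log-likelihoods) pointwise on a uniform potential grid, normalises by the
#' trapezoid rule, and computes mean and variance by quadrature. Guards
#' against underflow with a max-shift before exponentiation.
#'
#' @inheritParams pool_posterior
#' @param span_sd Half-width of the grid in posterior standard deviations
#'   (default 10; must cover at least 8).
#' @param n_points Number of grid points (default 4001).
#'
#' @return A list with `grid` (tibble of `u` and `density`), `mean` and
#'   `variance`.
#' @export
grid_posterior_oracle <- function(soma, dendrites = NULL,
                                  span_sd = 10, n_points = 4001) {
  if (span_sd < 8) stop("grid must span at least 8 posterior SDs", call. = FALSE)
  pooled <- pool_posterior(soma, dendrites)
  sd_post <- sqrt(pooled$lambda_e / pooled$g_bar)
  u <- seq(pooled$E_bar - span_sd * sd_post, pooled$E_bar + span_sd * sd_post,
           length.out = n_points)
  logp <- prior_logdensity(u, soma)
  if (!is.null(dendrites) && nrow(dendrites) > 0L) {
    alpha <- if ("alpha_sd" %in% names(dendrites)) dendrites$alpha_sd else dendrites$alpha
    for (i in seq_len(nrow(dendrites))) {
      logp <- logp + dendrite_loglikelihood(dendrites$E_d[i], u,
                                            dendrites$g_d[i], alpha[i],
                                            soma$lambda_e)
    }
  }
  dens <- exp(logp - max(logp))
  du <- u[2] - u[1]
  trap <- function(f) du * (sum(f) - 0.5 * (f[1] + f[length(f)]))
  dens <- dens / trap(dens)
  m <- trap(u * dens)
  v <- trap((u - m)^2 * dens)
  list(grid = tibble::tibble(u = u, density = dens), mean = m, variance = v)
}
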