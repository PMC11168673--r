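#' Bank of Gaussian-tuned feature detectors
#'
#' Input units with Gaussian tuning curves over a linear orientation variable
#' (degrees, no angular wrap-around). Preferred orientations homogeneously
#' cover `[theta_min, theta_max]`.
#'
#' @param n Number of detectors (>= 2).
#' @param theta_min,theta_max Range of preferred orientations (degrees).
#' @param kappa Tuning concentration (deg^-2), the inverse of the tuning
#'   variance.
#' @param r_min,r_max Baseline and peak firing rates (s^-1).
#'
#' @return An object of class `detector_bank`.
#' @export
detector_bank <- function(n = 70, theta_min = -315, theta_max = 405,
                          kappa = 1 / 6, r_min = 0.75, r_max = 16) {
  stopifnot(n >= 2, r_min < r_max, kappa > 0, theta_min < theta_max)
  structure(list(preferred = seq(theta_min, theta_max, length.out = n),
                 kappa = kappa, r_min = r_min, r_max = r_max),
            class = "detector_bank")
}

#' Tuning-curve response of a detector bank
#'
#' r_j(theta) = r_min + (r_max - r_min) exp(-kappa/2 (theta - theta'_j)^2).
#' Deterministic: all stochasticity lives in cue sampling.
#'
#' @param theta Cue orientation (degrees, scalar).
#' @param bank A [detector_bank()].
#'
#' @return Rate vector (s^-1), one entry per detector, within
#'   `[r_min, r_max]`.
#' @export
tuning_rate <- function(theta, bank) {
  stopifnot(is.finite(theta))
  bank$r_min + (bank$r_max - bank$r_min) *
    exp(-bank$kappa / 2 * (theta - bank$preferred)^2)
}

#' Sample noisy visual/tactile cues around a true orientation
#'
#' Each present modality observes theta_true corrupted by Gaussian noise with
#' its own amplitude. With probability `1 - p_bimodal` exactly one modality
#' (an unbiased coin) is absent; an absent modality's detectors stay silent
#' and its cue is `NA`. Draws from the current RNG.
#'
#' @param theta_true Ground-truth orientation (degrees).
#' @param sigma_V,sigma_T Noise amplitudes (degrees) of the visual and
#'   tactile modality.
#' @param p_bimodal Probability that both modalities are present.
#'
#' @return A one-row tibble with `theta_true`, `theta_visual`,
#'   `theta_tactile` (NA when absent), `c_V`, `c_T` (contrasts, 1 by
#'   default).
#' @export
sample_cues <- function(theta_true, sigma_V, sigma_T, p_bimodal = 1) {
  stopifnot(sigma_V >= 0, sigma_T >= 0, p_bimodal >= 0, p_bimodal <= 1)
  theta_v <- theta_true + sigma_V * stats::rnorm(1)
  theta_t <- theta_true + sigma_T * stats::rnorm(1)
  if (stats::runif(1) >= p_bimodal) {
    if (stats::runif(1) < 0.5) theta_v <- NA_real_ else theta_t <- NA_real_
  }
  tibble::tibble(theta_true = theta_true, theta_visual = theta_v,
                 theta_tactile = theta_t, c_V = 1, c_T = 1)
}

#' Scale detector rates by a stimulus contrast
#'
#' @param rates Rate vector (s^-1).
#' @param c Non-negative contrast; 0 silences the modality.
#' @return Scaled rates.
#' @export
contrast_scale <- function(rates, c) {
  stopifnot(c >= 0)
  c * rates
}

#' Mix signal and background rates
#'
#' Convex mixture r = gamma * r_signal + (1 - gamma) * r_background,
#' emulating a stimulus embedded in background activity; `gamma` is the
#' relative signal contrast.
#'
#' @param r_signal,r_background Rate vectors of equal length.
#' @param gamma Mixing factor in `[0, 1]`.
#' @return Mixed rate vector.
#' @export
mix_background <- function(r_signal, r_background, gamma) {
  stopifnot(gamma >= 0, gamma <= 1, length(r_signal) == length(r_background))
  gamma * r_signal + (1 - gamma) * r_background
}

#' Floor rates at a positive minimum
#'
#' Gaussian rate noise can produce non-positive rates; these are replaced by
#' the floor. Idempotent.
#'
#' @param rates Rate vector.
#' @param r_min_floor Positive floor (s^-1).
#' @return Floored rates.
#' @export
rate_floor <- function(rates, r_min_floor) {
  stopifnot(r_min_floor > 0)
  pmax(rates, r_min_floor)
}

#' Softplus activation and its inverse
#'
#' rho(u) = log(1 + exp(u)) maps the somatic potential (mV) to an output
#' rate; the inverse maps a positive target rate back to the target
#' potential. Both are computed overflow-safely.
#'
#' @param u Potential (mV).
#' @return Rate (s^-1).
#' @export
softplus <- function(u) {
  ifelse(u > 30, u, log1p(exp(u)))
}

#' @rdname softplus
#' @param r Rate (s^-1); must be positive for the inverse.
#' @export
softplus_inv <- function(r) {
  if (any(r <= 0)) stop("softplus inverse is undefined for rates <= 0",
                        call. = FALSE)
  ifelse(r > 30, r, log(expm1(r)))
}

#' Target potential for a boundary-classification neuron
#'
#' An output neuron is trained to fire at `r_high_star` on its preferred side
#' of the decision boundary and at `r_low_star` otherwise; orientations
#' exactly on the boundary count as the ">=" side. The target membrane
#' potential is the target rate passed through the inverse activation.
#'
#' @param theta_true Ground-truth orientation (degrees).
#' @param boundary Decision boundary (degrees).
#' @param neuron_role `"prefers_gt"` (high target for theta >= boundary) or
#'   `"prefers_lt"`.
#' @param r_low_star,r_high_star Positive target rates (s^-1).
#' @param u_ref Reference potential of the activation (mV): output rates are
#'   read out as rho(u_s - u_ref), so target potentials are
#'   u_ref + rho^-1(rate). With the reference at the resting potential the
#'   low target rate maps to a potential just above rest and the high rate
#'   to a depolarised but reachable potential, keeping both targets inside
#'   the convex hull of the reversal potentials.
#' @param activation Activation kind; only `"softplus"` is supported.
#'
#' @return Target potential mean (mV).
#' @export
target_potential <- function(theta_true, boundary = 45,
                             neuron_role = c("prefers_gt", "prefers_lt"),
                             r_low_star = 0.75, r_high_star = 16,
                             u_ref = 0, activation = "softplus") {
  neuron_role <- match.arg(neuron_role)
  stopifnot(identical(activation, "softplus"))
  high_side <- theta_true >= boundary
  if (neuron_role == "prefers_lt") high_side <- !high_side
  u_ref + softplus_inv(ifelse(high_side, r_high_star, r_low_star))
}
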