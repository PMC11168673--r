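#' Decision from the two output-neuron rates
#'
#' Combines the rate `r0` of the neuron preferring orientations above the
#' boundary with the rate `r1` of its counterpart into
#' r = 0.5 (r0 + (r_low + r_high - r1)) and decides "at or above the
#' boundary" iff r >= r_low + 0.5 (r_high - r_low). Ties count as the ">="
#' side. Vectorised.
#'
#' @param r0,r1 Output rates (s^-1).
#' @param r_low,r_high Low/high reference rates (s^-1).
#'
#' @return Logical vector: `TRUE` for the ">= boundary" decision.
#' @export
classify_output <- function(r0, r1, r_low = 0.75, r_high = 16) {
  stopifnot(all(r0 >= 0), all(r1 >= 0))
  r <- 0.5 * (r0 + (r_low + r_high - r1))
  r >= r_low + 0.5 * (r_high - r_low)
}

#' Precision-weighted MAP baseline decision
#'
#' The ideal observer knowing the true modality noise amplitudes combines
#' present cues by inverse-variance weighting,
#' theta_hat = (theta_V / sigma_V^2 + theta_T / sigma_T^2) /
#' (1 / sigma_V^2 + 1 / sigma_T^2), and compares against the boundary.
#' Absent cues (`NA`) drop out. Vectorised.
#'
#' @param theta_V,theta_T Cue orientations (degrees), `NA` when absent.
#' @param sigma_V,sigma_T Modality noise amplitudes (degrees).
#' @param boundary Decision boundary (degrees).
#'
#' @return Logical vector: `TRUE` for ">= boundary".
#' @export
map_baseline <- function(theta_V, theta_T, sigma_V, sigma_T, boundary = 45) {
  w_V <- ifelse(is.na(theta_V), 0, 1 / sigma_V^2)
  w_T <- ifelse(is.na(theta_T), 0, 1 / sigma_T^2)
  if (any(w_V + w_T == 0)) stop("at least one cue must be present", call. = FALSE)
  est <- (ifelse(is.na(theta_V), 0, theta_V) * w_V +
            ifelse(is.na(theta_T), 0, theta_T) * w_T) / (w_V + w_T)
  est >= boundary
}

#' Unweighted-average baseline decision
#'
#' Averages the present cues with equal weights and compares against the
#' boundary; with unequal modality reliabilities this ignores available
#' precision information and performs worse than [map_baseline()].
#'
#' @inheritParams map_baseline
#' @return Logical vector: `TRUE` for ">= boundary".
#' @export
unweighted_baseline <- function(theta_V, theta_T, boundary = 45) {
  present <- (!is.na(theta_V)) + (!is.na(theta_T))
  if (any(present == 0)) stop("at least one cue must be present", call. = FALSE)
  est <- (ifelse(is.na(theta_V), 0, theta_V) +
            ifelse(is.na(theta_T), 0, theta_T)) / present
  est >= boundary
}

#' Closed-form accuracy of the MAP rule under bimodal cues
#'
#' For ground truth uniform on `[theta_min, theta_max]` and both cues
#' present, the combined estimate is Gaussian around the truth with variance
#' 1 / (1/sigma_V^2 + 1/sigma_T^2); the probability of a correct decision at
#' truth theta is a Gaussian tail probability, integrated over the truth by
#' 1-D quadrature.
#'
#' @inheritParams map_baseline
#' @param theta_min,theta_max Ground-truth range (degrees).
#'
#' @return Expected accuracy (proportion correct).
#' @export
map_accuracy_quadrature <- function(sigma_V, sigma_T, boundary = 45,
                                    theta_min = -135, theta_max = 225) {
  sigma_c <- sqrt(1 / (1 / sigma_V^2 + 1 / sigma_T^2))
  p_correct <- function(theta) {
    p_ge <- stats::pnorm((theta - boundary) / sigma_c)
    ifelse(theta >= boundary, p_ge, 1 - p_ge)
  }
  stats::integrate(p_correct, theta_min, theta_max,
                   rel.tol = 1e-10)$value / (theta_max - theta_min)
}
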