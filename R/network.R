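#' Build the multimodal discrimination network
#'
#' Two output neurons, each with three dendritic compartments: one receiving
#' the visual detector bank, one the tactile bank, and one a single
#' prior-adjusting afferent firing at a constant rate (its plastic E/I
#' weights let the neuron learn its prior). Couplings are infinitely strong
#' and the soma operates in the instantaneous (zero-capacitance) limit.
#' Initial weights are drawn uniformly from the configured ranges using the
#' current RNG.
#'
#' @param config A [multimodal_config()].
#'
#' @return A list of class `multimodal_network` with fields `neurons` (list
#'   of two [neuron_config()]; the first prefers orientations above the
#'   boundary), `bank_V`, `bank_T`, `config`, and `trained` flag.
#' @export
build_multimodal_network <- function(config = multimodal_config()) {
  stopifnot(inherits(config, "multimodal_config"))
  bank <- function() detector_bank(
    n = config$n_detectors,
    theta_min = config$theta_fd_min_deg, theta_max = config$theta_fd_max_deg,
    kappa = config$kappa_deg2, r_min = config$r_min_hz, r_max = config$r_max_hz)
  rev <- reversal_potentials(config$E_exc_mV, config$E_inh_mV, config$E_leak_mV)
  soma <- soma_state(g0 = config$g0_nS, E0 = config$E0_mV, C = 0,
                     lambda_e = config$lambda_e)
  make_dend <- function(n_aff) {
    dendrite_state(
      w_exc = stats::runif(n_aff, config$w_init_exc_min, config$w_init_exc_max),
      w_inh = stats::runif(n_aff, config$w_init_inh_min, config$w_init_inh_max),
      g_leak = config$g_leak_dend_nS, g_sd = Inf, g_ds = Inf)
  }
  neurons <- lapply(1:2, function(k) {
    neuron_config(soma,
                  dendrites = list(make_dend(config$n_detectors),  # visual
                                   make_dend(config$n_detectors),  # tactile
                                   make_dend(1L)),                 # prior afferent
                  rev = rev)
  })
  structure(list(neurons = neurons, bank_V = bank(), bank_T = bank(),
                 config = config, trained = FALSE),
            class = "multimodal_network")
}

#' Per-dendrite rate lists for a cue pair
#'
#' Maps (possibly absent) visual/tactile cues through the network's detector
#' banks, applies contrast scaling, and appends the constant prior-afferent
#' rate. Absent cues (`NA`) silence the modality.
#'
#' @param network A `multimodal_network`.
#' @param theta_V,theta_T Cue orientations (degrees) or `NA`.
#' @param c_V,c_T Stimulus contrasts.
#'
#' @return A list of three rate vectors (visual, tactile, prior).
#' @export
cue_rates <- function(network, theta_V, theta_T, c_V = 1, c_T = 1) {
  cfg <- network$config
  r_V <- if (is.na(theta_V)) rep(0, cfg$n_detectors) else
    contrast_scale(tuning_rate(theta_V, network$bank_V), c_V)
  r_T <- if (is.na(theta_T)) rep(0, cfg$n_detectors) else
    contrast_scale(tuning_rate(theta_T, network$bank_T), c_T)
  list(r_V, r_T, cfg$prior_rate_hz)
}

#' Pooled posterior for many trials at once
#'
#' Vectorised counterpart of [neuron_posterior()]: rates for each dendrite
#' are supplied as an `n_trials x n_afferents` matrix (or a length-n vector
#' for single-afferent dendrites) and the pooled mean and conductance are
#' returned per trial.
#'
#' @param neuron A [neuron_config()].
#' @param rate_mats List (one per dendrite) of rate matrices/vectors.
#'
#' @return A tibble with columns `E_bar`, `g_bar`, one row per trial.
#' @export
posterior_matrix <- function(neuron, rate_mats) {
  stopifnot(length(rate_mats) == length(neuron$dendrites))
  rev <- neuron$rev
  num <- NULL
  den <- NULL
  for (i in seq_along(neuron$dendrites)) {
    d <- neuron$dendrites[[i]]
    R <- rate_mats[[i]]
    if (is.null(dim(R))) R <- matrix(R, ncol = length(d$w_exc))
    g_exc <- as.numeric(R %*% d$w_exc)
    g_inh <- as.numeric(R %*% d$w_inh)
    g_d <- g_exc + g_inh + d$g_leak
    gE_d <- g_exc * rev$E_exc + g_inh * rev$E_inh + d$g_leak * rev$E_leak
    alpha <- if (is.infinite(d$g_sd)) 1 else d$g_sd / (d$g_ds + g_d)
    w <- alpha * g_d
    contrib_num <- ifelse(g_d > 0, alpha * gE_d, 0)
    contrib_den <- ifelse(g_d > 0, w, 0)
    num <- if (is.null(num)) contrib_num else num + contrib_num
    den <- if (is.null(den)) contrib_den else den + contrib_den
  }
  g_bar <- neuron$soma$g0 + den
  E_bar <- (neuron$soma$g0 * neuron$soma$E0 + num) / g_bar
  tibble::tibble(E_bar = E_bar, g_bar = g_bar)
}

#' @export
print.multimodal_network <- function(x, ...) {
  cat(sprintf("<multimodal_network> %s; %d detectors/modality, kappa = %.3g deg^-2\n",
              if (x$trained) "trained" else "untrained",
              x$config$n_detectors, x$config$kappa_deg2))
  invisible(x)
}
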