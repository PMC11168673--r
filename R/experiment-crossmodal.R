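#' Cross-modal suppression contrast sweep
#'
#' Fixes conflicting visual and tactile cues (both on the preferred side of
#' the boundary, with the visual cue closer to it) and sweeps the stimulus
#' contrast, which scales all feature-detector rates of a modality, over a
#' log grid. The output rate of the boundary-preferring neuron is computed
#' in the noise-free instantaneous limit for visual-only, tactile-only and
#' bimodal stimulation. At vanishing contrast all three conditions collapse
#' onto the prior-driven rate; at low contrast the bimodal response exceeds
#' both unimodal ones (two weak pieces of evidence add); at high contrast
#' the somatic potential becomes the conductance-weighted convex combination
#' of the two synaptic reversal potentials, so the bimodal response falls
#' between the unimodal asymptotes -- cross-modal suppression.
#'
#' @param network A trained `multimodal_network`.
#' @param config A [crossmodal_config()].
#'
#' @return An object of class `crossmodal_result` / `bd_experiment` with
#'   `sweep` (tibble: contrast, condition, E_bar, g_bar, rate),
#'   `asymptotes` (analytic high-contrast potentials/rates and the
#'   prior-driven rate) and `regimes` (contrast at which the bimodal rate
#'   stops exceeding both unimodal rates).
#' @export
run_crossmodal_suppression <- function(network,
                                       config = crossmodal_config()) {
  if (!inherits(network, "multimodal_network") || !isTRUE(network$trained)) {
    stop("run_crossmodal_suppression requires a trained multimodal network",
         call. = FALSE)
  }
  ncfg <- network$config
  contrasts <- 10^seq(log10(config$contrast_min), log10(config$contrast_max),
                      length.out = config$n_contrasts)
  neuron <- network$neurons[[1]]  # prefers orientations above the boundary
  rate_of <- function(c_V, c_T) {
    out <- network_rates(network, config$theta_V_deg, config$theta_T_deg,
                         c_V = c_V, c_T = c_T)
    tibble::tibble(E_bar = out$E_bar_0, g_bar = out$g_bar_0,
                   rate = config$r_scale * out$r0)
  }
  sweep <- dplyr::bind_rows(lapply(contrasts, function(cc) {
    dplyr::bind_rows(
      dplyr::mutate(rate_of(cc, 0), condition = "V", contrast = cc),
      dplyr::mutate(rate_of(0, cc), condition = "T", contrast = cc),
      dplyr::mutate(rate_of(cc, cc), condition = "VT", contrast = cc))
  }))

  # Analytic high-contrast asymptotes: leaks, prior afferent and soma drop
  # out relative to the c-scaled synaptic conductances.
  syn <- function(dend, theta, bank) {
    r <- tuning_rate(theta, bank)
    g_exc <- sum(dend$w_exc * r)
    g_inh <- sum(dend$w_inh * r)
    list(g = g_exc + g_inh,
         gE = g_exc * network$neurons[[1]]$rev$E_exc +
           g_inh * network$neurons[[1]]$rev$E_inh)
  }
  sV <- syn(neuron$dendrites[[1]], config$theta_V_deg, network$bank_V)
  sT <- syn(neuron$dendrites[[2]], config$theta_T_deg, network$bank_T)
  E_inf_V <- sV$gE / sV$g
  E_inf_T <- sT$gE / sT$g
  E_inf_VT <- (sV$gE + sT$gE) / (sV$g + sT$g)
  prior_rate <- rate_of(0, 0)$rate
  asymptotes <- tibble::tibble(
    condition = c("V", "T", "VT", "none"),
    E_inf = c(E_inf_V, E_inf_T, E_inf_VT, NA_real_),
    rate_inf = c(config$r_scale *
                   softplus(c(E_inf_V, E_inf_T, E_inf_VT) - ncfg$u_ref_mV),
                 prior_rate))

  wide <- tidyr::pivot_wider(sweep[, c("contrast", "condition", "rate")],
                             names_from = "condition", values_from = "rate")
  enh <- wide$VT > pmax(wide$V, wide$T)
  crossover <- if (any(enh) && any(!enh)) {
    wide$contrast[which(!enh)[1]]
  } else NA_real_
  structure(list(sweep = sweep, asymptotes = asymptotes,
                 regimes = tibble::tibble(
                   enhancement_at_min = enh[1],
                   suppression_at_max = !enh[length(enh)],
                   crossover_contrast = crossover),
                 config = config),
            class = c("crossmodal_result", "bd_experiment"))
}
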