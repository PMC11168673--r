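#' Reversal potentials of a conductance-based compartment
#'
#' Bundles the excitatory, inhibitory and leak reversal potentials shared by
#' all compartments of a neuron. The default values are typical cortical
#' values (AMPA-like excitation at 0 mV, GABA-A-like inhibition at -85 mV,
#' leak at -70 mV).
#'
#' @param E_exc Excitatory reversal potential (mV).
#' @param E_inh Inhibitory reversal potential (mV).
#' @param E_leak Leak reversal potential (mV).
#'
#' @return An object of class `reversal_potentials`.
#' @export
#' @examples
#' rev <- reversal_potentials()
#' effective_reversal(g_exc = 1, g_inh = 1, g_leak = 0, rev = rev)
reversal_potentials <- function(E_exc = 0, E_inh = -85, E_leak = -70) {
  stopifnot(is.numeric(E_exc), is.numeric(E_inh), is.numeric(E_leak))
  if (!(E_inh < E_leak && E_leak < E_exc)) {
    stop("reversal potentials must satisfy E_inh < E_leak < E_exc", call. = FALSE)
  }
  structure(list(E_exc = E_exc, E_inh = E_inh, E_leak = E_leak),
            class = "reversal_potentials")
}

#' Somatic compartment parameters
#'
#' The soma carries an intrinsic conductance `g0` with induced reversal
#' potential `E0` (the leak, absent perisomatic synaptic input), a membrane
#' capacitance `C` and the exploration constant `lambda_e` that converts
#' conductance into membrane-potential variance (variance = lambda_e / g).
#'
#' @param g0 Somatic conductance (nS).
#' @param E0 Somatic reversal potential (mV).
#' @param C Somatic capacitance (pF). `0` flags the instantaneous limit.
#' @param lambda_e Exploration constant (nS mV^2); must be positive.
#'
#' @return An object of class `soma_state`.
#' @export
soma_state <- function(g0 = 1, E0 = -70, C = 50, lambda_e = 1) {
  stopifnot(g0 >= 0, lambda_e > 0, C >= 0)
  structure(list(g0 = g0, E0 = E0, C = C, lambda_e = lambda_e),
            class = "soma_state")
}

#' Dendritic compartment with excitatory/inhibitory afferents
#'
#' A compartment receives a vector of presynaptic afferents through excitatory
#' weights `w_exc` and inhibitory weights `w_inh` (both nS s, so that
#' conductance = weight x rate), plus a local leak. `g_sd`/`g_ds` are the
#' dendro-somatic and somato-dendritic coupling conductances; `Inf` flags the
#' strong-coupling limit in which the attenuation factor is exactly 1.
#'
#' @param w_exc,w_inh Non-negative synaptic weight vectors (nS s), one entry
#'   per afferent; recycled to common length.
#' @param g_leak Local leak conductance (nS).
#' @param g_sd,g_ds Coupling conductances (nS); may be `Inf`.
#' @param C_d Dendritic capacitance (pF), used by the full two-compartment
#'   integrator only.
#'
#' @return An object of class `dendrite_state`.
#' @export
dendrite_state <- function(w_exc, w_inh, g_leak = 0.2,
                           g_sd = Inf, g_ds = Inf, C_d = 1) {
  n <- max(length(w_exc), length(w_inh))
  w_exc <- rep_len(as.numeric(w_exc), n)
  w_inh <- rep_len(as.numeric(w_inh), n)
  if (any(w_exc < 0) || any(w_inh < 0)) {
    stop("synaptic weights must be non-negative", call. = FALSE)
  }
  stopifnot(g_leak >= 0, g_sd > 0, g_ds > 0, C_d > 0)
  if (is.infinite(g_sd) != is.infinite(g_ds)) {
    stop("coupling conductances must be jointly finite or jointly infinite",
         call. = FALSE)
  }
  structure(list(w_exc = w_exc, w_inh = w_inh, g_leak = g_leak,
                 g_sd = g_sd, g_ds = g_ds, C_d = C_d),
            class = "dendrite_state")
}

#' Full neuron configuration
#'
#' @param soma A [soma_state()].
#' @param dendrites A list of [dendrite_state()] objects.
#' @param rev A [reversal_potentials()] object shared by all compartments.
#'
#' @return An object of class `neuron_config`.
#' @export
neuron_config <- function(soma, dendrites = list(), rev = reversal_potentials()) {
  stopifnot(inherits(soma, "soma_state"), inherits(rev, "reversal_potentials"))
  ok <- vapply(dendrites, inherits, logical(1), what = "dendrite_state")
  if (!all(ok)) stop("`dendrites` must be a list of dendrite_state objects", call. = FALSE)
  structure(list(soma = soma, dendrites = dendrites, rev = rev),
            class = "neuron_config")
}

#' Effective reversal potential of a compartment
#'
#' Conductance-weighted mean of the synaptic and leak reversal potentials:
#' the potential an isolated compartment relaxes to. The result always lies
#' in the convex hull of the contributing reversal potentials.
#'
#' @param g_exc,g_inh,g_leak Non-negative conductances (nS); vectors recycle.
#' @param rev A [reversal_potentials()] object.
#'
#' @return Effective reversal potential(s) in mV.
#' @export
effective_reversal <- function(g_exc, g_inh, g_leak, rev = reversal_potentials()) {
  if (any(g_exc < 0) || any(g_inh < 0) || any(g_leak < 0)) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  tot <- g_exc + g_inh + g_leak
  if (any(tot <= 0)) {
    stop("degenerate input: total compartment conductance must be positive",
         call. = FALSE)
  }
  (g_exc * rev$E_exc + g_inh * rev$E_inh + g_leak * rev$E_leak) / tot
}

#' Dendro-somatic coupling attenuation factor
#'
#' The influence of a dendrite on the soma (and vice versa) is attenuated by
#' alpha = g_coupling / (g_ds + g_d), where `g_d` is the isolated dendritic
#' conductance. For the soma-bound direction the numerator is `g_sd`, for the
#' dendrite-bound direction `g_ds`. Infinite coupling yields exactly 1.
#'
#' @param dendrite A [dendrite_state()].
#' @param direction `"dendrite_to_soma"` (numerator `g_sd`) or
#'   `"soma_to_dendrite"` (numerator `g_ds`).
#' @param g_dendrite Isolated dendritic conductance g_d (nS).
#'
#' @return Dimensionless factor in `[0, 1]`.
#' @export
coupling_factor <- function(dendrite,
                            direction = c("dendrite_to_soma", "soma_to_dendrite"),
                            g_dendrite) {
  direction <- match.arg(direction)
  stopifnot(g_dendrite >= 0)
  g_num <- switch(direction, dendrite_to_soma = dendrite$g_sd,
                  soma_to_dendrite = dendrite$g_ds)
  if (is.infinite(g_num)) return(1)
  g_num / (dendrite$g_ds + g_dendrite)
}

# Fast internal compartment summary on plain vectors (hot loop of training).
dend_summary_fast <- function(neuron, rates) {
  dends <- neuron$dendrites
  D <- length(dends)
  g_exc <- g_inh <- g_d <- E_d <- alpha_sd <- alpha_ds <- numeric(D)
  rev <- neuron$rev
  for (i in seq_len(D)) {
    d <- dends[[i]]
    r <- rates[[i]]
    if (length(r) == 1L && length(d$w_exc) > 1L) r <- rep_len(r, length(d$w_exc))
    ge <- sum(d$w_exc * r)
    gi <- sum(d$w_inh * r)
    gd <- ge + gi + d$g_leak
    g_exc[i] <- ge; g_inh[i] <- gi; g_d[i] <- gd
    E_d[i] <- if (gd > 0)
      (ge * rev$E_exc + gi * rev$E_inh + d$g_leak * rev$E_leak) / gd else NA_real_
    alpha_sd[i] <- if (is.infinite(d$g_sd)) 1 else d$g_sd / (d$g_ds + gd)
    alpha_ds[i] <- if (is.infinite(d$g_ds)) 1 else d$g_ds / (d$g_ds + gd)
  }
  list(g_exc = g_exc, g_inh = g_inh, g_d = g_d, E_d = E_d,
       alpha_sd = alpha_sd, alpha_ds = alpha_ds)
}

pool_fast <- function(soma, summ) {
  w <- summ$alpha_sd * summ$g_d
  keep <- w > 0
  g_bar <- soma$g0 + sum(w[keep])
  if (g_bar <= 0) stop("degenerate input: pooled conductance must be positive",
                       call. = FALSE)
  E_bar <- (soma$g0 * soma$E0 + sum(w[keep] * summ$E_d[keep])) / g_bar
  structure(list(E_bar = E_bar, g_bar = g_bar, lambda_e = soma$lambda_e),
            class = "pooled_posterior")
}

#' Summarise dendritic compartments for given presynaptic rates
#'
#' Evaluates, per compartment, the synaptic conductances g_exc = sum(w_exc r),
#' g_inh = sum(w_inh r), the isolated dendritic conductance
#' g_d = g_exc + g_inh + g_leak, the effective reversal potential E_d and the
#' coupling factors.
#'
#' @param neuron A [neuron_config()].
#' @param rates List of non-negative rate vectors (s^-1), one per dendrite,
#'   each matching that dendrite's number of afferents.
#'
#' @return A tibble with one row per dendrite and columns `g_exc`, `g_inh`,
#'   `g_d`, `E_d`, `alpha_sd`, `alpha_ds`.
#' @export
dendrite_summary <- function(neuron, rates) {
  dends <- neuron$dendrites
  if (length(rates) != length(dends)) {
    stop("`rates` must supply one rate vector per dendrite", call. = FALSE)
  }
  for (i in seq_along(dends)) {
    r <- as.numeric(rates[[i]])
    if (length(r) != 1L && length(r) != length(dends[[i]]$w_exc)) {
      stop("rate vector length does not match number of afferents", call. = FALSE)
    }
    if (any(r < 0)) stop("presynaptic rates must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(dend_summary_fast(neuron, rates))
}

#' Pool prior and dendritic opinions into the somatic posterior
#'
#' Precision-weighted (conductance-weighted) fusion: the pooled somatic
#' reversal potential is the convex combination of the somatic and dendritic
#' effective reversal potentials weighted by their coupling-attenuated
#' conductances, and the pooled conductance is their sum. The result
#' parametrises a Gaussian over the somatic potential with mean `E_bar` and
#' variance `lambda_e / g_bar`.
#'
#' @param soma A [soma_state()].
#' @param dendrites A data frame with columns `E_d`, `g_d` and a coupling
#'   column `alpha_sd` (or `alpha`), e.g. from [dendrite_summary()]. May have
#'   zero rows (prior-only pooling).
#'
#' @return An object of class `pooled_posterior` with fields `E_bar` (mV),
#'   `g_bar` (nS) and `lambda_e`.
#' @export
pool_posterior <- function(soma, dendrites = NULL) {
  if (is.null(dendrites) || nrow(dendrites) == 0L) {
    alpha <- g_d <- E_d <- numeric(0)
  } else {
    alpha <- if ("alpha_sd" %in% names(dendrites)) dendrites$alpha_sd else dendrites$alpha
    g_d <- dendrites$g_d
    E_d <- dendrites$E_d
  }
  w <- alpha * g_d
  # a fully silent dendrite (g_d = 0) carries no opinion and drops out
  drop <- w == 0
  g_bar <- soma$g0 + sum(w[!drop])
  if (g_bar <= 0) {
    stop("degenerate input: pooled conductance must be positive", call. = FALSE)
  }
  E_bar <- (soma$g0 * soma$E0 + sum(w[!drop] * E_d[!drop])) / g_bar
  structure(list(E_bar = E_bar, g_bar = g_bar, lambda_e = soma$lambda_e),
            class = "pooled_posterior")
}

#' Somatic posterior of a neuron for given presynaptic rates
#'
#' Convenience wrapper: [dendrite_summary()] followed by [pool_posterior()].
#'
#' @inheritParams dendrite_summary
#' @return A `pooled_posterior`.
#' @export
neuron_posterior <- function(neuron, rates) {
  pool_posterior(neuron$soma, dendrite_summary(neuron, rates))
}

#' Somatic energy function
#'
#' The quadratic energy whose gradient descent generates the somatic
#' dynamics: E(u) = (g_bar / 2) (u - E_bar)^2, in nS mV^2. It equals
#' -lambda_e log p(u) up to an additive constant, so the noise-free somatic
#' dynamics descend the energy while ascending the log-posterior.
#'
#' @param u_s Somatic potential(s), mV.
#' @param pooled A `pooled_posterior`.
#'
#' @return Energy value(s), nS mV^2.
#' @export
energy <- function(u_s, pooled) {
  (pooled$g_bar / 2) * (u_s - pooled$E_bar)^2
}

#' Gradient of the somatic energy
#'
#' Returns -dE/du = g_bar (E_bar - u), the drift of the somatic dynamics
#' (nS mV, i.e. pA).
#'
#' @inheritParams energy
#' @export
energy_gradient <- function(u_s, pooled) {
  pooled$g_bar * (pooled$E_bar - u_s)
}

#' Conductance-plane representation of a compartment
#'
#' A compartment with inhibitory and excitatory conductances (g_inh, g_exc)
#' is a vector in the conductance plane; its intersection with the
#' antidiagonal x + y = 1 gives normalised coordinates and realises the
#' convex combination that maps conductances to the membrane potential
#' (leak neglected).
#'
#' @param g_inh,g_exc Conductances (nS), vectors recycle; their sum must be
#'   positive.
#' @param rev A [reversal_potentials()] object.
#'
#' @return A tibble with columns `x`, `y` (antidiagonal coordinates,
#'   x + y = 1) and `potential` (mV).
#' @export
conductance_plane_point <- function(g_inh, g_exc, rev = reversal_potentials()) {
  if (any(g_inh < 0) || any(g_exc < 0)) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  tot <- g_inh + g_exc
  if (any(tot <= 0)) {
    stop("degenerate input: g_inh + g_exc must be positive", call. = FALSE)
  }
  tibble::tibble(
    x = g_inh / tot,
    y = g_exc / tot,
    potential = (g_inh * rev$E_inh + g_exc * rev$E_exc) / tot
  )
}

#' @export
print.pooled_posterior <- function(x, ...) {
  cat(sprintf(
    "<pooled_posterior> E_bar = %.3f mV, g_bar = %.4f nS, sd = %.4f mV\n",
    x$E_bar, x$g_bar, sqrt(x$lambda_e / x$g_bar)))
  invisible(x)
}

#' @export
print.neuron_config <- function(x, ...) {
  cat(sprintf("<neuron_config> %d dendrite(s); g0 = %.3f nS, E0 = %.1f mV, C = %g pF, lambda_e = %g nS mV^2\n",
              length(x$dendrites), x$soma$g0, x$soma$E0, x$soma$C, x$soma$lambda_e))
  invisible(x)
}
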