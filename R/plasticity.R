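#' Gradient of the log-posterior with respect to synaptic weights
#'
#' The plasticity rule performs stochastic gradient ascent on
#' lambda_e * log p(u* | W, r), where u* is a sample from the target
#' potential distribution. For afferent j of dendrite i with presynaptic rate
#' r_j the excitatory/inhibitory weight derivative is
#'
#'   alpha_sd * \[ (u* - E_bar)(E_exc/inh - E_tilde)
#'               + (alpha_ds / 2)(lambda_e / g_bar - (u* - E_bar)^2) \] * r_j
#'
#' with E_tilde = alpha_ds * E_bar + (1 - alpha_ds) * E_d. The first bracket
#' term corrects the pooled mean, the second matches the pooled variance;
#' under infinitely strong coupling both alphas equal 1 and E_tilde = E_bar.
#'
#' @param u_star Target potential sample (mV).
#' @param pooled The neuron's current `pooled_posterior`.
#' @param dend One row of [dendrite_summary()] (fields `E_d`, `alpha_sd`,
#'   `alpha_ds`) for the dendrite being updated.
#' @param rates Presynaptic rate vector of that dendrite (s^-1).
#' @param rev A [reversal_potentials()] object.
#'
#' @return A list with per-afferent derivative vectors `d_w_exc`, `d_w_inh`
#'   (nS s per unit time) and scalar diagnostics `delta_mu_exc`,
#'   `delta_mu_inh` (mean-error terms, mV^2) and `delta_sigma2`
#'   (variance-error term, mV^2).
#' @export
weight_gradient <- function(u_star, pooled, dend, rates,
                            rev = reversal_potentials()) {
  rates <- as.numeric(rates)
  err <- u_star - pooled$E_bar
  E_tilde <- dend$alpha_ds * pooled$E_bar + (1 - dend$alpha_ds) * dend$E_d
  delta_mu_exc <- err * (rev$E_exc - E_tilde)
  delta_mu_inh <- err * (rev$E_inh - E_tilde)
  delta_sigma2 <- (dend$alpha_ds / 2) *
    (pooled$lambda_e / pooled$g_bar - err^2)
  list(
    d_w_exc = dend$alpha_sd * (delta_mu_exc + delta_sigma2) * rates,
    d_w_inh = dend$alpha_sd * (delta_mu_inh + delta_sigma2) * rates,
    delta_mu_exc = delta_mu_exc,
    delta_mu_inh = delta_mu_inh,
    delta_sigma2 = delta_sigma2
  )
}

#' Gradients for all dendrites of a neuron
#'
#' @inheritParams weight_gradient
#' @param neuron A [neuron_config()].
#' @param rates Per-dendrite list of rate vectors.
#' @param summ Optional precomputed [dendrite_summary()].
#' @param pooled Optional precomputed pooled posterior.
#'
#' @return A list (one element per dendrite) of [weight_gradient()] results.
#' @export
neuron_weight_gradient <- function(neuron, rates, u_star,
                                   summ = NULL, pooled = NULL) {
  if (is.null(summ)) summ <- dend_summary_fast(neuron, rates)
  if (is.null(pooled)) pooled <- pool_fast(neuron$soma, summ)
  lapply(seq_along(neuron$dendrites), function(i) {
    r <- rates[[i]]
    if (length(r) == 1L) r <- rep_len(r, length(neuron$dendrites[[i]]$w_exc))
    dend_i <- list(E_d = summ$E_d[i], alpha_sd = summ$alpha_sd[i],
                   alpha_ds = summ$alpha_ds[i])
    weight_gradient(u_star, pooled, dend_i, r, neuron$rev)
  })
}

#' Apply a (batch of) weight gradient(s) with non-negativity
#'
#' Weights move by the learning rate times the batch-mean gradient and are
#' clipped at zero: conductance-based synapses cannot have negative weights.
#'
#' @param weights Numeric weight vector (nS s).
#' @param gradients A numeric gradient vector, or a list of such vectors
#'   (a batch), matching `weights` in length.
#' @param eta Positive learning rate.
#'
#' @return Updated weight vector.
#' @export
apply_update <- function(weights, gradients, eta) {
  stopifnot(eta > 0)
  if (is.list(gradients)) {
    gradients <- Reduce(`+`, gradients) / length(gradients)
  }
  pmax(0, weights + eta * gradients)
}

#' Train a neuron on samples from a target potential distribution
#'
#' Runs the gradient plasticity rule in the instantaneous-soma regime: on
#' each trial the sampler supplies presynaptic rates and a target potential
#' sample u*, the pooled posterior is computed in the C -> 0 limit, and all
#' excitatory/inhibitory weights move along the log-posterior gradient
#' (batch-averaged for `batch_size > 1`), clipped at zero.
#'
#' @param neuron A [neuron_config()]; its weights are the initial condition.
#' @param trial_sampler `function(trial)` returning
#'   `list(rates = <per-dendrite rate list>, u_star = <mV>)`. Rates and
#'   target may be correlated (they usually share a latent stimulus). Draws
#'   from the current RNG.
#' @param n_trials Number of trials.
#' @param eta Learning rate.
#' @param batch_size Gradients are averaged over this many trials per update.
#' @param log_every Record diagnostics every this many trials (0 = only the
#'   final state).
#' @param w_max_factor Divergence guard: abort if any weight exceeds
#'   `w_max_factor` times the largest initial weight (plus 1 nS s slack).
#'
#' @return A list of class `bd_training` with `neuron` (trained), `log`
#'   (tibble: trial, dendrite, w_exc, w_inh, w_tot, E_bar, g_bar) and
#'   `updates` (tibble of per-update summed E/I weight changes, used for
#'   learning-phase diagnostics).
#' @export
train <- function(neuron, trial_sampler, n_trials, eta,
                  batch_size = 1L, log_every = max(1L, n_trials %/% 200L),
                  w_max_factor = 1e3) {
  stopifnot(eta > 0, batch_size >= 1)
  D <- length(neuron$dendrites)
  w_bound <- w_max_factor *
    max(1, vapply(neuron$dendrites,
                  function(d) max(d$w_exc, d$w_inh), numeric(1)))
  batch <- vector("list", batch_size)
  b <- 0L
  log_rows <- list()
  n_upd <- ceiling(n_trials / batch_size)
  upd_trial <- integer(n_upd)
  upd_exc <- matrix(NA_real_, n_upd, D)
  upd_inh <- matrix(NA_real_, n_upd, D)
  u_ptr <- 0L
  log_state <- function(trial) {
    pooled <- pool_fast(neuron$soma, dend_summary_fast(neuron, last_rates))
    we <- vapply(neuron$dendrites, function(d) sum(d$w_exc), numeric(1))
    wi <- vapply(neuron$dendrites, function(d) sum(d$w_inh), numeric(1))
    tibble::tibble(trial = trial, dendrite = seq_len(D),
                   w_exc = we, w_inh = wi, w_tot = we + wi,
                   E_bar = pooled$E_bar, g_bar = pooled$g_bar)
  }
  last_rates <- NULL
  for (t in seq_len(n_trials)) {
    s <- trial_sampler(t)
    last_rates <- s$rates
    b <- b + 1L
    batch[[b]] <- neuron_weight_gradient(neuron, s$rates, s$u_star)
    if (b == batch_size || t == n_trials) {
      u_ptr <- u_ptr + 1L
      upd_trial[u_ptr] <- t
      for (i in seq_len(D)) {
        if (b == 1L) {
          g_exc <- batch[[1L]][[i]]$d_w_exc
          g_inh <- batch[[1L]][[i]]$d_w_inh
        } else {
          g_exc <- Reduce(`+`, lapply(batch[seq_len(b)], function(x) x[[i]]$d_w_exc)) / b
          g_inh <- Reduce(`+`, lapply(batch[seq_len(b)], function(x) x[[i]]$d_w_inh)) / b
        }
        neuron$dendrites[[i]]$w_exc <- pmax(0, neuron$dendrites[[i]]$w_exc + eta * g_exc)
        neuron$dendrites[[i]]$w_inh <- pmax(0, neuron$dendrites[[i]]$w_inh + eta * g_inh)
        upd_exc[u_ptr, i] <- sum(g_exc)
        upd_inh[u_ptr, i] <- sum(g_inh)
      }
      b <- 0L
      w_now <- max(vapply(neuron$dendrites,
                          function(d) max(d$w_exc, d$w_inh), numeric(1)))
      if (!is.finite(w_now) || w_now > w_bound) {
        stop(sprintf("training diverged at trial %d (max weight %.3g)", t, w_now),
             call. = FALSE)
      }
    }
    if (log_every > 0 && (t %% log_every == 0L || t == n_trials)) {
      log_rows[[length(log_rows) + 1L]] <- dplyr::bind_rows(log_state(t))
    }
  }
  updates <- tibble::tibble(
    trial = rep(upd_trial[seq_len(u_ptr)], each = D),
    dendrite = rep(seq_len(D), u_ptr),
    d_w_exc = as.numeric(t(upd_exc[seq_len(u_ptr), , drop = FALSE])),
    d_w_inh = as.numeric(t(upd_inh[seq_len(u_ptr), , drop = FALSE])))
  structure(list(neuron = neuron,
                 log = dplyr::bind_rows(log_rows),
                 updates = updates),
            class = "bd_training")
}

#' Write a training log to CSV
#'
#' @param training A `bd_training` result.
#' @param path Output path.
#' @export
write_training_log <- function(training, path) {
  utils::write.csv(as.data.frame(training$log), path, row.names = FALSE)
  invisible(path)
}
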