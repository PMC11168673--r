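# Randomised biophysical states used across tests. All draws happen under
# the caller-supplied seed so every test is reproducible in isolation.

random_pooled_inputs <- function(n_dendrites = 3) {
  soma <- soma_state(g0 = runif(1, 0.1, 2), E0 = runif(1, -80, -60),
                     C = runif(1, 10, 100), lambda_e = runif(1, 0.5, 100))
  dend <- tibble::tibble(
    E_d = runif(n_dendrites, -85, 0),
    g_d = runif(n_dendrites, 0.05, 5),
    alpha_sd = runif(n_dendrites, 0.1, 1))
  list(soma = soma, dendrites = dend)
}

random_neuron <- function(n_dendrites = 2, n_afferents = 3, coupling = c(4, 4),
                          lambda_e = 1.5) {
  dends <- lapply(seq_len(n_dendrites), function(i)
    dendrite_state(w_exc = runif(n_afferents, 0, 0.5),
                   w_inh = runif(n_afferents, 0, 0.5),
                   g_leak = runif(1, 0.05, 0.3),
                   g_sd = coupling[1], g_ds = coupling[2]))
  neuron_config(soma_state(g0 = runif(1, 0.2, 1.5), E0 = -70, C = 50,
                           lambda_e = lambda_e),
                dendrites = dends)
}

random_rates <- function(neuron) {
  lapply(neuron$dendrites, function(d) runif(length(d$w_exc), 0.2, 8))
}

# lambda_e * log p(u_star | W, r) through the full pooling pipeline;
# independent of the plasticity rule implementation.
pipeline_logscore <- function(neuron, rates, u_star) {
  p <- neuron_posterior(neuron, rates)
  p$lambda_e * (-p$g_bar / (2 * p$lambda_e) * (u_star - p$E_bar)^2 -
                  0.5 * log(2 * pi * p$lambda_e / p$g_bar))
}
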