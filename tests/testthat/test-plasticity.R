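test_that("weight gradient matches finite differences of the log-score on random states", {
  set.seed(61)
  n_checked <- 0
  for (k in 1:25) {
    coupling <- if (k %% 2 == 0) c(Inf, Inf) else runif(2, 2, 8)[c(1, 1)]
    nr <- random_neuron(n_dendrites = sample(1:3, 1),
                        n_afferents = sample(1:3, 1), coupling = coupling,
                        lambda_e = runif(1, 0.5, 5))
    rates <- random_rates(nr)
    u_star <- runif(1, -85, -20)
    gr <- neuron_weight_gradient(nr, rates, u_star)
    h <- 1e-6
    for (i in seq_along(nr$dendrites)) {
      for (j in seq_along(nr$dendrites[[i]]$w_exc)) {
        for (side in c("w_exc", "w_inh")) {
          np <- nr; np$dendrites[[i]][[side]][j] <- np$dendrites[[i]][[side]][j] + h
          nm <- nr; nm$dendrites[[i]][[side]][j] <- nm$dendrites[[i]][[side]][j] - h
          fd <- (pipeline_logscore(np, rates, u_star) -
                   pipeline_logscore(nm, rates, u_star)) / (2 * h)
          got <- if (side == "w_exc") gr[[i]]$d_w_exc[j] else gr[[i]]$d_w_inh[j]
          expect_equal(got, fd, tolerance = 1e-5)
          n_checked <- n_checked + 1
        }
      }
    }
  }
  expect_gte(n_checked, 100)
})

test_that("gradient vanishes for silent afferents and in expectation at the fixed point", {
  set.seed(62)
  nr <- random_neuron(n_dendrites = 2, n_afferents = 2, coupling = c(Inf, Inf))
  rates <- list(c(0, 3), c(2, 0))
  gr <- neuron_weight_gradient(nr, rates, -50)
  expect_identical(gr[[1]]$d_w_exc[1], 0)
  expect_identical(gr[[2]]$d_w_inh[2], 0)
  # u* ~ posterior makes both error terms vanish in expectation
  p <- neuron_posterior(nr, rates)
  sd_post <- sqrt(p$lambda_e / p$g_bar)
  n <- 2e4
  u_draws <- p$E_bar + sd_post * rnorm(n)
  tot <- Reduce(`+`, lapply(u_draws, function(u)
    neuron_weight_gradient(nr, rates, u)[[1]]$d_w_exc)) / n
  per_draw_sd <- sd(vapply(u_draws[1:2000], function(u)
    neuron_weight_gradient(nr, rates, u)[[1]]$d_w_exc[2], numeric(1)))
  expect_lt(abs(tot[2]), 4 * per_draw_sd / sqrt(n))
})

test_that("updates clip at zero and respect batch-mean identities", {
  w <- c(0.5, 0.2)
  expect_identical(apply_update(w, c(0, 0), eta = 0.1), w)
  upd <- apply_update(w, c(-100, 1), eta = 0.1)
  expect_identical(upd[1], 0)  # clipping is exact
  expect_equal(upd[2], 0.3)
  g <- c(0.3, -0.1)
  expect_equal(apply_update(w, list(g, g, g), eta = 0.5),
               apply_update(w, g, eta = 0.5))
})

test_that("training is stationary at a matched target and frozen at eta ~ 0", {
  set.seed(63)
  nr <- random_neuron(n_dendrites = 2, n_afferents = 1, coupling = c(Inf, Inf))
  rates <- list(2, 3)
  p <- neuron_posterior(nr, rates)
  sd_post <- sqrt(p$lambda_e / p$g_bar)
  sampler <- function(t) list(rates = rates,
                              u_star = p$E_bar + sd_post * rnorm(1))
  w0 <- unlist(lapply(nr$dendrites, function(d) c(d$w_exc, d$w_inh)))
  res <- train(nr, sampler, n_trials = 1000, eta = 1e-5)
  w1 <- unlist(lapply(res$neuron$dendrites, function(d) c(d$w_exc, d$w_inh)))
  # drift bounded by the Monte-Carlo noise floor of the gradient
  g_sd <- sd(vapply(1:500, function(k)
    neuron_weight_gradient(nr, rates, sampler(k)$u_star)[[1]]$d_w_inh, numeric(1)))
  expect_lt(max(abs(w1 - w0)), 5 * 1e-5 * g_sd * sqrt(1000))
  # a vanishing learning rate freezes the weights exactly
  res0 <- train(nr, sampler, n_trials = 50, eta = 1e-300)
  w00 <- unlist(lapply(res0$neuron$dendrites, function(d) c(d$w_exc, d$w_inh)))
  expect_equal(w00, w0)
})

test_that("training aborts on divergence", {
  set.seed(64)
  nr <- random_neuron(n_dendrites = 1, n_afferents = 1, coupling = c(Inf, Inf))
  sampler <- function(t) list(rates = list(5), u_star = -50)
  expect_error(train(nr, sampler, n_trials = 5000, eta = 50,
                     w_max_factor = 10), "diverged")
})

test_that("weights stay non-negative throughout training", {
  set.seed(65)
  nr <- random_neuron(n_dendrites = 2, n_afferents = 1, coupling = c(Inf, Inf))
  sampler <- function(t) list(rates = list(runif(1, 0.5, 3), runif(1, 0.5, 3)),
                              u_star = rnorm(1, -75, 1))
  res <- train(nr, sampler, n_trials = 500, eta = 1e-3,
               log_every = 10)
  expect_true(all(res$log$w_exc >= 0))
  expect_true(all(res$log$w_inh >= 0))
})
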