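test_that("langevin step keeps the fixed point and guards against unstable dt", {
  p <- structure(list(E_bar = -55, g_bar = 2, lambda_e = 1),
                 class = "pooled_posterior")
  expect_equal(langevin_step(-55, p, C = 50, dt = 0.2, noise_draw = 0), -55)
  expect_error(langevin_step(-55, p, C = 0.1, dt = 0.2), "unstable")
})

test_that("noise-free relaxation follows exp(-t / (C / g_bar))", {
  set.seed(12)
  nr <- random_neuron()
  rates <- random_rates(nr)
  p <- neuron_posterior(nr, rates)
  tau <- nr$soma$C / p$g_bar
  traj <- simulate_soma(nr, rates, duration_ms = 8 * tau, dt_ms = 0.05,
                        noise = noise_spec(enabled = FALSE), u0 = -40)
  theory <- p$E_bar + (-40 - p$E_bar) * exp(-traj$time_ms / tau)
  expect_lt(max(abs(traj$u_s - theory)), 0.02)
})

test_that("stationary law matches the pooled posterior (OU moments, 3 SE)", {
  set.seed(13)
  nr <- random_neuron()
  rates <- random_rates(nr)
  p <- neuron_posterior(nr, rates)
  tau <- nr$soma$C / p$g_bar
  dur <- 4e4
  traj <- simulate_soma(nr, rates, dur, dt_ms = 0.2, noise = noise_spec(seed = 99))
  u <- traj$u_s[traj$time_ms > 10 * tau]
  n_eff <- length(u) * 0.2 / (2 * tau)
  sd_th <- sqrt(p$lambda_e / p$g_bar)
  expect_lt(abs(mean(u) - p$E_bar), 3 * sd_th / sqrt(n_eff))
  expect_lt(abs(var(u) - sd_th^2), 3 * sd_th^2 * sqrt(2 / n_eff))
  # autocorrelation time close to C / g_bar
  expect_lt(abs(autocorrelation_time(u, 0.2, max_lag_ms = 8 * tau) - tau),
            0.2 * tau)
})

test_that("identical seeds give bitwise-identical trajectories", {
  set.seed(14)
  nr <- random_neuron()
  rates <- random_rates(nr)
  t1 <- simulate_soma(nr, rates, 50, 0.2, noise_spec(seed = 42))
  t2 <- simulate_soma(nr, rates, 50, 0.2, noise_spec(seed = 42))
  expect_identical(t1$u_s, t2$u_s)
  t3 <- simulate_soma(nr, rates, 50, 0.2, noise_spec(seed = 43))
  expect_false(identical(t1$u_s, t3$u_s))
})

test_that("step stimuli shrink the stationary spread of the somatic potential", {
  set.seed(15)
  nr <- random_neuron()
  weak <- lapply(random_rates(nr), function(r) r * 0.1)
  strong <- lapply(weak, function(r) r * 40)
  sched <- rate_schedule(c(0, 1500), list(weak, strong))
  us <- vapply(1:40, function(k) {
    traj <- simulate_soma(nr, sched, 3000, 0.2, noise_spec(seed = 1000 + k))
    c(pre = var(traj$u_s[traj$time_ms > 700 & traj$time_ms <= 1500]),
      post = var(traj$u_s[traj$time_ms > 2200]))
  }, numeric(2))
  expect_lt(mean(us["post", ]), mean(us["pre", ]))
})

test_that("terminal noise-free potential equals the pooled mean", {
  set.seed(16)
  nr <- random_neuron()
  rates <- random_rates(nr)
  p <- neuron_posterior(nr, rates)
  traj <- simulate_soma(nr, rates, 2000, 0.2, noise_spec(enabled = FALSE),
                        u0 = -80)
  expect_equal(tail(traj$u_s, 1), p$E_bar, tolerance = 1e-6)
})

test_that("full two-compartment dynamics approach the reduced model as C_d shrinks", {
  set.seed(17)
  mk <- function(C_d) neuron_config(
    soma_state(1, -70, 50, 1),
    dendrites = list(dendrite_state(0.4, 0.6, 0.2, 5, 5, C_d = C_d),
                     dendrite_state(0.2, 0.1, 0.2, 5, 5, C_d = C_d)))
  rates <- list(3, 5)
  reduced <- simulate_soma(mk(1), rates, 300, 0.2, noise_spec(enabled = FALSE))
  err <- vapply(c(5, 0.5, 0.05), function(C_d) {
    full <- simulate_full(mk(C_d), rates, 300, 0.2)
    abs(tail(full$u_s, 1) - tail(reduced$u_s, 1))
  }, numeric(1))
  expect_lt(err[3], 0.1)          # singular-perturbation consistency
  expect_true(all(diff(err) < 0)) # monotone in C_d on the ladder
})

test_that("full dynamics steady state satisfies the dendritic gap equation", {
  nr <- neuron_config(
    soma_state(1, -70, 50, 1),
    dendrites = list(dendrite_state(0.5, 0.3, 0.2, 4, 4, C_d = 0.5)))
  rates <- list(2.5)
  traj <- simulate_full(nr, rates, 500, 0.2)
  summ <- dendrite_summary(nr, rates)
  u_s <- tail(traj$u_s, 1)
  u_d <- tail(traj$u_d_1, 1)
  gap_pred <- summ$g_d / (summ$g_d + 4) * (summ$E_d - u_s)
  expect_equal(u_d - u_s, gap_pred, tolerance = 1e-6)
})

test_that("uniform reversal potentials clamp the full dynamics", {
  rev <- reversal_potentials()
  nr <- neuron_config(
    soma_state(1, rev$E_leak, 50, 1),
    dendrites = list(dendrite_state(0, 0, 0.2, 4, 4, C_d = 0.5)), rev = rev)
  traj <- simulate_full(nr, list(1), 100, 0.2, u0 = rev$E_leak)
  expect_true(all(abs(traj$u_s - rev$E_leak) < 1e-8))
})

test_that("noise-free trajectories are invariant under dt refinement", {
  set.seed(18)
  nr <- random_neuron()
  rates <- random_rates(nr)
  coarse <- simulate_soma(nr, rates, 100, 0.2, noise_spec(enabled = FALSE), u0 = -50)
  fine <- simulate_soma(nr, rates, 100, 0.05, noise_spec(enabled = FALSE), u0 = -50)
  finer <- simulate_soma(nr, rates, 100, 0.025, noise_spec(enabled = FALSE), u0 = -50)
  at <- function(traj) traj$u_s[traj$time_ms == 50]
  e1 <- abs(at(coarse) - at(finer))
  e2 <- abs(at(fine) - at(finer))
  expect_lt(e2, e1)  # error decreases at least first order
})

test_that("instantaneous soma returns the MAP and samples the posterior", {
  set.seed(19)
  nr <- random_neuron()
  prior_only <- neuron_config(nr$soma, list(), nr$rev)
  expect_equal(instantaneous_soma(prior_only, list(), mode = "map"),
               nr$soma$E0)
  rates <- random_rates(nr)
  p <- neuron_posterior(nr, rates)
  expect_equal(instantaneous_soma(nr, rates, mode = "map"), p$E_bar)
  draws <- replicate(1e5, instantaneous_soma(nr, rates, mode = "sample"))
  v <- p$lambda_e / p$g_bar
  expect_lt(abs(var(draws) - v), 3 * v * sqrt(2 / 1e5))
  # map mode equals the long-time noise-free limit
  traj <- simulate_soma(nr, rates, 3000, 0.2, noise_spec(enabled = FALSE), u0 = -20)
  expect_equal(tail(traj$u_s, 1), instantaneous_soma(nr, rates, "map"),
               tolerance = 1e-6)
})

test_that("negative rates in a schedule are rejected", {
  nr <- random_neuron()
  expect_error(simulate_soma(nr, list(c(-1, 1, 1), c(1, 1, 1)), 10, 0.2),
               "non-negative")
})
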