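# A small trained network shared by the experiment tests (scaled-down
# training keeps this file fast; ordinal claims survive the scaling).
small_net <- local({
  res <- run_multimodal_task(multimodal_config(scale = 0.02), seed = 11)
  res$network
})

test_that("output classification reduces to a rate comparison", {
  # r0 = high, r1 = low decides the '>= boundary' side and vice versa
  expect_true(classify_output(16, 0.75))
  expect_false(classify_output(0.75, 16))
  # for r0 = r1 the combined rate equals the midpoint: ties go to '>='
  set.seed(71)
  r <- runif(20, 0, 20)
  expect_true(all(classify_output(r, r)))
  # algebraic simplification: decision depends only on sign of r0 - r1
  r0 <- runif(50, 0, 20); r1 <- runif(50, 0, 20)
  expect_identical(classify_output(r0, r1), r0 >= r1)
})

test_that("MAP baseline precision-weights cues and matches its quadrature form", {
  expect_identical(map_baseline(50, 40, 1, 1), TRUE)   # unweighted mean 45
  expect_identical(map_baseline(44, 60, 1, 10), FALSE) # visual dominates
  expect_identical(map_baseline(NA, 60, 1, 10), TRUE)  # single modality
  set.seed(72)
  n <- 2e5
  theta <- runif(n, -135, 225)
  tv <- theta + 13.5 * rnorm(n)
  tt <- theta + 28.5 * rnorm(n)
  acc_mc <- mean(map_baseline(tv, tt, 13.5, 28.5) == (theta >= 45))
  acc_q <- map_accuracy_quadrature(13.5, 28.5)
  expect_lt(abs(acc_mc - acc_q), 3 * sqrt(acc_q * (1 - acc_q) / n))
  # unweighted averaging is strictly worse under unequal noise
  acc_unw <- mean(unweighted_baseline(tv, tt) == (theta >= 45))
  expect_lt(acc_unw, acc_mc)
  # identical cues: both rules agree
  expect_identical(map_baseline(50, 50, 1, 2), unweighted_baseline(50, 50))
})

test_that("psychometric fit recovers known parameters and flags flat data", {
  theta <- seq(20, 70, by = 2.5)
  p_true <- pnorm((theta - 45) / 8)
  set.seed(73)
  p_obs <- pmin(1, pmax(0, p_true + rnorm(length(theta), 0, 0.01)))
  fit <- fit_psychometric(theta, p_obs)
  expect_true(fit$converged)
  expect_lt(abs(fit$threshold - 45) / 45, 0.05)
  expect_lt(abs(fit$scale - 8) / 8, 0.05)
  td <- tidy(fit)
  expect_setequal(td$term, c("threshold", "scale"))
  expect_false(glance(fit_psychometric(theta, rep(0.5, length(theta))))$converged)
})

test_that("variance learning matches the target mean and is reproducible", {
  cfg <- variance_learning_config(n_trials = 2000, n_eval = 500)
  res <- run_variance_learning(cfg, seed = 21)
  # terminal pooled mean within 5% of the E_inh..E_exc dynamic range
  range_mV <- 85
  expect_lt(res$summary$mean_abs_err, 0.05 * range_mV)
  # learning rate ~ 0 freezes the weights
  frozen <- run_variance_learning(
    variance_learning_config(n_trials = 200, n_eval = 100, eta = 1e-300),
    seed = 21)
  w0 <- dplyr::filter(frozen$training$log, trial == min(trial))
  w1 <- dplyr::filter(frozen$training$log, trial == max(trial))
  expect_equal(w1$w_tot, w0$w_tot)
  # same seed reruns bitwise-identically
  res2 <- run_variance_learning(cfg, seed = 21)
  expect_identical(res$summary, res2$summary)
  expect_identical(res$training$log, res2$training$log)
})

test_that("symmetric channel noise yields symmetric terminal weights", {
  cfg <- variance_learning_config(sigma_V = 0.2, sigma_T = 0.2,
                                  n_trials = 4000, n_eval = 500)
  res <- run_variance_learning(cfg, seed = 22)
  expect_lt(abs(res$summary$w_tot_1 - res$summary$w_tot_2) /
              (res$summary$w_tot_1 + res$summary$w_tot_2), 0.1)
})

test_that("multimodal training beats chance and reruns reproducibly", {
  res <- run_multimodal_task(multimodal_config(scale = 0.02), seed = 11)
  acc <- setNames(res$accuracy$accuracy, res$accuracy$condition)
  expect_gt(acc["VT"], 0.85)
  expect_gte(acc["VT"], acc["T"])
  res2 <- run_multimodal_task(multimodal_config(scale = 0.02), seed = 11)
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$network$neurons[[1]]$dendrites[[1]]$w_exc,
                   res2$network$neurons[[1]]$dendrites[[1]]$w_exc)
  # the tibble-facing glance method mirrors the accuracy table
  g <- glance(res)
  expect_equal(g$accuracy_VT, unname(acc["VT"]))
})

test_that("cross-modal sweep collapses to the prior-driven rate at zero contrast", {
  cm <- run_crossmodal_suppression(small_net,
                                   crossmodal_config(contrast_min = 1e-6,
                                                     n_contrasts = 11))
  lowest <- dplyr::filter(cm$sweep, contrast == min(contrast))
  prior_rate <- cm$asymptotes$rate_inf[cm$asymptotes$condition == "none"]
  expect_equal(lowest$rate, rep(prior_rate, 3), tolerance = 1e-3)
  # asymptote is the conductance-weighted convex combination of the
  # unimodal synaptic reversal potentials
  E_inf <- cm$asymptotes$E_inf
  expect_gte(E_inf[3], min(E_inf[1:2]))
  expect_lte(E_inf[3], max(E_inf[1:2]))
  expect_error(run_crossmodal_suppression(build_multimodal_network()),
               "trained")
})

test_that("stimulus-response statistics show the pull to a common reversal", {
  sr <- run_stimulus_response(small_net,
                              stimulus_response_config(n_trials = 16),
                              seed = 5)
  expect_lt(sr$summary$spread_post_mV, sr$summary$spread_pre_mV)
  expect_lt(sr$summary$slope_amp_vs_prestim, 0)
  expect_lt(sr$summary$var_post, sr$summary$var_pre)
  # no-stimulus control: no systematic evoked amplitude, no spread shrink
  ctrl <- run_stimulus_response(
    small_net, stimulus_response_config(n_trials = 16, gamma_after = 0),
    seed = 5)
  amp_sd <- sd(ctrl$trials$amplitude_mV)
  expect_lt(abs(mean(ctrl$trials$amplitude_mV)), 3 * amp_sd / sqrt(16))
  expect_gt(ctrl$summary$spread_post_mV / ctrl$summary$spread_pre_mV, 0.3)
  # identical seeds reproduce the summary bitwise
  sr2 <- run_stimulus_response(small_net,
                               stimulus_response_config(n_trials = 16),
                               seed = 5)
  expect_identical(sr$summary, sr2$summary)
})
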