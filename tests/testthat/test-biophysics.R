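test_that("effective reversal potential is the conductance-weighted mean", {
  rev <- reversal_potentials()
  # symmetric E/I drive lands at the midpoint
  expect_equal(effective_reversal(1, 1, 0, rev), -42.5)
  # leak-only compartment sits at the leak potential
  expect_equal(effective_reversal(0, 0, 0.2, rev), -70)
  # direct one-line weighted-mean evaluation as independent oracle
  g <- c(exc = 2, inh = 1, leak = 0.2)
  oracle <- sum(g * c(0, -85, -70)) / sum(g)
  expect_equal(unname(effective_reversal(g[1], g[2], g[3], rev)),
               unname(oracle))
})

test_that("effective reversal rejects degenerate and negative conductances", {
  expect_error(effective_reversal(0, 0, 0), "degenerate")
  expect_error(effective_reversal(-1, 0, 0.2), "non-negative")
})

test_that("reversal potential ordering is enforced", {
  expect_error(reversal_potentials(E_exc = -90), "E_inh < E_leak < E_exc")
})

test_that("coupling factor covers strong-coupling, symmetric and decoupled limits", {
  d_inf <- dendrite_state(0.1, 0.1, g_sd = Inf, g_ds = Inf)
  expect_identical(coupling_factor(d_inf, "dendrite_to_soma", 5), 1)
  d_sym <- dendrite_state(0.1, 0.1, g_sd = 1, g_ds = 1)
  expect_equal(coupling_factor(d_sym, "dendrite_to_soma", 1), 0.5)
  expect_equal(coupling_factor(d_sym, "soma_to_dendrite", 1), 0.5)
  d_dec <- dendrite_state(0.1, 0.1, g_sd = 1e-12, g_ds = 1)
  expect_lt(coupling_factor(d_dec, "dendrite_to_soma", 1), 1e-12)
  expect_error(dendrite_state(0.1, 0.1, g_sd = Inf, g_ds = 3), "jointly")
})

test_that("pooling reduces to prior and likelihood-dominated limits", {
  soma <- soma_state(g0 = 0.5, E0 = -70, lambda_e = 1)
  p <- pool_posterior(soma)
  expect_equal(p$E_bar, -70)
  expect_equal(p$g_bar, 0.5)
  one <- tibble::tibble(E_d = -40, g_d = 2, alpha_sd = 1)
  p2 <- pool_posterior(soma_state(g0 = 1e-12, E0 = -70, lambda_e = 1), one)
  expect_equal(p2$E_bar, -40, tolerance = 1e-9)
  expect_equal(p2$g_bar, 2, tolerance = 1e-9)
  # two dendrites with equal weight pool to the arithmetic mean
  two <- tibble::tibble(E_d = c(-60, -20), g_d = c(2, 1), alpha_sd = c(0.5, 1))
  p3 <- pool_posterior(soma_state(1e-12, 0, lambda_e = 1), two)
  expect_equal(p3$E_bar, -40, tolerance = 1e-9)
})

test_that("pooling matches the grid oracle and satisfies convexity/additivity", {
  set.seed(101)
  for (k in 1:25) {
    st <- random_pooled_inputs(n_dendrites = sample(1:4, 1))
    p <- pool_posterior(st$soma, st$dendrites)
    g <- grid_posterior_oracle(st$soma, st$dendrites)
    expect_equal(p$E_bar, g$mean, tolerance = 1e-6)
    expect_equal(p$lambda_e / p$g_bar, g$variance, tolerance = 1e-6)
    # convexity: pooled mean within the hull of contributing potentials
    pots <- c(st$soma$E0, st$dendrites$E_d)
    expect_gte(p$E_bar, min(pots))
    expect_lte(p$E_bar, max(pots))
    # precision additivity is exact
    expect_identical(p$g_bar,
                     st$soma$g0 + sum(st$dendrites$alpha_sd * st$dendrites$g_d))
  }
})

test_that("scaling all conductances leaves the pooled mean invariant", {
  set.seed(7)
  st <- random_pooled_inputs()
  p1 <- pool_posterior(st$soma, st$dendrites)
  c_fac <- 3.7
  soma2 <- soma_state(st$soma$g0 * c_fac, st$soma$E0, st$soma$C, st$soma$lambda_e)
  dend2 <- dplyr::mutate(st$dendrites, g_d = g_d * c_fac)
  p2 <- pool_posterior(soma2, dend2)
  expect_equal(p2$E_bar, p1$E_bar)
  expect_equal(p2$g_bar, c_fac * p1$g_bar)
})

test_that("energy is quadratic with analytic gradient and log-density link", {
  set.seed(11)
  for (k in 1:20) {
    st <- random_pooled_inputs()
    p <- pool_posterior(st$soma, st$dendrites)
    expect_identical(energy(p$E_bar, p), 0)
    u <- runif(1, -90, 0)
    h <- 1e-5
    fd <- -(energy(u + h, p) - energy(u - h, p)) / (2 * h)
    expect_equal(energy_gradient(u, p), fd, tolerance = 1e-6)
    # energy differences equal -lambda_e * log-density differences
    sd_post <- sqrt(p$lambda_e / p$g_bar)
    ld <- function(x) dnorm(x, p$E_bar, sd_post, log = TRUE)
    expect_equal(energy(u, p) - energy(p$E_bar, p),
                 -p$lambda_e * (ld(u) - ld(p$E_bar)), tolerance = 1e-8)
  }
})

test_that("conductance-plane point realises the zero-leak convex combination", {
  rev <- reversal_potentials()
  pt <- conductance_plane_point(1, 1, rev)
  expect_equal(pt$x, 0.5)
  expect_equal(pt$potential, (rev$E_inh + rev$E_exc) / 2)
  expect_equal(conductance_plane_point(0, 2, rev)$potential, rev$E_exc)
  set.seed(3)
  g_i <- runif(20, 0.01, 5)
  g_e <- runif(20, 0.01, 5)
  pt2 <- conductance_plane_point(g_i, g_e, rev)
  expect_equal(pt2$x + pt2$y, rep(1, 20))
  expect_equal(pt2$potential, effective_reversal(g_e, g_i, 0, rev))
  expect_error(conductance_plane_point(0, 0), "degenerate")
})

test_that("silent dendrites drop out of the pooled posterior", {
  soma <- soma_state(g0 = 1, E0 = -70, lambda_e = 1)
  dend <- tibble::tibble(E_d = c(NA, -40), g_d = c(0, 2), alpha_sd = c(1, 1))
  p <- pool_posterior(soma, dend)
  expect_equal(p$g_bar, 3)
  expect_equal(p$E_bar, (1 * -70 + 2 * -40) / 3)
})
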