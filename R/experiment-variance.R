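#' Mean/variance learning with two channels of different reliability
#'
#' A single-compartment "target" neuron with fixed random weights converts a
#' latent input rate r ~ Normal(mu_r, sigma_r^2) into target potential
#' samples u* drawn from its somatic posterior. A two-compartment learner
#' receives the same latent rate through two noisy channels (visual:
#' sigma_V, tactile: sigma_T) and adapts its E/I weights with the gradient
#' rule until its somatic distribution matches the targets. At convergence
#' the pooled mean tracks the target mean, the pooled variance
#' lambda_e / g_bar accounts for the residual target spread, and the total
#' weight of each channel is proportional to that channel's reliability.
#'
#' @param config A [variance_learning_config()].
#' @param seed Master seed; separate streams drive initialisation, cue noise
#'   and target sampling.
#'
#' @return An object of class `bd_experiment` (and `variance_learning_result`)
#'   with fields `config`, `seed`, `training` (a `bd_training`), `eval`
#'   (per-trial evaluation tibble) and `summary` (one-row tibble: terminal
#'   mean/variance match and per-dendrite weight shares).
#' @export
run_variance_learning <- function(config = variance_learning_config(), seed = 1) {
  stopifnot(inherits(config, "variance_learning_config"))
  streams <- rng_streams(seed, c("init", "cues", "targets", "eval"))
  rev <- reversal_potentials(config$E_exc_mV, config$E_inh_mV, config$E_leak_mV)
  soma <- soma_state(g0 = config$g0_nS, E0 = config$E0_mV, C = 0,
                     lambda_e = config$lambda_e)

  target_neuron <- with_stream(streams, "init", neuron_config(
    soma,
    dendrites = list(dendrite_state(
      w_exc = stats::runif(1, config$w_target_exc_min, config$w_target_exc_max),
      w_inh = stats::runif(1, config$w_target_inh_min, config$w_target_inh_max),
      g_leak = config$g_leak_dend_nS)),
    rev = rev))
  learner <- with_stream(streams, "init", neuron_config(
    soma,
    dendrites = lapply(seq_len(config$n_dendrites), function(i) dendrite_state(
      w_exc = stats::runif(1, config$w_init_exc_min, config$w_init_exc_max),
      w_inh = stats::runif(1, config$w_init_inh_min, config$w_init_inh_max),
      g_leak = config$g_leak_dend_nS)),
    rev = rev))

  draw_trial <- function(streams) {
    draws <- with_stream(streams, "cues", stats::rnorm(3))
    r <- config$mu_r + config$sigma_r * draws[1]
    r_V <- rate_floor(r + config$sigma_V * draws[2], config$r_min)
    r_T <- rate_floor(r + config$sigma_T * draws[3], config$r_min)
    r_true <- rate_floor(r, config$r_min)
    pooled_t <- pool_fast(target_neuron$soma,
                          dend_summary_fast(target_neuron, list(r_true)))
    u_star <- with_stream(streams, "targets",
                          pooled_t$E_bar +
                            sqrt(pooled_t$lambda_e / pooled_t$g_bar) *
                            stats::rnorm(1))
    list(rates = list(r_V, r_T), u_star = u_star)
  }

  training <- train(learner, function(t) draw_trial(streams),
                    n_trials = config$n_trials, eta = config$eta,
                    batch_size = config$batch_size)
  trained <- training$neuron

  eval_rows <- purrr::map(seq_len(config$n_eval), function(k) {
    tr <- draw_trial(streams)
    pooled <- pool_fast(trained$soma, dend_summary_fast(trained, tr$rates))
    tibble::tibble(u_star = tr$u_star, E_bar = pooled$E_bar,
                   g_bar = pooled$g_bar,
                   post_var = pooled$lambda_e / pooled$g_bar)
  })
  eval_tbl <- dplyr::bind_rows(eval_rows)

  w_tot <- vapply(trained$dendrites, function(d) sum(d$w_exc) + sum(d$w_inh),
                  numeric(1))
  mu_star <- mean(eval_tbl$u_star)
  sigma2_star <- stats::var(eval_tbl$u_star)
  model_var <- stats::var(eval_tbl$E_bar) + mean(eval_tbl$post_var)
  summary_tbl <- tibble::tibble(
    mu_star = mu_star,
    sigma2_star = sigma2_star,
    mean_E_bar = mean(eval_tbl$E_bar),
    mean_post_var = mean(eval_tbl$post_var),
    model_var = model_var,
    mean_abs_err = abs(mean(eval_tbl$E_bar) - mu_star),
    var_rel_err = abs(model_var - sigma2_star) / sigma2_star,
    w_tot_1 = w_tot[1], w_tot_2 = w_tot[2],
    w_share_1 = w_tot[1] / sum(w_tot),
    rel_reliability_1 = (1 / config$sigma_V^2) /
      (1 / config$sigma_V^2 + 1 / config$sigma_T^2)
  )
  structure(list(config = config, seed = seed, training = training,
                 target_neuron = target_neuron,
                 eval = eval_tbl, summary = summary_tbl),
            class = c("variance_learning_result", "bd_experiment"))
}

#' Early/late co-variation of excitatory and inhibitory weight changes
#'
#' During the early learning phase, while the pooled mean still mismatches
#' the target mean, excitatory and inhibitory strengths move in opposite
#' directions; once the mean is matched they co-vary to adjust the variance.
#' Per-trial updates are dominated by zero-mean gradient noise, so the
#' trend is measured on the logged weight trajectory: changes of the summed
#' E and I weights between consecutive log points, correlated within an
#' early and a late trial window (pooled over dendrites).
#'
#' @param training A `bd_training` (from [run_variance_learning()]'s
#'   `training` field).
#' @param early_frac,late_frac Fractions of trials forming the windows.
#' @param bins_per_phase Number of coarse trial bins per phase; weight
#'   trajectories are averaged within bins before differencing, which
#'   suppresses the zero-mean walk of individual updates.
#'
#' @return A tibble with `phase` and `correlation`.
#' @export
update_covariation <- function(training, early_frac = 0.1, late_frac = 0.5,
                               bins_per_phase = 10) {
  tmax <- max(training$log$trial)
  phase_cor <- function(lo, hi) {
    win <- dplyr::filter(training$log, .data$trial > lo, .data$trial <= hi)
    win$bin <- pmin(bins_per_phase,
                    1 + floor(bins_per_phase * (win$trial - lo) / (hi - lo)))
    coarse <- win |>
      dplyr::group_by(.data$dendrite, .data$bin) |>
      dplyr::summarise(w_exc = mean(.data$w_exc), w_inh = mean(.data$w_inh),
                       .groups = "drop_last") |>
      dplyr::arrange(.data$bin, .by_group = TRUE) |>
      dplyr::mutate(d_exc = .data$w_exc - dplyr::lag(.data$w_exc),
                    d_inh = .data$w_inh - dplyr::lag(.data$w_inh)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$d_exc))
    stats::cor(coarse$d_exc, coarse$d_inh)
  }
  tibble::tibble(
    phase = c("early", "late"),
    correlation = c(phase_cor(0, early_frac * tmax),
                    phase_cor((1 - late_frac) * tmax, tmax)))
}

#' Reliability sweep: terminal weight share versus relative reliability
#'
#' Repeats [run_variance_learning()] over a grid of relative reliabilities
#' of channel 1 (holding the channel-2 noise amplitude fixed) and regresses
#' the terminal total-weight share of channel 1 on the relative reliability.
#' At the learning fixed point the share equals the relative reliability, so
#' the regression slope is 1.
#'
#' @param config A [variance_learning_config()] (the sweep overrides
#'   `sigma_V`).
#' @param rel_reliabilities Grid of relative reliabilities of channel 1 in
#'   (0, 1).
#' @param seed Master seed; each run gets a distinct derived seed.
#'
#' @return A list of class `reliability_sweep` with `results` (tibble:
#'   `rel_reliability`, `sigma_1`, `w_share_1`), `slope`, `intercept`.
#' @export
run_reliability_sweep <- function(config = variance_learning_config(),
                                  rel_reliabilities = seq(0.2, 0.8, by = 0.1),
                                  seed = 1) {
  stopifnot(all(rel_reliabilities > 0), all(rel_reliabilities < 1))
  rows <- purrr::imap(rel_reliabilities, function(p, i) {
    sigma_1 <- config$sigma_T * sqrt((1 - p) / p)
    cfg <- do.call(variance_learning_config, utils::modifyList(
      unclass(config)[setdiff(names(unclass(config)), "experiment")],
      list(sigma_V = sigma_1)))
    res <- run_variance_learning(cfg, seed = seed + 101 * i)
    tibble::tibble(rel_reliability = p, sigma_1 = sigma_1,
                   w_share_1 = res$summary$w_share_1)
  })
  results <- dplyr::bind_rows(rows)
  fit <- stats::lm(w_share_1 ~ rel_reliability, data = results)
  structure(list(results = results,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "reliability_sweep")
}
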