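#' Train and evaluate the multimodal discrimination network
#'
#' Two output neurons (preferring orientations above / below the boundary)
#' learn from noisy visual and tactile cues about a ground-truth orientation
#' drawn uniformly from the training range. Each neuron's target potential
#' is the inverse-activation image of its role-dependent target rate, jittered
#' by a narrow Gaussian; weights follow the batch-averaged gradient rule in
#' the instantaneous-soma regime. Testing classifies fresh cues from the
#' test range in five conditions: the trained network with both modalities
#' (VT), visual only (V), tactile only (T), the precision-weighted ideal
#' observer (MAP) and the unweighted cue average.
#'
#' @param config A [multimodal_config()]; `scale` multiplies the training
#'   and test trial counts.
#' @param seed Master seed.
#' @param network Optional prebuilt/pretrained `multimodal_network`; when
#'   supplied, training is skipped if it is already trained.
#'
#' @return An object of class `multimodal_result` / `bd_experiment` with
#'   fields `network` (trained), `config`, `seed`, `accuracy` (tibble:
#'   condition, accuracy, n), `psychometric` (per-condition binned
#'   proportions), `fits` (named list of [fit_psychometric()] results) and
#'   `test` (per-trial decisions).
#' @export
run_multimodal_task <- function(config = multimodal_config(), seed = 1,
                                network = NULL) {
  stopifnot(inherits(config, "multimodal_config"))
  streams <- rng_streams(seed, c("init", "cues", "targets", "test"))
  if (is.null(network)) {
    network <- with_stream(streams, "init", build_multimodal_network(config))
  }
  if (!network$trained) {
    network <- train_multimodal(network, streams)
  }
  test <- test_multimodal(network, streams,
                          n_test = max(100L, round(config$n_test * config$scale)))
  structure(c(list(network = network, config = config, seed = seed), test),
            class = c("multimodal_result", "bd_experiment"))
}

# Joint batch trainer for the two output neurons (shared stimuli).
train_multimodal <- function(network, streams) {
  cfg <- network$config
  n_train <- max(1L, round(cfg$n_train * cfg$scale))
  b_size <- cfg$batch_size
  neurons <- network$neurons
  roles <- c("prefers_gt", "prefers_lt")
  u_targets <- c(softplus_inv(cfg$r_low_star_hz), softplus_inv(cfg$r_high_star_hz))
  batch <- list(vector("list", b_size), vector("list", b_size))
  b <- 0L
  for (t in seq_len(n_train)) {
    draw <- with_stream(streams, "cues", {
      theta <- stats::runif(1, cfg$theta_train_min_deg, cfg$theta_train_max_deg)
      sample_cues(theta, cfg$sigma_V_deg, cfg$sigma_T_deg, cfg$p_bimodal)
    })
    rates <- cue_rates(network, draw$theta_visual, draw$theta_tactile)
    z <- with_stream(streams, "targets", stats::rnorm(2))
    b <- b + 1L
    for (k in 1:2) {
      u_mean <- target_potential(draw$theta_true, cfg$boundary_deg, roles[k],
                                 cfg$r_low_star_hz, cfg$r_high_star_hz,
                                 u_ref = cfg$u_ref_mV)
      u_star <- u_mean + cfg$sigma_target_mV * z[k]
      batch[[k]][[b]] <- neuron_weight_gradient(neurons[[k]], rates, u_star)
    }
    if (b == b_size || t == n_train) {
      for (k in 1:2) {
        for (i in seq_along(neurons[[k]]$dendrites)) {
          g_exc <- Reduce(`+`, lapply(batch[[k]][seq_len(b)],
                                      function(x) x[[i]]$d_w_exc)) / b
          g_inh <- Reduce(`+`, lapply(batch[[k]][seq_len(b)],
                                      function(x) x[[i]]$d_w_inh)) / b
          neurons[[k]]$dendrites[[i]]$w_exc <-
            pmax(0, neurons[[k]]$dendrites[[i]]$w_exc + cfg$eta * g_exc)
          neurons[[k]]$dendrites[[i]]$w_inh <-
            pmax(0, neurons[[k]]$dendrites[[i]]$w_inh + cfg$eta * g_inh)
        }
      }
      b <- 0L
      w_max <- max(unlist(lapply(neurons, function(nr)
        vapply(nr$dendrites, function(d) max(d$w_exc, d$w_inh), numeric(1)))))
      if (!is.finite(w_max) || w_max > 1e3) {
        stop(sprintf("multimodal training diverged at trial %d", t), call. = FALSE)
      }
    }
  }
  network$neurons <- neurons
  network$trained <- TRUE
  network$n_train <- n_train
  network
}

# Vectorised rate matrices for a batch of cue orientations; NA rows silent.
bank_rate_matrix <- function(theta, bank) {
  R <- bank$r_min + (bank$r_max - bank$r_min) *
    exp(-bank$kappa / 2 * outer(theta, bank$preferred, "-")^2)
  R[is.na(theta), ] <- 0
  R
}

# Trained-network output rates for cue vectors (MAP-mode readout).
network_rates <- function(network, theta_V, theta_T, c_V = 1, c_T = 1) {
  n <- max(length(theta_V), length(theta_T))
  theta_V <- rep_len(theta_V, n)
  theta_T <- rep_len(theta_T, n)
  R_V <- bank_rate_matrix(theta_V, network$bank_V) * c_V
  R_T <- bank_rate_matrix(theta_T, network$bank_T) * c_T
  R_P <- matrix(network$config$prior_rate_hz, n, 1)
  out <- lapply(network$neurons, function(nr)
    posterior_matrix(nr, list(R_V, R_T, R_P)))
  u_ref <- network$config$u_ref_mV
  tibble::tibble(E_bar_0 = out[[1]]$E_bar, g_bar_0 = out[[1]]$g_bar,
                 E_bar_1 = out[[2]]$E_bar, g_bar_1 = out[[2]]$g_bar,
                 r0 = softplus(out[[1]]$E_bar - u_ref),
                 r1 = softplus(out[[2]]$E_bar - u_ref))
}

test_multimodal <- function(network, streams, n_test) {
  cfg <- network$config
  draws <- with_stream(streams, "test", {
    theta <- stats::runif(n_test, cfg$theta_test_min_deg, cfg$theta_test_max_deg)
    tibble::tibble(
      theta_true = theta,
      theta_V = theta + cfg$sigma_V_deg * stats::rnorm(n_test),
      theta_T = theta + cfg$sigma_T_deg * stats::rnorm(n_test))
  })
  truth <- draws$theta_true >= cfg$boundary_deg
  decide <- function(theta_V, theta_T) {
    out <- network_rates(network, theta_V, theta_T)
    classify_output(out$r0, out$r1, cfg$r_low_star_hz, cfg$r_high_star_hz)
  }
  dec <- tibble::tibble(
    VT = decide(draws$theta_V, draws$theta_T),
    V = decide(draws$theta_V, rep(NA_real_, n_test)),
    T = decide(rep(NA_real_, n_test), draws$theta_T),
    MAP = map_baseline(draws$theta_V, draws$theta_T,
                       cfg$sigma_V_deg, cfg$sigma_T_deg, cfg$boundary_deg),
    unweighted = unweighted_baseline(draws$theta_V, draws$theta_T,
                                     cfg$boundary_deg))
  accuracy <- dplyr::bind_rows(lapply(names(dec), function(cond) {
    tibble::tibble(condition = cond,
                   accuracy = mean(dec[[cond]] == truth),
                   n = n_test)
  }))
  test_tbl <- dplyr::bind_cols(draws, dec, tibble::tibble(truth = truth))
  psych <- psychometric_table(test_tbl, cfg)
  fits <- lapply(split(psych, psych$condition), function(tb)
    fit_psychometric(tb$theta_bin, tb$p_ge, tb$n))
  list(accuracy = accuracy, test = test_tbl, psychometric = psych, fits = fits)
}

#' Binned psychometric table from per-trial decisions
#'
#' @param test_tbl Per-trial tibble with `theta_true` and logical decision
#'   columns (from [run_multimodal_task()]'s `test` field).
#' @param config The experiment's [multimodal_config()].
#' @param bin_width_deg Bin width (degrees).
#' @param span_deg Half-range around the boundary to tabulate.
#'
#' @return A tibble with `condition`, `theta_bin` (centre), `p_ge`, `n`.
#' @export
psychometric_table <- function(test_tbl, config, bin_width_deg = 5,
                               span_deg = 60) {
  conds <- intersect(c("VT", "V", "T", "MAP", "unweighted"), names(test_tbl))
  lo <- config$boundary_deg - span_deg
  hi <- config$boundary_deg + span_deg
  keep <- test_tbl$theta_true >= lo & test_tbl$theta_true <= hi
  tb <- test_tbl[keep, ]
  centres <- floor((tb$theta_true - lo) / bin_width_deg) * bin_width_deg +
    lo + bin_width_deg / 2
  dplyr::bind_rows(lapply(conds, function(cond) {
    agg <- tapply(tb[[cond]], centres, mean)
    cnt <- tapply(tb[[cond]], centres, length)
    tibble::tibble(condition = cond,
                   theta_bin = as.numeric(names(agg)),
                   p_ge = as.numeric(agg), n = as.integer(cnt))
  }))
}
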