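#' Experiment configurations
#'
#' Each runner takes a validated configuration object holding every tunable
#' parameter with explicit units in the key names. Constructors fill
#' defaults; [load_config()]/[save_config()] round-trip configurations
#' through YAML. Unknown keys are rejected.
#'
#' @name bd_config
NULL

new_bd_config <- function(experiment, defaults, overrides) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  for (k in names(cfg)) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]])) {
      stop(sprintf("configuration key '%s' must be a finite scalar", k),
           call. = FALSE)
    }
  }
  structure(c(list(experiment = experiment), cfg),
            class = c(paste0(experiment, "_config"), "bd_config"))
}

#' @describeIn bd_config Mean/variance learning with two input channels of
#'   different reliability: a single-compartment target neuron generates
#'   target potential samples from a shared latent input rate; the learner
#'   receives the rate through two noisy channels.
#' @param ... Scalar overrides of the listed defaults.
#' @export
variance_learning_config <- function(...) {
  defaults <- list(
    n_dendrites = 2,
    g0_nS = 0.25,            # somatic leak conductance
    g_leak_dend_nS = 0.025,  # dendritic leak conductance
    E0_mV = -70,
    E_exc_mV = 0, E_inh_mV = -85, E_leak_mV = -70,
    lambda_e = 1,
    w_init_exc_min = 0, w_init_exc_max = 0.019,   # nS s
    w_init_inh_min = 0, w_init_inh_max = 0.21,
    w_target_exc_min = 0, w_target_exc_max = 1.07,
    w_target_inh_min = 0, w_target_inh_max = 7.0,
    eta = 1.25e-3,
    n_trials = 110000,
    dt_trial_ms = 10,
    mu_r = 1.2, sigma_r = 0.5,   # latent input rate distribution, s^-1
    r_min = 0.001,               # rate floor, s^-1
    sigma_V = 0.01875,           # visual-channel rate noise, s^-1
    sigma_T = 0.3,               # tactile-channel rate noise, s^-1
    batch_size = 1,
    n_eval = 4000                # evaluation trials after training
  )
  new_bd_config("variance_learning", defaults, list(...))
}

#' @describeIn bd_config Multimodal boundary discrimination: two output
#'   neurons with visual, tactile and prior-adjusting compartments learn to
#'   classify orientations against a 45 degree boundary from noisy cues.
#' @export
multimodal_config <- function(...) {
  defaults <- list(
    n_neurons = 2, n_dendrites = 3,
    g0_nS = 1.0, g_leak_dend_nS = 0.2,
    E0_mV = -70,
    E_exc_mV = 0, E_inh_mV = -85, E_leak_mV = -70,
    lambda_e = 1,
    n_detectors = 70,
    theta_fd_min_deg = -315, theta_fd_max_deg = 405,
    kappa_deg2 = 0.04,           # tuning concentration (see vignette)
    r_min_hz = 0.75, r_max_hz = 16,
    w_init_exc_min = 0, w_init_exc_max = 0.005,
    w_init_inh_min = 0, w_init_inh_max = 0.024,
    eta = 0.25e-4,
    sigma_V_deg = 13.5, sigma_T_deg = 28.5,
    theta_train_min_deg = -270, theta_train_max_deg = 360,
    theta_test_min_deg = -135, theta_test_max_deg = 225,
    boundary_deg = 45,
    n_train = 400000, n_test = 500000,
    p_bimodal = 0.9,
    batch_size = 12,
    r_low_star_hz = 0.75, r_high_star_hz = 16,
    u_ref_mV = -70,             # activation reference (resting potential)
    prior_rate_hz = 1,          # constant rate of the prior-adjusting afferent
    sigma_target_mV = 0.1,      # width of the narrow Gaussian target
    scale = 1                   # multiplies n_train and n_test
  )
  new_bd_config("multimodal", defaults, list(...))
}

#' @describeIn bd_config Cross-modal suppression: contrast sweep of fixed
#'   conflicting cues through a trained multimodal network.
#' @export
crossmodal_config <- function(...) {
  defaults <- list(
    theta_V_deg = 50, theta_T_deg = 65,
    contrast_min = 1e-3, contrast_max = 1e2, n_contrasts = 41,
    r_scale = 2.5
  )
  new_bd_config("crossmodal", defaults, list(...))
}

#' @describeIn bd_config Stimulus-evoked response statistics: finite-
#'   capacitance Langevin runs of a trained output neuron around stimulus
#'   onset, with background-orientation mixing.
#' @export
stimulus_response_config <- function(...) {
  defaults <- list(
    n_trials = 40,
    mu_noise_deg = 35, sigma_noise_deg = 15,  # background orientation
    theta_stimulus_deg = 44,
    gamma_before = 0.0, gamma_after = 0.88,   # relative signal contrast
    dt_ms = 0.2, duration_ms = 100, onset_ms = 50,
    C_pF = 50, lambda_e = 100,
    window_ms = 25                            # pre/post analysis windows
  )
  new_bd_config("stimulus_response", defaults, list(...))
}

config_constructors <- function() {
  list(variance_learning = variance_learning_config,
       multimodal = multimodal_config,
       crossmodal = crossmodal_config,
       stimulus_response = stimulus_response_config)
}

#' Load an experiment configuration from a YAML file
#'
#' The file must carry an `experiment` key naming one of the configuration
#' families; remaining keys override that family's defaults. Unknown keys
#' and non-scalar values are rejected with the offending key named.
#'
#' @param path Path to a YAML file.
#' @return A validated `bd_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || is.null(raw$experiment)) {
    ctors <- paste(names(config_constructors()), collapse = ", ")
    stop(sprintf("config must contain an 'experiment' key (one of: %s)", ctors),
         call. = FALSE)
  }
  ctor <- config_constructors()[[raw$experiment]]
  if (is.null(ctor)) {
    stop(sprintf("unknown experiment '%s'", raw$experiment), call. = FALSE)
  }
  do.call(ctor, raw[setdiff(names(raw), "experiment")])
}

#' Save an experiment configuration to YAML
#'
#' @param config A `bd_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "bd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
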