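SNAPSHOT_VERSION <- "1"

#' Serialize a trained network to a JSON snapshot
#'
#' Stores the configuration, all synaptic weights, the detector-bank
#' definitions and provenance (seed, trial count) in a version-tagged,
#' full-precision JSON file, so that simulations replayed from the loaded
#' snapshot reproduce the original bitwise.
#'
#' @param network A `multimodal_network`.
#' @param path Output path.
#' @param seed,notes Optional provenance fields.
#' @export
save_snapshot <- function(network, path, seed = NULL, notes = NULL) {
  stopifnot(inherits(network, "multimodal_network"))
  snap <- list(
    version = SNAPSHOT_VERSION,
    type = "multimodal_network",
    config = unclass(network$config),
    trained = network$trained,
    n_train = network$n_train,
    provenance = list(seed = seed, notes = notes,
                      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    neurons = lapply(network$neurons, function(nr) {
      list(soma = unclass(nr$soma),
           rev = unclass(nr$rev),
           dendrites = lapply(nr$dendrites, unclass))
    })
  )
  jsonlite::write_json(snap, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a network snapshot
#'
#' @param path Path to a snapshot written by [save_snapshot()].
#' @return A `multimodal_network`.
#' @export
load_snapshot <- function(path) {
  if (!file.exists(path)) stop(sprintf("snapshot not found: %s", path),
                               call. = FALSE)
  snap <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                   error = function(e)
                     stop(sprintf("cannot parse snapshot %s: %s",
                                  path, conditionMessage(e)), call. = FALSE))
  if (!identical(as.character(snap$version), SNAPSHOT_VERSION)) {
    stop(sprintf("snapshot version mismatch: file has '%s', expected '%s'",
                 snap$version, SNAPSHOT_VERSION), call. = FALSE)
  }
  cfg <- do.call(multimodal_config,
                 snap$config[setdiff(names(snap$config), "experiment")])
  num <- function(x) as.numeric(unlist(x))  # "Inf" strings become Inf
  neurons <- lapply(snap$neurons, function(nr) {
    soma <- soma_state(num(nr$soma$g0), num(nr$soma$E0), num(nr$soma$C),
                       num(nr$soma$lambda_e))
    rev <- reversal_potentials(num(nr$rev$E_exc), num(nr$rev$E_inh),
                               num(nr$rev$E_leak))
    dends <- lapply(nr$dendrites, function(d)
      dendrite_state(num(d$w_exc), num(d$w_inh), num(d$g_leak),
                     num(d$g_sd), num(d$g_ds), num(d$C_d)))
    neuron_config(soma, dends, rev)
  })
  bank <- function() detector_bank(
    n = cfg$n_detectors, theta_min = cfg$theta_fd_min_deg,
    theta_max = cfg$theta_fd_max_deg, kappa = cfg$kappa_deg2,
    r_min = cfg$r_min_hz, r_max = cfg$r_max_hz)
  structure(list(neurons = neurons, bank_V = bank(), bank_T = bank(),
                 config = cfg, trained = isTRUE(snap$trained),
                 n_train = snap$n_train,
                 provenance = snap$provenance),
            class = "multimodal_network")
}
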