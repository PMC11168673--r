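#' Named reproducible random-number streams
#'
#' Experiments draw from several conceptually separate random sources (cue
#' noise, target samples, weight initialisation, membrane noise). Each named
#' stream holds its own Mersenne-Twister state derived deterministically from
#' the master seed, so changing how many draws one stream consumes does not
#' perturb the others.
#'
#' @param seed Master integer seed.
#' @param names Character vector of stream names.
#'
#' @return An environment of class `rng_streams`.
#' @export
rng_streams <- function(seed, names) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  env$states <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (i in seq_along(names)) {
    sub_seed <- (abs(seed) %% 1000003L) * 2011L + i * 7919L
    set.seed(sub_seed %% .Machine$integer.max)
    env$states[[names[i]]] <- get(".Random.seed", globalenv())
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(env) <- "rng_streams"
  env
}

#' Evaluate an expression under a named RNG stream
#'
#' Swaps the stream's RNG state in, evaluates `expr`, stores the advanced
#' state back, and restores the previously active global state.
#'
#' @param streams An [rng_streams()] object.
#' @param name Stream name.
#' @param expr Expression to evaluate.
#'
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  if (is.null(streams$states[[name]])) {
    stop(sprintf("unknown RNG stream '%s'", name), call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams$states[[name]], globalenv())
  on.exit({
    streams$states[[name]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}
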