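#' Plot a somatic potential trajectory
#'
#' @param object A trajectory tibble from [simulate_soma()] or
#'   [simulate_full()].
#' @param ... Unused.
#' @return A ggplot object: potential trace with the pooled mean overlaid
#'   when available.
#' @export
autoplot.bd_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$u_s)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "time (ms)", y = "somatic potential (mV)")
  if ("E_bar" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$E_bar),
                                linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot a training log
#'
#' @param object A `bd_training`.
#' @param ... Unused.
#' @return A ggplot: per-dendrite excitatory/inhibitory summed weights over
#'   trials.
#' @export
autoplot.bd_training <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, c("w_exc", "w_inh"),
                              names_to = "type", values_to = "weight")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$weight,
                                     colour = factor(.data$dendrite),
                                     linetype = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "summed weight (nS s)",
                  colour = "dendrite", linetype = NULL)
}

#' Plot a psychometric fit
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot: binned proportions and fitted curve.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  if (is.null(object$fitted)) stop("fit failed; nothing to plot", call. = FALSE)
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_hat), colour = "firebrick") +
    ggplot2::labs(x = "orientation (deg)", y = "P(decision >= boundary)")
}

#' Plot a cross-modal suppression sweep
#'
#' @param object A `crossmodal_result`.
#' @param ... Unused.
#' @return A ggplot: output rate vs contrast per condition with asymptotes.
#' @export
autoplot.crossmodal_result <- function(object, ...) {
  asy <- object$asymptotes[!is.na(object$asymptotes$E_inf) |
                             object$asymptotes$condition == "none", ]
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$contrast, y = .data$rate,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = asy,
                        ggplot2::aes(yintercept = .data$rate_inf,
                                     colour = .data$condition),
                        linetype = "dashed", alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "stimulus contrast", y = "output rate (1/s)")
}

#' Plot stimulus-evoked per-bin mean traces
#'
#' @param object A `stimulus_response_result`.
#' @param ... Unused.
#' @return A ggplot: mean somatic traces grouped by prestimulus-potential
#'   quartile.
#' @export
autoplot.stimulus_response_result <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$time_ms, y = .data$u_mean,
                               colour = factor(.data$bin))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "mean somatic potential (mV)",
                  colour = "prestimulus quartile")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
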