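#' Fit a complementary-error-function psychometric curve
#'
#' Least-squares fit of p(theta) = 0.5 erfc((theta_thresh - theta) /
#' (sqrt(2) s)) -- equivalently a Gaussian CDF centred at the threshold with
#' scale `s` -- to binned proportions of ">= boundary" decisions.
#'
#' @param theta_bins Bin centres (degrees); at least 5 bins spanning the
#'   boundary.
#' @param p_ge Proportion of ">= boundary" decisions per bin.
#' @param n Optional per-bin trial counts used as weights.
#' @param start Optional named start values `threshold`, `scale`.
#'
#' @return An object of class `psychometric_fit` with fields `threshold`
#'   (degrees), `scale` (degrees), `converged`, `fitted` (tibble) and the
#'   underlying `nls` fit (or `NULL` on failure).
#' @export
fit_psychometric <- function(theta_bins, p_ge, n = NULL, start = NULL) {
  stopifnot(length(theta_bins) == length(p_ge), length(theta_bins) >= 5)
  dat <- data.frame(theta = theta_bins, p = p_ge)
  w <- if (is.null(n)) rep(1, nrow(dat)) else n
  if (is.null(start)) {
    start <- list(threshold = theta_bins[which.min(abs(p_ge - 0.5))],
                  scale = diff(range(theta_bins)) / 4)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ stats::pnorm((theta - threshold) / scale),
                      data = dat, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(threshold = NA_real_, scale = NA_real_,
                          converged = FALSE, fitted = NULL, fit = NULL,
                          message = "psychometric fit failed"),
                     class = "psychometric_fit"))
  }
  cf <- stats::coef(fit)
  # a near-flat curve fits with an essentially unbounded scale; flag it
  degenerate <- abs(cf[["scale"]]) > 10 * diff(range(theta_bins)) ||
    stats::sd(p_ge) < 1e-3
  structure(list(threshold = unname(cf[["threshold"]]),
                 scale = abs(unname(cf[["scale"]])),
                 converged = !degenerate,
                 fitted = tibble::tibble(
                   theta = theta_bins, p = p_ge,
                   p_hat = stats::predict(fit)),
                 fit = fit,
                 message = if (degenerate) "unbounded-scale (flat data)" else "ok"),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> threshold = %.2f deg, scale = %.2f deg (%s)\n",
              x$threshold, x$scale, x$message))
  invisible(x)
}

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("threshold", "scale"),
                          estimate = c(x$threshold, x$scale),
                          std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"])
}

#' Glance at a psychometric fit
#'
#' @inheritParams tidy.psychometric_fit
#' @return A one-row tibble with `threshold`, `scale`, `converged`,
#'   `n_bins`, `rss`.
#' @export
glance.psychometric_fit <- function(x, ...) {
  rss <- if (is.null(x$fitted)) NA_real_ else sum((x$fitted$p - x$fitted$p_hat)^2)
  tibble::tibble(threshold = x$threshold, scale = x$scale,
                 converged = x$converged,
                 n_bins = if (is.null(x$fitted)) NA_integer_ else nrow(x$fitted),
                 rss = rss)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
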