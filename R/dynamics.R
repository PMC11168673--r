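#' Noise specification for stochastic simulations
#'
#' @param seed Integer seed; identical seed and inputs give bitwise-identical
#'   trajectories.
#' @param enabled If `FALSE` the Langevin noise term is omitted and the
#'   dynamics are deterministic gradient descent on the somatic energy.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(seed = 1L, enabled = TRUE) {
  structure(list(seed = as.integer(seed), enabled = isTRUE(enabled)),
            class = "noise_spec")
}

#' Piecewise-constant rate schedule
#'
#' All stimulation protocols are step stimuli, so rate schedules are
#' piecewise constant on the integration grid: segment `i` starts at
#' `start_ms[i]` and supplies one rate vector per dendrite.
#'
#' @param start_ms Strictly increasing segment onsets (ms); first must be 0.
#' @param rates A list (one element per segment) of per-dendrite rate lists.
#'
#' @return A tibble with columns `start_ms` and `rates`.
#' @export
rate_schedule <- function(start_ms, rates) {
  if (!is.list(rates[[1]])) rates <- list(rates)
  start_ms <- as.numeric(start_ms)
  stopifnot(length(start_ms) == length(rates), start_ms[1] == 0,
            !is.unsorted(start_ms, strictly = TRUE))
  tibble::tibble(start_ms = start_ms, rates = rates)
}

#' One Euler-Maruyama step of the somatic Langevin dynamics
#'
#' The somatic potential performs noisy gradient ascent on the log-posterior:
#' C du = g_bar (E_bar - u) dt + xi, with white noise of spectral density
#' 2 C lambda_e. One step therefore reads
#' u' = u + (dt / C) g_bar (E_bar - u) + sqrt(2 lambda_e dt / C) * z with
#' standard-normal `z`. The stationary law is
#' Normal(E_bar, lambda_e / g_bar) -- the pooled posterior -- with
#' autocorrelation time tau = C / g_bar.
#'
#' @param u_s Current somatic potential (mV).
#' @param pooled A `pooled_posterior`.
#' @param C Somatic capacitance (pF).
#' @param dt Time step (ms); must satisfy dt * g_bar / C < 1.
#' @param noise_draw Standard-normal draw(s); 0 disables the noise term.
#'
#' @return Updated potential (mV).
#' @export
langevin_step <- function(u_s, pooled, C, dt, noise_draw = 0) {
  stopifnot(dt > 0, C > 0)
  k <- dt * pooled$g_bar / C
  if (k >= 1) {
    stop(sprintf("unstable integration: dt = %g ms gives dt*g_bar/C = %.3f >= 1; reduce dt",
                 dt, k), call. = FALSE)
  }
  u_s + k * (pooled$E_bar - u_s) + sqrt(2 * pooled$lambda_e * dt / C) * noise_draw
}

# Fast path for a constant-input segment: the Euler-Maruyama recursion
# u[n+1] = (1-k) u[n] + k E_bar + s z[n] is a linear recursive filter.
ou_segment <- function(u0, pooled, C, dt, n_steps, noise_sd_draws = NULL) {
  k <- dt * pooled$g_bar / C
  if (k >= 1) {
    stop(sprintf("unstable integration: dt = %g ms gives dt*g_bar/C = %.3f >= 1; reduce dt",
                 dt, k), call. = FALSE)
  }
  if (n_steps == 0L) return(numeric(0))
  drive <- rep(k * pooled$E_bar, n_steps)
  if (!is.null(noise_sd_draws)) drive <- drive + noise_sd_draws
  as.numeric(stats::filter(drive, 1 - k, method = "recursive", init = u0))
}

#' Simulate the reduced (fast-dendrite) somatic dynamics
#'
#' Integrates the somatic Langevin equation with Euler-Maruyama at fixed
#' `dt`, recomputing the pooled posterior whenever the rate schedule changes.
#' A classical fixed-step stochastic scheme is used deliberately: its
#' stationary statistics match the Ornstein-Uhlenbeck law that the posterior
#' contract is tested against.
#'
#' @param neuron A [neuron_config()].
#' @param schedule A [rate_schedule()] (or a plain per-dendrite rate list for
#'   constant input).
#' @param duration_ms Total simulated time (ms).
#' @param dt_ms Time step (ms), default 0.2.
#' @param noise A [noise_spec()].
#' @param u0 Initial potential (mV); defaults to the initial pooled mean.
#'
#' @return A tibble trajectory with columns `time_ms`, `u_s`, `E_bar`,
#'   `g_bar`, of class `bd_trajectory`. Time 0 holds the initial condition.
#' @export
simulate_soma <- function(neuron, schedule, duration_ms, dt_ms = 0.2,
                          noise = noise_spec(), u0 = NULL) {
  if (!is.data.frame(schedule)) schedule <- rate_schedule(0, list(schedule))
  C <- neuron$soma$C
  stopifnot(C > 0, duration_ms > 0)
  times <- seq(0, duration_ms, by = dt_ms)
  n <- length(times)
  pooled_per_seg <- lapply(schedule$rates, function(r) neuron_posterior(neuron, r))
  seg_idx <- findInterval(times, schedule$start_ms)
  E_bar <- vapply(pooled_per_seg, `[[`, numeric(1), "E_bar")[seg_idx]
  g_bar <- vapply(pooled_per_seg, `[[`, numeric(1), "g_bar")[seg_idx]
  if (is.null(u0)) u0 <- E_bar[1]
  if (noise$enabled) {
    set.seed(noise$seed)
    z <- stats::rnorm(n - 1)
  } else {
    z <- rep(0, n - 1)
  }
  lam <- neuron$soma$lambda_e
  u <- numeric(n)
  u[1] <- u0
  seg_step <- seg_idx[seq_len(n - 1)]  # rates in effect at each step's start
  sd_step <- if (noise$enabled) sqrt(2 * lam * dt_ms / C) else 0
  for (s in unique(seg_step)) {
    steps <- which(seg_step == s)  # indices into z / transitions
    pooled <- pooled_per_seg[[s]]
    u[steps + 1L] <- ou_segment(u[steps[1]], pooled, C, dt_ms,
                                length(steps),
                                if (sd_step > 0) sd_step * z[steps] else NULL)
  }
  structure(tibble::tibble(time_ms = times, u_s = u, E_bar = E_bar, g_bar = g_bar),
            class = c("bd_trajectory", class(tibble::tibble())))
}

#' Simulate the full coupled soma-dendrite system
#'
#' Integrates the two-compartment ODE system with finite dendritic
#' capacitances and finite couplings:
#' C du_s = g0 (E0 - u_s) + sum_i g_sd,i (u_d,i - u_s),
#' C_d du_d,i = g_d,i (E_d,i - u_d,i) + g_ds,i (u_s - u_d,i).
#' Small dendritic capacitances make the system stiff, so deterministic runs
#' use the implicit-capable `lsoda` solver segment by segment; with noise
#' enabled a fixed-step Euler-Maruyama scheme is used instead and `dt_ms`
#' must resolve the fastest dendritic time constant C_d / (g_d + g_ds).
#'
#' @inheritParams simulate_soma
#'
#' @return A tibble trajectory with `time_ms`, `u_s` and one `u_d_<i>` column
#'   per dendrite.
#' @export
simulate_full <- function(neuron, schedule, duration_ms, dt_ms = 0.2,
                          noise = noise_spec(enabled = FALSE), u0 = NULL) {
  if (!is.data.frame(schedule)) schedule <- rate_schedule(0, list(schedule))
  dends <- neuron$dendrites
  D <- length(dends)
  stopifnot(D >= 1)
  if (any(vapply(dends, function(d) is.infinite(d$g_sd) || is.infinite(d$g_ds),
                 logical(1)))) {
    stop("simulate_full requires finite coupling conductances", call. = FALSE)
  }
  C <- neuron$soma$C
  C_d <- vapply(dends, `[[`, numeric(1), "C_d")
  g_sd <- vapply(dends, `[[`, numeric(1), "g_sd")
  g_ds <- vapply(dends, `[[`, numeric(1), "g_ds")
  soma <- neuron$soma
  times <- seq(0, duration_ms, by = dt_ms)
  n <- length(times)
  seg_idx <- findInterval(times, schedule$start_ms)
  seg_summ <- lapply(schedule$rates, function(r) dendrite_summary(neuron, r))
  deriv <- function(state, summ) {
    u_s <- state[1]
    u_d <- state[-1]
    dus <- (soma$g0 * (soma$E0 - u_s) + sum(g_sd * (u_d - u_s))) / C
    dud <- (summ$g_d * (summ$E_d - u_d) + g_ds * (u_s - u_d)) / C_d
    c(dus, dud)
  }
  summ0 <- seg_summ[[1]]
  if (is.null(u0)) u0 <- neuron_posterior(neuron, schedule$rates[[1]])$E_bar
  state <- c(u0, summ0$E_d)  # dendrites start at local reversal
  out <- matrix(NA_real_, n, 1 + D)
  out[1, ] <- state
  if (noise$enabled) {
    set.seed(noise$seed)
    z <- stats::rnorm(n - 1)
    tau_fast <- min(C_d / (vapply(seg_summ, function(s) max(s$g_d), numeric(1)) + g_ds))
    if (dt_ms > tau_fast) {
      stop(sprintf(
        "unstable integration: dt = %g ms does not resolve the fastest dendritic time constant %.3g ms",
        dt_ms, tau_fast), call. = FALSE)
    }
    for (i in seq_len(n - 1)) {
      state <- state + dt_ms * deriv(state, seg_summ[[seg_idx[i]]])
      state[1] <- state[1] + sqrt(2 * soma$lambda_e * dt_ms / C) * z[i]
      out[i + 1, ] <- state
    }
  } else {
    ode_fn <- function(t, y, parms) list(deriv(y, parms))
    pos <- 1L
    seg_step <- seg_idx[seq_len(n - 1)]
    for (s in unique(seg_step)) {
      steps <- which(seg_step == s)
      seg_times <- c(times[steps[1]], times[steps + 1L])
      sol <- deSolve::ode(y = state, times = seg_times, func = ode_fn,
                          parms = seg_summ[[s]], method = "lsoda",
                          rtol = 1e-8, atol = 1e-8)
      out[steps + 1L, ] <- sol[-1, -1, drop = FALSE]
      state <- as.numeric(sol[nrow(sol), -1])
    }
  }
  colnames(out) <- c("u_s", paste0("u_d_", seq_len(D)))
  res <- tibble::as_tibble(as.data.frame(out))
  res <- dplyr::bind_cols(tibble::tibble(time_ms = times), res)
  structure(res, class = c("bd_trajectory", class(tibble::tibble())))
}

#' Instantaneous (zero-capacitance) somatic readout
#'
#' In the C -> 0 limit the somatic potential equilibrates instantly: the MAP
#' readout is the pooled posterior mean `E_bar`, and the sampling readout
#' draws from the full posterior Normal(E_bar, lambda_e / g_bar). Sampling
#' uses the current RNG state.
#'
#' @param neuron A [neuron_config()].
#' @param rates Per-dendrite rate list as in [dendrite_summary()].
#' @param mode `"map"` or `"sample"`.
#'
#' @return Somatic potential (mV).
#' @export
instantaneous_soma <- function(neuron, rates, mode = c("map", "sample")) {
  mode <- match.arg(mode)
  pooled <- neuron_posterior(neuron, rates)
  if (mode == "map") return(pooled$E_bar)
  pooled$E_bar + sqrt(pooled$lambda_e / pooled$g_bar) * stats::rnorm(1)
}

#' Estimate the autocorrelation time of a stationary trace
#'
#' Fits log-linear decay to the empirical autocorrelation function over lags
#' where it stays above `floor` and returns the fitted exponential time
#' constant, comparable to the theoretical tau = C / g_bar.
#'
#' @param u Stationary potential trace.
#' @param dt_ms Sampling interval (ms).
#' @param max_lag_ms Largest lag used (ms).
#' @param floor Autocorrelation values below this are excluded from the fit.
#'
#' @return Autocorrelation time (ms).
#' @export
autocorrelation_time <- function(u, dt_ms, max_lag_ms = NULL, floor = 0.05) {
  n_lag <- if (is.null(max_lag_ms)) min(length(u) - 1, 5000L) else
    round(max_lag_ms / dt_ms)
  a <- stats::acf(u, lag.max = n_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(a) - 1
  # fit only up to the first drop below the floor; beyond that the acf is
  # estimator noise and would bias the slope
  cut <- which(a <= floor)[1]
  if (!is.na(cut)) a <- a[seq_len(cut - 1)]
  lags <- lags[seq_along(a)]
  keep <- lags > 0
  if (sum(keep) < 3) stop("trace too short to estimate autocorrelation time",
                          call. = FALSE)
  fit <- stats::lm(log(a[keep]) ~ 0 + lags[keep])
  -dt_ms / unname(stats::coef(fit)[1])
}

#' Write a trajectory to a delimited text file
#'
#' @param traj A trajectory tibble from [simulate_soma()] or
#'   [simulate_full()].
#' @param path Output path (CSV).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
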