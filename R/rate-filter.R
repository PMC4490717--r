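# Online firing-rate estimation: a first-order exponential averaging filter
# applied to the instantaneous binned population rate.

#' Smoothing weight of the first-order rate filter
#'
#' Computes the exponential-moving-average weight `alpha = 1 - exp(-dt/tau)`
#' used by the online firing-rate estimator.
#'
#' @param dt Filter update interval in seconds (the spike-count bin width).
#' @param tau Smoothing time constant in seconds.
#' @return The dimensionless weight in (0, 1).
#' @examples
#' compute_alpha(0.004, 2.5)
#' @export
compute_alpha <- function(dt, tau) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive, finite number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive, finite number", call. = FALSE)
  1 - exp(-dt / tau)
}

#' Configuration of the online firing-rate filter
#'
#' @param dt Update interval in seconds. Default 0.004 s (4 ms bins).
#' @param tau Smoothing time constant in seconds. Default 2.5 s for
#'   population control; 0.8 s is used for single-unit control in vivo.
#' @param n_units Number of units contributing to the population rate.
#' @return An object of class `oc_rate_filter_config`.
#' @export
rate_filter_config <- function(dt = 0.004, tau = 2.5, n_units = 1L) {
  alpha <- compute_alpha(dt, tau)
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L)
    stop("`n_units` must be at least 1", call. = FALSE)
  structure(list(dt = dt, tau = tau, alpha = alpha, n_units = n_units),
            class = "oc_rate_filter_config")
}

#' Initial state of the rate estimator
#'
#' @param f Initial smoothed rate, Hz/unit.
#' @param r_inst Initial instantaneous rate, Hz/unit.
#' @param t Time of the estimate, seconds.
#' @return An object of class `oc_rate_estimate`.
#' @export
rate_estimate <- function(f = 0, r_inst = 0, t = 0) {
  if (f < 0 || r_inst < 0) stop("rates must be non-negative", call. = FALSE)
  structure(list(f = f, r_inst = r_inst, t = t), class = "oc_rate_estimate")
}

#' Advance the rate estimator by one bin
#'
#' Converts a spike count in one bin into an instantaneous population rate
#' `r = n_spikes / (n_units * dt)` (Hz/unit) and blends it into the smoothed
#' estimate `f <- alpha * r + (1 - alpha) * f`.
#'
#' @param state An `oc_rate_estimate`.
#' @param cfg An `oc_rate_filter_config`.
#' @param n_spikes Total number of spikes (all units) observed in the bin.
#' @return The updated `oc_rate_estimate`.
#' @export
update_rate_estimate <- function(state, cfg, n_spikes) {
  if (!is.numeric(n_spikes) || length(n_spikes) != 1L || is.na(n_spikes) ||
      n_spikes < 0)
    stop("`n_spikes` must be a single non-negative number", call. = FALSE)
  r <- n_spikes / (cfg$n_units * cfg$dt)
  state$r_inst <- r
  state$f <- cfg$alpha * r + (1 - cfg$alpha) * state$f
  state$t <- state$t + cfg$dt
  state
}
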