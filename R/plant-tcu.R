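# Synthetic thalamocortical-unit (TCU) plant: a single unit with
# Poisson-like firing under optical drive, an elevated-CV bursty
# spontaneous mode, short-latency whisker-evoked spikes, adaptation of the
# opsin-driven gain, and slow excitability drift.

#' Parameters of the synthetic thalamocortical-unit plant
#'
#' The unit fires as a conditional-intensity process
#' `lambda = (baseline * env + opsin_gain * a * b) * x + sensory`,
#' with an absolute refractory period. `b` is the low-pass-filtered blue
#' power, `a` the opsin/firing adaptation state, `env` a two-state bursting
#' envelope (unit mean) that makes spontaneous interspike intervals
#' markedly more variable than Poisson (CV of the ISI distribution around
#' 1.7, matching anesthetized thalamic burst firing), and `x` a slow
#' log-normal excitability drift. Sensory drive is a short-latency kernel
#' triggered by whisker-deflection onsets.
#'
#' @param baseline Spontaneous mean rate, Hz. Default 5.
#' @param opsin_gain Driven rate per unit light power, Hz per mW·mm^-2.
#'   Default 3.
#' @param refractory Absolute refractory period, s. Default 0.002.
#' @param kernel_latency Sensory response latency, s. Default 0.005.
#' @param kernel_amplitude Evoked spikes per deflection. Default 1.
#' @param kernel_width Gaussian SD of the evoked-rate kernel, s.
#'   Default 0.0015.
#' @param burst_rate Spontaneous burst-episode rate, 1/s. Default 1.5.
#' @param burst_gain Within-burst rate multiplier. Default 10.
#' @param burst_duration Mean burst duration, s. Default 0.05.
#' @param adapt_tau Adaptation recovery time constant, s. Default 60.
#' @param adapt_depth Fraction of optical gain lost at full adaptation.
#'   Default 0.35.
#' @param adapt_rate Adaptation onset rate at full drive, 1/s. Default 1/20.
#' @param drive_half Light power normalizing the adaptation drive, mW·mm^-2.
#'   Default 5.
#' @param excit_sd,excit_tau Within-trial excitability drift (log scale SD,
#'   s). Defaults 0.2 and 20.
#' @param instance_sd Per-instance excitability factor (log scale SD).
#'   Default 0.2.
#' @param opsin_tau Opsin response time constant, s. Default 0.03.
#' @return An object of class `oc_tcu_params`.
#' @export
tcu_plant_params <- function(baseline = 5, opsin_gain = 3, refractory = 0.002,
                             kernel_latency = 0.005, kernel_amplitude = 1,
                             kernel_width = 0.0015,
                             burst_rate = 1.5, burst_gain = 10,
                             burst_duration = 0.05,
                             adapt_tau = 60, adapt_depth = 0.35,
                             adapt_rate = 1 / 20, drive_half = 5,
                             excit_sd = 0.2, excit_tau = 20,
                             instance_sd = 0.2, opsin_tau = 0.03) {
  if (baseline < 0 || opsin_gain < 0 || kernel_amplitude < 0)
    stop("rates and gains must be non-negative", call. = FALSE)
  if (adapt_depth < 0 || adapt_depth >= 1)
    stop("`adapt_depth` must lie in [0, 1)", call. = FALSE)
  structure(list(baseline = baseline, opsin_gain = opsin_gain,
                 refractory = refractory,
                 kernel_latency = kernel_latency,
                 kernel_amplitude = kernel_amplitude,
                 kernel_width = kernel_width,
                 burst_rate = burst_rate, burst_gain = burst_gain,
                 burst_duration = burst_duration,
                 adapt_tau = adapt_tau, adapt_depth = adapt_depth,
                 adapt_rate = adapt_rate, drive_half = drive_half,
                 excit_sd = excit_sd, excit_tau = excit_tau,
                 instance_sd = instance_sd, opsin_tau = opsin_tau,
                 n_units = 1L),
            class = "oc_tcu_params")
}

#' Create a synthetic thalamocortical-unit plant
#'
#' @param params An `oc_tcu_params`.
#' @return An object of class `oc_plant` (type `"tcu"`).
#' @export
tcu_plant <- function(params = tcu_plant_params()) {
  structure(list(type = "tcu", params = params), class = "oc_plant")
}

#' Advance the TCU plant by one simulation step
#'
#' @param state Plant state environment from [plant_init()] (mutated in
#'   place).
#' @param params The plant's `oc_tcu_params`.
#' @param blue_power Blue light power density this step, mW·mm^-2.
#' @param sensory_rate Instantaneous sensory-evoked intensity, Hz (the
#'   whisker-deflection kernel evaluated at this step; 0 without whisker
#'   input).
#' @param dt Step length, seconds.
#' @return Spike count for this step (0 or 1).
#' @export
tcu_step <- function(state, params, blue_power, sensory_rate = 0, dt) {
  if (blue_power < 0) stop("light power must be non-negative", call. = FALSE)
  p <- params
  st <- state
  st$b <- st$b + (blue_power - st$b) * dt / p$opsin_tau
  st$t <- st$t + dt
  if (st$t >= st$t_switch) {
    if (st$in_burst) {
      st$in_burst <- FALSE
      st$t_switch <- st$t + if (p$burst_rate > 0)
        stats::rexp(1, p$burst_rate) else Inf
    } else {
      st$in_burst <- TRUE
      st$t_switch <- st$t + stats::rexp(1, 1 / p$burst_duration)
    }
  }
  env <- if (st$in_burst) p$burst_gain else st$env_base
  st$k <- st$k + 1L
  if (st$k %% st$excit_steps == 0L) {
    st$z <- st$z * st$rho +
      sqrt(1 - st$rho^2) * stats::rnorm(1, 0, p$excit_sd)
  }
  excit <- st$instance * exp(st$z - p$excit_sd^2 / 2)
  drive <- st$b / (st$b + p$drive_half)
  floor_a <- 1 - p$adapt_depth
  st$a <- st$a + dt * ((1 - st$a) / p$adapt_tau -
                         p$adapt_rate * drive * (st$a - floor_a))
  st$a <- min(max(st$a, floor_a), 1)
  lam <- (p$baseline * env + p$opsin_gain * st$a * st$b) * excit + sensory_rate
  if (st$t - st$t_last_spike < p$refractory) return(0L)
  spike <- stats::runif(1) < -expm1(-lam * dt)
  if (spike) {
    st$t_last_spike <- st$t
    1L
  } else 0L
}

# Instantaneous evoked-rate trace (Hz) from whisker-deflection onsets:
# Gaussian kernels of area `kernel_amplitude` at `kernel_latency` after
# each onset, sampled on the simulation grid.
sensory_rate_trace <- function(onsets, params, n_steps, dt) {
  out <- numeric(n_steps)
  if (length(onsets) == 0L) return(out)
  w <- params$kernel_width
  span <- 4 * w
  for (on in onsets) {
    c0 <- on + params$kernel_latency
    i0 <- max(1L, as.integer(floor((c0 - span) / dt)) + 1L)
    i1 <- min(n_steps, as.integer(ceiling((c0 + span) / dt)))
    if (i0 > i1) next
    tt <- (i0:i1 - 0.5) * dt
    out[i0:i1] <- out[i0:i1] +
      params$kernel_amplitude * stats::dnorm(tt, mean = c0, sd = w)
  }
  out
}
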