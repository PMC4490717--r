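# Feedback control laws: recursive (velocity-form) PI with anti-windup and
# split excitatory/inhibitory outputs, a pure-integral variant for in vivo
# fiber stimulation, and on-off (bang-bang) controllers driven by the
# integrated error.

#' PI controller configuration
#'
#' Velocity-form discrete PI controller
#' `u[t] = u[t-1] + K * (e[t] - e[t-1] + (Ts/Ti) * e[t])`,
#' whose scalar output is split into an excitatory control variable
#' `U_C = clip(u + delta1, 0, 1)` and an inhibitory one
#' `U_H = clip(-u + delta2, 0, 1)`. The offsets `delta1`, `delta2` set the
#' degree of overlap between excitation and suppression around `u = 0`.
#' Anti-windup bounds the integrating state itself: `u` is clipped to
#' `[-delta2, 1 - delta1]`, the interval outside which both split outputs
#' are pinned at their saturation values.
#'
#' @param K Proportional gain (dimensionless). Nominal 0.1.
#' @param Ti Integral time constant, seconds. Nominal 1 s.
#' @param Ts Control period, seconds. Nominal 0.01 s.
#' @param delta1,delta2 Split offsets in `[0, 1]`. Nominal 0.25 each.
#' @param u_min,u_max Bounds applied to each split output. Default `[0, 1]`.
#' @return An object of class `oc_pi_config`.
#' @export
pi_config <- function(K = 0.1, Ti = 1, Ts = 0.01,
                      delta1 = 0.25, delta2 = 0.25,
                      u_min = 0, u_max = 1) {
  if (Ti <= 0) stop("`Ti` must be positive", call. = FALSE)
  if (Ts <= 0) stop("`Ts` must be positive", call. = FALSE)
  if (delta1 < 0 || delta1 > 1 || delta2 < 0 || delta2 > 1)
    stop("`delta1` and `delta2` must lie in [0, 1]", call. = FALSE)
  if (u_min >= u_max) stop("`u_min` must be below `u_max`", call. = FALSE)
  structure(list(K = K, Ti = Ti, Ts = Ts, delta1 = delta1, delta2 = delta2,
                 u_min = u_min, u_max = u_max),
            class = "oc_pi_config")
}

#' PI controller state
#'
#' @param u Scalar control output at the previous step.
#' @param e_prev Previous error, Hz/unit. Controllers start neutral
#'   (`u = 0`, `e_prev = 0`) at control onset.
#' @return An object of class `oc_pi_state`.
#' @export
pi_state <- function(u = 0, e_prev = 0) {
  structure(list(u = u, e_prev = e_prev), class = "oc_pi_state")
}

#' One PI controller update
#'
#' @param state An `oc_pi_state`.
#' @param cfg An `oc_pi_config`.
#' @param e Current error `f* - f`, Hz/unit. Positive error drives excitation.
#' @return The updated `oc_pi_state` (anti-windup already applied to `u`).
#' @export
pi_step <- function(state, cfg, e) {
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e))
    stop("`e` must be a single finite number", call. = FALSE)
  u <- state$u + cfg$K * (e - state$e_prev + (cfg$Ts / cfg$Ti) * e)
  lo <- cfg$delta2 * -1 + cfg$u_min  # -delta2 when outputs bounded at 0
  hi <- cfg$u_max - cfg$delta1       # 1 - delta1 when outputs bounded at 1
  state$u <- min(max(u, lo), hi)
  state$e_prev <- e
  state
}

#' Split the scalar control output into excitatory and inhibitory variables
#'
#' @param u Scalar control output.
#' @param cfg An `oc_pi_config` providing the split offsets and bounds.
#' @return Named numeric vector `c(U_C = , U_H = )`, each clipped to the
#'   output bounds (default `[0, 1]`).
#' @export
split_control <- function(u, cfg = pi_config()) {
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u))
    stop("`u` must be a single finite number", call. = FALSE)
  clip01 <- function(x) min(max(x, cfg$u_min), cfg$u_max)
  c(U_C = clip01(u + cfg$delta1), U_H = clip01(-u + cfg$delta2))
}

#' Pure-integral controller configuration (in vivo fiber stimulation)
#'
#' Integral-only update `u[t] = u[t-1] + (Ts/Ti) * e[t]`, with `u` clipped
#' to `[0, 1]` (anti-windup). The in vivo loop pairs this with a 0.8 s
#' rate-filter time constant and maps `u` to fiber light power as `G * u`.
#'
#' @param Ti Integral time constant, seconds. Nominal 1 s.
#' @param Ts Control period, seconds. Nominal 0.01 s.
#' @return An object of class `oc_integral_config`.
#' @export
integral_config <- function(Ti = 1, Ts = 0.01) {
  if (Ti <= 0) stop("`Ti` must be positive", call. = FALSE)
  if (Ts <= 0) stop("`Ts` must be positive", call. = FALSE)
  structure(list(Ti = Ti, Ts = Ts), class = "oc_integral_config")
}

#' One pure-integral controller update
#'
#' @param state An `oc_pi_state` (only `u` is used).
#' @param cfg An `oc_integral_config`.
#' @param e Current error `f* - f`, Hz/unit.
#' @return The updated state with `u` clipped to `[0, 1]`.
#' @export
integral_step <- function(state, cfg, e) {
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e))
    stop("`e` must be a single finite number", call. = FALSE)
  u <- state$u + (cfg$Ts / cfg$Ti) * e
  state$u <- min(max(u, 0), 1)
  state$e_prev <- e
  state
}

#' On-off controller state
#'
#' The on-off (bang-bang) controllers act on the integrated error
#' `I_f[t] = sum_k e[k] * dt` (Hz·s/unit), accumulated at the rate-filter
#' step and clipped to `[-I_max, I_max]` so it cannot wind up without bound.
#' The excitatory mode emits fixed light pulses while `I_f > 0`, at most
#' every `min_interval` seconds (10 Hz cap); the inhibitory mode gates
#' continuous yellow light on while `I_f < 0`.
#'
#' @param mode Either `"excitatory"` or `"inhibitory"`.
#' @param I_max Accumulator bound, Hz·s/unit. Default 10.
#' @return An object of class `oc_onoff_state`.
#' @export
onoff_state <- function(mode = c("excitatory", "inhibitory"), I_max = 10) {
  mode <- match.arg(mode)
  structure(list(I_f = 0, t_last_pulse = -Inf, mode = mode, gate = FALSE,
                 I_max = I_max),
            class = "oc_onoff_state")
}

#' One update of the excitatory on-off controller
#'
#' Accumulates the error and emits a blue-light pulse command (default 5 ms,
#' 13.4 mW·mm^-2, 465 nm) when the integrated error is positive, subject to
#' a maximal stimulation frequency of 10 Hz (minimum 0.1 s between pulse
#' onsets).
#'
#' @param state An `oc_onoff_state` in excitatory mode.
#' @param e Current error, Hz/unit.
#' @param dt Accumulation step, seconds (the rate-filter step).
#' @param t Current time, seconds.
#' @param pulse_width Pulse width, seconds. Default 0.005.
#' @param pulse_power Pulse power density, mW·mm^-2. Default 13.4.
#' @param min_interval Minimum time between pulse onsets, s. Default 0.1.
#' @return A list with elements `state` (updated) and `pulse` (`NULL`, or a
#'   list with `t`, `width_s`, `power`, `wavelength_nm`).
#' @export
onoff_excitatory_step <- function(state, e, dt, t,
                                  pulse_width = 0.005, pulse_power = 13.4,
                                  min_interval = 0.1) {
  if (state$mode != "excitatory")
    stop("state is not in excitatory mode", call. = FALSE)
  state$I_f <- min(max(state$I_f + e * dt, -state$I_max), state$I_max)
  pulse <- NULL
  # small slack so grid times that are exact multiples of min_interval fire
  if (state$I_f > 0 && (t - state$t_last_pulse) >= min_interval - 1e-9) {
    pulse <- list(t = t, width_s = pulse_width, power = pulse_power,
                  wavelength_nm = 465)
    state$t_last_pulse <- t
  }
  list(state = state, pulse = pulse)
}

#' One update of the inhibitory on-off controller
#'
#' Accumulates the error and switches continuous yellow light (1.0 A to the
#' 590 nm LEDs, ~11.8 mW·mm^-2 at the preparation) on whenever the
#' integrated error is negative.
#'
#' @param state An `oc_onoff_state` in inhibitory mode.
#' @param e Current error, Hz/unit.
#' @param dt Accumulation step, seconds.
#' @return A list with elements `state` (updated, `gate` reflecting the
#'   light) and `light_on` (logical).
#' @export
onoff_inhibitory_step <- function(state, e, dt) {
  if (state$mode != "inhibitory")
    stop("state is not in inhibitory mode", call. = FALSE)
  state$I_f <- min(max(state$I_f + e * dt, -state$I_max), state$I_max)
  state$gate <- state$I_f < 0
  list(state = state, light_on = state$gate)
}

#' Piecewise-constant target-rate schedule
#'
#' @param times Segment start times in seconds (strictly increasing; the
#'   first must be at or before 0, times are relative to control onset).
#' @param rates Target rates, Hz/unit, one per segment; all non-negative.
#' @return An object of class `oc_target_schedule`.
#' @export
target_schedule <- function(times = 0, rates) {
  if (length(times) != length(rates))
    stop("`times` and `rates` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(rates < 0)) stop("target rates must be non-negative", call. = FALSE)
  structure(list(times = times, rates = rates), class = "oc_target_schedule")
}

#' Evaluate a target schedule
#'
#' @param schedule An `oc_target_schedule`.
#' @param t Times (seconds, relative to control onset) at which to evaluate.
#' @return Target rates, Hz/unit (the first segment extends backwards in time).
#' @export
target_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$times)
  idx[idx < 1L] <- 1L
  schedule$rates[idx]
}
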