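# Mapping of control variables to parametric optical stimuli, and rendering
# of sampled light-power traces (square pulse trains, triangle, sine, PRBS,
# continuous) plus the whisker-deflection waveform.

#' Map the excitatory control variable to blue pulse-train parameters
#'
#' The single control variable `U_C` in `[0, 1]` simultaneously modulates
#' pulse frequency (`10*U_C + 10` Hz), pulse width (`5*U_C` ms) and peak
#' power density (`13.2*U_C` mW·mm^-2) of 465 nm stimulation.
#'
#' @param U_C Excitatory control variable in `[0, 1]`.
#' @param power_coeff Peak-power coefficient, mW·mm^-2 at `U_C = 1`.
#'   Default 13.2.
#' @return A list of class `oc_pulse_train` with `freq_hz`, `width_ms`,
#'   `power`, `wavelength_nm`.
#' @examples
#' map_Uc_to_pulse_params(0.47)$freq_hz  # 14.7
#' @export
map_Uc_to_pulse_params <- function(U_C, power_coeff = 13.2) {
  if (!is.numeric(U_C) || length(U_C) != 1L || is.na(U_C) ||
      U_C < 0 || U_C > 1)
    stop("`U_C` must be a single number in [0, 1]", call. = FALSE)
  structure(list(freq_hz = 10 * U_C + 10,
                 width_ms = 5 * U_C,
                 power = power_coeff * U_C,
                 wavelength_nm = 465),
            class = "oc_pulse_train")
}

#' Map the inhibitory control variable to yellow LED current and power
#'
#' `U_H` in `[0, 1]` is delivered directly as the forward current (amperes)
#' of the 590 nm LEDs. A configurable current-to-power curve (default:
#' linear, reaching `max_power` mW·mm^-2 at 1 A) converts the command to
#' effective power density at the preparation.
#'
#' @param U_H Inhibitory control variable in `[0, 1]`.
#' @param max_power Power density at 1 A, mW·mm^-2. Default 10.8.
#' @param curve Optional function current -> power overriding the linear
#'   default.
#' @return A list of class `oc_led_command` with `current_a` and `power`.
#' @export
map_UH_to_led_current <- function(U_H, max_power = 10.8, curve = NULL) {
  if (!is.numeric(U_H) || length(U_H) != 1L || is.na(U_H) ||
      U_H < 0 || U_H > 1)
    stop("`U_H` must be a single number in [0, 1]", call. = FALSE)
  power <- if (is.null(curve)) max_power * U_H else curve(U_H)
  structure(list(current_a = U_H, power = power, wavelength_nm = 590),
            class = "oc_led_command")
}

#' Map the integral-control output to fiber light power
#'
#' In vivo, optical feedback linearizes the LED driver so the control output
#' converts directly to light power as `G * u`.
#'
#' @param u Control output in `[0, 1]`.
#' @param G Fiber gain, mW·mm^-2 per unit control output. Must be positive.
#' @return Light power density, mW·mm^-2.
#' @export
map_u_to_fiber_power <- function(u, G) {
  if (!is.numeric(G) || length(G) != 1L || is.na(G) || G <= 0)
    stop("`G` must be a single positive number", call. = FALSE)
  if (any(u < 0 | u > 1)) stop("`u` must lie in [0, 1]", call. = FALSE)
  G * u
}

#' Waveform family specification
#'
#' Parameters of the optical waveform families used for excitatory
#' stimulation: `square` (the standard pulse-train mapping), `triangle`
#' (10 Hz ramps with a fixed rising slope), `sine` (half-wave-rectified
#' 10 Hz sinusoid), `prbs` (binary levels redrawn at 150 Hz from a
#' maximal-length shift-register sequence), and `continuous` (constant).
#'
#' @param kind One of `"square"`, `"triangle"`, `"sine"`, `"prbs"`,
#'   `"continuous"`.
#' @param carrier_freq Carrier frequency for the periodic kinds, Hz.
#'   Default 10.
#' @param rising_slope Triangle rising slope, mW·ms^-1·mm^-2. Default 0.22.
#' @param peak_coeff Peak power at `U_C = 1`, mW·mm^-2, for the triangle,
#'   sine, PRBS and continuous kinds. Default 13.4.
#' @param prbs_update PRBS update frequency, Hz. Default 150.
#' @param prbs_order Shift-register order of the PRBS generator. Default 15.
#' @param power_coeff Peak power of the `square` pulse-train mapping at
#'   `U_C = 1`. Default 13.2.
#' @return An object of class `oc_waveform_spec`.
#' @export
waveform_spec <- function(kind = c("square", "triangle", "sine", "prbs",
                                   "continuous"),
                          carrier_freq = 10, rising_slope = 0.22,
                          peak_coeff = 13.4, prbs_update = 150,
                          prbs_order = 15L, power_coeff = 13.2) {
  kind <- match.arg(kind)
  if (carrier_freq < 0 || rising_slope < 0 || peak_coeff < 0 ||
      prbs_update <= 0)
    stop("waveform parameters must be non-negative", call. = FALSE)
  structure(list(kind = kind, carrier_freq = carrier_freq,
                 rising_slope = rising_slope, peak_coeff = peak_coeff,
                 prbs_update = prbs_update, prbs_order = as.integer(prbs_order),
                 power_coeff = power_coeff),
            class = "oc_waveform_spec")
}

# Maximal-length linear feedback shift register (Fibonacci form).
# Taps are for known maximal-length polynomials; order 15 uses x^15+x^14+1,
# giving a period of 2^15 - 1 with ones exceeding zeros by exactly one.
.lfsr_taps <- function(order) {
  taps <- switch(as.character(order),
                 "7" = c(7L, 6L), "9" = c(9L, 5L), "10" = c(10L, 7L),
                 "11" = c(11L, 9L), "15" = c(15L, 14L))
  if (is.null(taps))
    stop("no maximal-length taps known for order ", order, call. = FALSE)
  taps
}

#' Generate a maximal-length pseudorandom binary sequence
#'
#' @param n Number of bits to generate.
#' @param order Shift-register order. Default 15 (period 32767).
#' @param init Initial register contents: integer vector of 0/1 of length
#'   `order`, not all zero. Default all ones.
#' @return Integer vector of 0/1 bits.
#' @export
prbs_bits <- function(n, order = 15L, init = NULL) {
  taps <- .lfsr_taps(order)
  reg <- if (is.null(init)) rep(1L, order) else as.integer(init)
  if (length(reg) != order || all(reg == 0L))
    stop("`init` must be a non-zero 0/1 vector of length `order`",
         call. = FALSE)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- reg[order]
    fb <- xor(reg[taps[1L]] == 1L, reg[taps[2L]] == 1L)
    reg <- c(as.integer(fb), reg[-order])
  }
  out
}

#' Render an optical waveform as a sampled light-power trace
#'
#' Renders the waveform family at a fixed `U_C` over `duration` seconds.
#' Square pulse trains follow the pulse-train mapping
#' ([map_Uc_to_pulse_params()]); pulses narrower than one sample are
#' rendered with energy-preserving fractional samples. Triangles rise at
#' `rising_slope` to a peak of `peak_coeff * U_C` and fall at the same
#' slope (the peak is limited to the value reachable within half a carrier
#' period). Sines are half-wave rectified (light power cannot be negative).
#' PRBS levels toggle between 0 and `peak_coeff * U_C` at `prbs_update` Hz
#' following a maximal-length shift-register sequence whose register is
#' seeded from `seed`.
#'
#' @param spec An `oc_waveform_spec`.
#' @param U_C Excitatory control variable in `[0, 1]`.
#' @param duration Trace duration, seconds.
#' @param sample_interval Sample interval, seconds. Default 0.001.
#' @param seed Integer seed for the PRBS register (ignored otherwise).
#' @return An object of class `oc_trace`: list with `dt`, `t`, `samples`
#'   (power density, mW·mm^-2) and `units`.
#' @export
render_waveform <- function(spec, U_C, duration, sample_interval = 0.001,
                            seed = 1L) {
  if (!inherits(spec, "oc_waveform_spec"))
    stop("`spec` must be an oc_waveform_spec", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (U_C < 0 || U_C > 1) stop("`U_C` must lie in [0, 1]", call. = FALSE)
  dt <- sample_interval
  n <- as.integer(round(duration / dt))
  t <- (seq_len(n) - 1) * dt
  peak <- spec$peak_coeff * U_C
  samples <- switch(
    spec$kind,
    continuous = rep(peak, n),
    sine = pmax(0, peak * sin(2 * pi * spec$carrier_freq * t)),
    triangle = {
      period <- 1 / spec$carrier_freq
      slope <- spec$rising_slope * 1000  # mW per second per mm^2
      pk <- min(peak, slope * period / 2)
      t_rise <- pk / slope
      ph <- t %% period
      ifelse(ph < t_rise, slope * ph, pmax(0, pk - slope * (ph - t_rise)))
    },
    prbs = {
      set.seed(as.integer(seed))
      init <- sample(c(0L, 1L), spec$prbs_order, replace = TRUE)
      if (all(init == 0L)) init[1L] <- 1L
      idx <- floor(t * spec$prbs_update) + 1
      bits <- prbs_bits(max(idx), order = spec$prbs_order, init = init)
      peak * bits[idx]
    },
    square = {
      cmd <- map_Uc_to_pulse_params(U_C, power_coeff = spec$power_coeff)
      width <- cmd$width_ms / 1000
      # pulse onsets where the phase accumulator wraps: t_k = k / freq
      onset <- if (cmd$freq_hz > 0 && width > 0)
        seq(1 / cmd$freq_hz, duration, by = 1 / cmd$freq_hz) else numeric(0)
      out <- numeric(n)
      for (on in onset) {
        # energy-preserving overlap of [on, on + width) with each sample
        i0 <- floor(on / dt) + 1
        i1 <- min(floor((on + width) / dt) + 1, n)
        for (i in i0:i1) {
          if (i > n) break
          lo <- (i - 1) * dt; hi <- i * dt
          ov <- max(0, min(hi, on + width) - max(lo, on))
          out[i] <- out[i] + cmd$power * ov / dt
        }
      }
      out
    },
    stop("unknown waveform kind: ", spec$kind, call. = FALSE))
  structure(list(dt = dt, t = t, samples = samples,
                 units = "mW/mm^2", kind = spec$kind),
            class = "oc_trace")
}

#' Render a punctate whisker-deflection train
#'
#' Each deflection has exponential rising and falling phases with a total
#' excursion of 8 degrees and 99% rise and fall times of 5 ms (average
#' rising-phase angular velocity 1600 deg/s); deflections repeat at
#' `train_freq` (10 Hz in the sensory-drive experiments). The exponential
#' phases are normalized so the commanded excursion is reached exactly at
#' the end of the 5 ms rise.
#'
#' @param train_freq Deflection train frequency, Hz (0 gives a flat trace).
#' @param duration Trace duration, seconds.
#' @param sample_interval Sample interval, seconds. Default 1e-4.
#' @param excursion_deg Total excursion, degrees. Default 8.
#' @param rise_time 99% rise (and fall) time, seconds. Default 0.005.
#' @return An `oc_trace` whose `samples` are angular position in degrees;
#'   attribute `onsets` gives deflection onset times.
#' @export
render_whisker_deflection <- function(train_freq, duration,
                                      sample_interval = 1e-4,
                                      excursion_deg = 8, rise_time = 0.005) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (train_freq < 0) stop("`train_freq` must be non-negative", call. = FALSE)
  if (train_freq > 0 && train_freq > 1 / (2 * rise_time))
    stop("`train_freq` infeasible: deflections overlap", call. = FALSE)
  dt <- sample_interval
  n <- as.integer(round(duration / dt))
  t <- (seq_len(n) - 1) * dt
  out <- numeric(n)
  onsets <- numeric(0)
  if (train_freq > 0) {
    # 99% rise in rise_time fixes the exponential time constant
    tau <- rise_time / log(100)
    norm <- 1 - exp(-rise_time / tau)  # = 0.99
    onsets <- seq(0, duration - 2 * rise_time, by = 1 / train_freq)
    for (on in onsets) {
      ri <- t >= on & t < on + rise_time
      fi <- t >= on + rise_time & t < on + 2 * rise_time
      out[ri] <- excursion_deg * (1 - exp(-(t[ri] - on) / tau)) / norm
      # falling phase: time-mirrored rise, returning to 0 at on + 2*rise
      out[fi] <- excursion_deg *
        (1 - exp(-(on + 2 * rise_time - t[fi]) / tau)) / norm
    }
  }
  structure(list(dt = dt, t = t, samples = out, units = "deg",
                 onsets = onsets),
            class = "oc_trace")
}
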