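# Multi-rate closed-loop engine: a 1 ms simulation grid, the rate filter
# ticking every 4 ms, controllers ticking every 10 ms on a latency-delayed
# rate estimate, with optional pre-pulse conditioning, control locking,
# open-loop replay, and parameter sweeps.

#' Loop timing of the closed-loop engine
#'
#' @param sim_step Master simulation step, s. Default 0.001.
#' @param filter_step Rate-filter update interval, s. Default 0.004.
#' @param control_step Controller update interval, s. Default 0.01.
#' @param loop_latency Delay between a spike being counted and the
#'   controller seeing its effect on the rate estimate, s (emulates online
#'   detection/classification latency). Default 0.005.
#' @return An object of class `oc_loop_timing`.
#' @export
loop_timing <- function(sim_step = 0.001, filter_step = 0.004,
                        control_step = 0.01, loop_latency = 0.005) {
  fs <- filter_step / sim_step
  cs <- control_step / sim_step
  if (abs(fs - round(fs)) > 1e-9 || abs(cs - round(cs)) > 1e-9)
    stop("filter_step and control_step must be integer multiples of sim_step",
         call. = FALSE)
  if (loop_latency < 0) stop("`loop_latency` must be >= 0", call. = FALSE)
  structure(list(sim_step = sim_step, filter_step = filter_step,
                 control_step = control_step, loop_latency = loop_latency),
            class = "oc_loop_timing")
}

#' PI controller front end for the closed-loop engine
#'
#' Bundles the PI law, its companion rate filter, and the stimulus mappings
#' into a controller the engine can run. The excitatory channel is rendered
#' with the chosen waveform family; the inhibitory channel is continuous
#' yellow light `U_H * led_max_power`.
#'
#' @param K,Ti,Ts,delta1,delta2 PI parameters; see [pi_config()].
#' @param tau Rate-filter time constant, s. Default 2.5.
#' @param waveform Excitatory waveform kind. Default `"square"`.
#' @param power_coeff Square-train peak power at `U_C = 1`. Default 13.2.
#' @param peak_coeff Peak power of the non-square waveform kinds.
#'   Default 13.4.
#' @param led_max_power Yellow power at `U_H = 1`, mW·mm^-2. Default 10.8.
#' @return An object of class `oc_controller` (type `"pi"`).
#' @export
pi_controller <- function(K = 0.1, Ti = 1, Ts = 0.01,
                          delta1 = 0.25, delta2 = 0.25, tau = 2.5,
                          waveform = "square", power_coeff = 13.2,
                          peak_coeff = 13.4, led_max_power = 10.8) {
  structure(list(type = "pi",
                 cfg = pi_config(K = K, Ti = Ti, Ts = Ts,
                                 delta1 = delta1, delta2 = delta2),
                 tau = tau,
                 waveform = waveform_spec(waveform,
                                          peak_coeff = peak_coeff,
                                          power_coeff = power_coeff),
                 led_max_power = led_max_power),
            class = "oc_controller")
}

#' Pure-integral controller front end (in vivo fiber stimulation)
#'
#' @param Ti,Ts Integral parameters; see [integral_config()].
#' @param tau Rate-filter time constant, s. Default 0.8 (single-unit
#'   control).
#' @param G Fiber gain, mW·mm^-2 per unit control output. Default 20.
#' @return An object of class `oc_controller` (type `"integral"`).
#' @export
integral_controller <- function(Ti = 1, Ts = 0.01, tau = 0.8, G = 20) {
  structure(list(type = "integral", cfg = integral_config(Ti = Ti, Ts = Ts),
                 tau = tau, G = G),
            class = "oc_controller")
}

#' On-off (bang-bang) controller front end
#'
#' @param mode `"excitatory"` (blue pulses while the integrated error is
#'   positive, capped at 10 Hz) or `"inhibitory"` (continuous yellow light
#'   while the integrated error is negative).
#' @param tau Rate-filter time constant, s. Default 2.5.
#' @param I_max Integrated-error bound, Hz·s/unit. Default 10.
#' @param pulse_width Excitatory pulse width, s. Default 0.005.
#' @param pulse_power Excitatory pulse power, mW·mm^-2. Default 13.4.
#' @param yellow_power Inhibitory on-phase power, mW·mm^-2. Default 11.8.
#' @param min_interval Minimum time between pulse onsets, s. Default 0.1.
#' @return An object of class `oc_controller` (type `"onoff"`).
#' @export
onoff_controller <- function(mode = c("excitatory", "inhibitory"), tau = 2.5,
                             I_max = 10, pulse_width = 0.005,
                             pulse_power = 13.4, yellow_power = 11.8,
                             min_interval = 0.1) {
  mode <- match.arg(mode)
  structure(list(type = "onoff", mode = mode, tau = tau, I_max = I_max,
                 pulse_width = pulse_width, pulse_power = pulse_power,
                 yellow_power = yellow_power, min_interval = min_interval),
            class = "oc_controller")
}

# grow-able spike buffer helpers -------------------------------------------

new_spike_buffer <- function(n0 = 4096L) {
  env <- new.env(parent = emptyenv())
  env$time <- numeric(n0); env$unit <- integer(n0); env$n <- 0L
  env
}

push_spikes <- function(buf, times, units) {
  m <- length(times)
  if (m == 0L) return(invisible(NULL))
  need <- buf$n + m
  if (need > length(buf$time)) {
    newlen <- max(2L * length(buf$time), need)
    length(buf$time) <- newlen
    length(buf$unit) <- newlen
  }
  idx <- (buf$n + 1L):need
  buf$time[idx] <- times
  buf$unit[idx] <- units
  buf$n <- need
  invisible(NULL)
}

spike_buffer_df <- function(buf) {
  data.frame(time = buf$time[seq_len(buf$n)], unit = buf$unit[seq_len(buf$n)])
}

#' Run a closed-loop firing-rate control trial
#'
#' Orchestrates a controller-plant loop on the multi-rate clock: the plant
#' advances every `sim_step`, the rate filter every `filter_step`, and the
#' controller every `control_step`, reading the rate estimate delayed by
#' `loop_latency`. When `pre_pulse` is on, a 10-s conditioning train of
#' `U_C = 1` stimuli is applied starting 20 s before control onset.
#'
#' @param plant An `oc_plant` (network, TCU, or static-gain test plant).
#' @param controller An `oc_controller`.
#' @param schedule An `oc_target_schedule` (times relative to control
#'   onset) or a single target rate.
#' @param duration Length of the control epoch, seconds.
#' @param timing An `oc_loop_timing`.
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param pre_pulse Apply the 10-s conditioning train 20 s before onset.
#' @param whisker `NULL`, or a list with `freq` (Hz), `start`, `stop`
#'   (seconds relative to control onset) describing a punctate
#'   whisker-deflection train (TCU plant only).
#' @param lock_at `NULL`, or the time (s, relative to onset) at which the
#'   control signal is frozen for the remainder of the trial.
#' @param lock_mode `"last-value"` freezes `u` at its most recent value;
#'   `"first-half-mean"` at its mean over `[0, lock_at]`.
#' @return An object of class `oc_trial`: spike events, the rate estimate,
#'   target, control-variable and optical traces on a shared time base,
#'   the seed, a configuration snapshot, and annotations.
#' @export
run_closed_loop <- function(plant, controller, schedule, duration,
                            timing = loop_timing(), seed = 1L,
                            pre_pulse = FALSE, whisker = NULL,
                            lock_at = NULL,
                            lock_mode = c("last-value", "first-half-mean")) {
  lock_mode <- match.arg(lock_mode)
  if (is.numeric(schedule)) schedule <- target_schedule(0, schedule)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (!is.null(lock_at)) {
    if (lock_at <= 0 || lock_at >= duration)
      stop("`lock_at` must lie strictly inside (0, duration)", call. = FALSE)
    if (controller$type == "onoff")
      stop("control locking is defined for the PI and integral controllers",
           call. = FALSE)
  }
  if (plant$type == "static" && controller$type == "onoff")
    stop("the static test plant supports the PI and integral controllers",
         call. = FALSE)
  if (!is.null(whisker) && plant$type != "tcu")
    stop("whisker input applies to the TCU plant", call. = FALSE)

  dt <- timing$sim_step
  fsteps <- as.integer(round(timing$filter_step / dt))
  csteps <- as.integer(round(timing$control_step / dt))
  lat <- as.integer(round(timing$loop_latency / dt))
  pre_dur <- if (pre_pulse) 20 else 0
  total <- pre_dur + duration
  n <- as.integer(round(total / dt))
  onset <- pre_dur
  n_units <- plant$params$n_units
  alpha <- compute_alpha(timing$filter_step, controller$tau)

  set.seed(as.integer(seed))
  st <- plant_init(plant, dt)

  # precomputed whisker drive (TCU only)
  whisker_pos <- NULL
  sens <- NULL
  if (!is.null(whisker)) {
    wtr <- render_whisker_deflection(whisker$freq,
                                     duration = whisker$stop - whisker$start,
                                     sample_interval = dt)
    whisker_pos <- numeric(n)
    i0 <- as.integer(round((onset + whisker$start) / dt))
    idx <- seq_along(wtr$samples) + i0
    keep <- idx >= 1L & idx <= n
    whisker_pos[idx[keep]] <- wtr$samples[keep]
    onsets_abs <- wtr$onsets + onset + whisker$start
    sens <- sensory_rate_trace(onsets_abs, plant$params, n, dt)
  }

  # trace storage
  f_ms <- numeric(n); blue_ms <- numeric(n); yellow_ms <- numeric(n)
  counts_ms <- numeric(n)
  nticks <- n %/% csteps
  u_t <- numeric(nticks); u_v <- numeric(nticks)
  uc_v <- numeric(nticks); uh_v <- numeric(nticks); tick <- 0L
  buf <- new_spike_buffer()

  # controller state
  ctype <- controller$type
  pist <- pi_state()
  oost <- if (ctype == "onoff")
    onoff_state(controller$mode, I_max = controller$I_max) else NULL
  U_C <- 0; U_H <- 0; u_cur <- 0
  locked <- FALSE; u_locked <- NA_real_

  # excitatory pulse renderer state (square trains / on-off pulses)
  ph <- 0; prem <- 0; ppeak <- 0
  p_freq <- 0; p_width <- 0; p_power <- 0
  # non-square waveform state
  wkind <- if (ctype == "pi") controller$waveform$kind else "none"
  wspec <- if (ctype == "pi") controller$waveform else NULL
  prbs_bit <- 0L; prbs_next <- 0
  prbs_reg <- NULL
  if (identical(wkind, "prbs")) {
    prbs_reg <- sample(c(0L, 1L), wspec$prbs_order, replace = TRUE)
    if (all(prbs_reg == 0L)) prbs_reg[1L] <- 1L
    prbs_taps <- .lfsr_taps(wspec$prbs_order)
  }
  pre_active <- FALSE

  f <- 0; acc <- 0
  is_net <- plant$type == "network"
  is_tcu <- plant$type == "tcu"
  is_static <- plant$type == "static"
  params <- plant$params
  g_static <- if (is_static) params$g else NA_real_

  for (k in seq_len(n)) {
    tk <- k * dt
    trel <- tk - onset

    # ---- excitatory light sample -----------------------------------------
    if (pre_pulse && tk <= 10 && ctype != "integral") {
      if (!pre_active) {            # engage the conditioning train
        cmd <- map_Uc_to_pulse_params(1, power_coeff = 13.2)
        p_freq <- cmd$freq_hz; p_width <- cmd$width_ms / 1000
        p_power <- cmd$power; pre_active <- TRUE
      }
    } else if (pre_active) {        # quiet gap before control onset
      p_freq <- 0; prem <- 0; pre_active <- FALSE
    }

    blue <- 0
    if (ctype == "integral") {
      blue <- controller$G * u_cur
      if (pre_pulse && tk <= 10) blue <- controller$G  # conditioning drive
    } else if (wkind %in% c("square", "none") || pre_active || trel <= 0) {
      # pulse-train channel (square PI stimuli, pre-pulse, on-off pulses)
      if (p_freq > 0) {
        ph <- ph + p_freq * dt
        if (ph >= 1) { ph <- ph - 1; prem <- p_width; ppeak <- p_power }
      }
      if (prem > 0) {
        blue <- ppeak * min(prem, dt) / dt
        prem <- prem - dt
        if (prem < 0) prem <- 0
      }
    } else if (wkind == "sine") {
      blue <- max(0, wspec$peak_coeff * U_C *
                    sin(2 * pi * wspec$carrier_freq * trel))
    } else if (wkind == "triangle") {
      period <- 1 / wspec$carrier_freq
      slope <- wspec$rising_slope * 1000
      pk <- min(wspec$peak_coeff * U_C, slope * period / 2)
      phx <- trel %% period
      t_rise <- pk / slope
      blue <- if (phx < t_rise) slope * phx else
        max(0, pk - slope * (phx - t_rise))
    } else if (wkind == "prbs") {
      if (trel >= prbs_next) {
        prbs_bit <- prbs_reg[wspec$prbs_order]
        fb <- xor(prbs_reg[prbs_taps[1L]] == 1L,
                  prbs_reg[prbs_taps[2L]] == 1L)
        prbs_reg <- c(as.integer(fb), prbs_reg[-wspec$prbs_order])
        prbs_next <- prbs_next + 1 / wspec$prbs_update
      }
      blue <- prbs_bit * wspec$peak_coeff * U_C
    } else if (wkind == "continuous") {
      blue <- wspec$peak_coeff * U_C
    }
    if (ctype == "onoff" && controller$mode == "excitatory" && prem > 0) {
      # handled by the shared pulse channel above
    }

    # ---- inhibitory light sample -----------------------------------------
    yellow <- 0
    if (ctype == "pi") {
      yellow <- controller$led_max_power * U_H
    } else if (ctype == "onoff" && controller$mode == "inhibitory" &&
               isTRUE(oost$gate)) {
      yellow <- controller$yellow_power
    }

    # ---- plant -----------------------------------------------------------
    if (is_net) {
      counts <- network_step(st, params, blue, yellow, dt)
      nsp <- sum(counts)
      if (nsp > 0L) {
        nz <- counts > 0L
        units <- rep.int(which(nz), counts[nz])
        push_spikes(buf, tk - dt + stats::runif(nsp) * dt, units)
      }
    } else if (is_tcu) {
      nsp <- tcu_step(st, params, blue,
                      if (is.null(sens)) 0 else sens[k], dt)
      if (nsp > 0L) push_spikes(buf, tk - dt + stats::runif(1) * dt, 1L)
    } else {
      drive <- if (ctype == "integral") u_cur else U_C
      nsp <- g_static * drive * n_units * dt
    }
    counts_ms[k] <- nsp
    acc <- acc + nsp
    blue_ms[k] <- blue
    yellow_ms[k] <- yellow

    # ---- rate filter and on-off accumulation -----------------------------
    if (k %% fsteps == 0L) {
      r <- acc / (n_units * timing$filter_step)
      f <- alpha * r + (1 - alpha) * f
      acc <- 0
      if (ctype == "onoff" && trel > 0) {
        fd <- f_ms[max(k - lat, 1L)]
        # the just-computed f is not yet in f_ms; delayed view is consistent
        e <- target_at(schedule, trel) - if (lat == 0L) f else fd
        if (controller$mode == "excitatory") {
          res <- onoff_excitatory_step(oost, e, timing$filter_step, tk,
                                       pulse_width = controller$pulse_width,
                                       pulse_power = controller$pulse_power,
                                       min_interval = controller$min_interval)
          oost <- res$state
          if (!is.null(res$pulse)) {
            prem <- controller$pulse_width
            ppeak <- controller$pulse_power
          }
        } else {
          res <- onoff_inhibitory_step(oost, e, timing$filter_step)
          oost <- res$state
        }
      }
    }
    f_ms[k] <- f

    # ---- PI / integral control tick --------------------------------------
    if ((ctype == "pi" || ctype == "integral") &&
        k %% csteps == 0L && trel > 0) {
      if (!is.null(lock_at) && !locked && trel >= lock_at) {
        u_locked <- if (lock_mode == "last-value") u_cur else {
          done <- seq_len(tick)
          mean(u_v[done][u_t[done] > 0 & u_t[done] <= lock_at])
        }
        locked <- TRUE
      }
      if (locked) {
        u_cur <- u_locked
        if (ctype == "pi") {
          uu <- split_control(u_cur, controller$cfg)
          U_C <- uu[[1L]]; U_H <- uu[[2L]]
        }
      } else {
        fd <- f_ms[max(k - lat, 1L)]
        e <- target_at(schedule, trel) - fd
        if (ctype == "pi") {
          pist <- pi_step(pist, controller$cfg, e)
          u_cur <- pist$u
          uu <- split_control(u_cur, controller$cfg)
          U_C <- uu[[1L]]; U_H <- uu[[2L]]
          if (wkind == "square") {
            cmd <- map_Uc_to_pulse_params(U_C,
                                          power_coeff = wspec$power_coeff)
            p_freq <- cmd$freq_hz
            p_width <- cmd$width_ms / 1000
            p_power <- cmd$power
          }
        } else {
          pist <- integral_step(pist, controller$cfg, e)
          u_cur <- pist$u
        }
      }
      tick <- tick + 1L
      u_t[tick] <- trel; u_v[tick] <- u_cur
      uc_v[tick] <- U_C; uh_v[tick] <- U_H
    }
  }

  tt <- seq_len(n) * dt
  keep <- seq_len(tick)
  structure(list(
    dt_sim = dt, n_steps = n, t = tt,
    spikes = spike_buffer_df(buf),
    f = f_ms,
    target = ifelse(tt > onset, target_at(schedule, tt - onset), NA_real_),
    blue = blue_ms, yellow = yellow_ms, counts = counts_ms,
    control = data.frame(t = u_t[keep], u = u_v[keep],
                         U_C = uc_v[keep], U_H = uh_v[keep]),
    whisker = whisker_pos,
    seed = as.integer(seed),
    config = list(plant = plant, controller = controller,
                  schedule = schedule, timing = timing,
                  duration = duration, pre_pulse = pre_pulse,
                  whisker = whisker, lock_at = lock_at,
                  lock_mode = if (is.null(lock_at)) NULL else lock_mode),
    annotations = list(
      control_onset = onset,
      pre_pulse_window = if (pre_pulse) c(0, 10) else NULL,
      lock_window = if (is.null(lock_at)) NULL
      else c(onset + lock_at, total),
      duration = duration, total = total)),
    class = "oc_trial")
}

#' Replay recorded optical traces in open loop
#'
#' Drives a plant with the optical traces stored in a previous trial
#' record, with no feedback. The plant is re-initialized from `seed`, so a
#' different seed emulates replay against a preparation whose excitability
#' has drifted since the recording.
#'
#' @param plant An `oc_plant`.
#' @param recorded An `oc_trial` containing full optical traces.
#' @param seed Integer seed for the replay plant.
#' @return An `oc_trial` (annotated as a replay; `control` is empty and the
#'   target trace is carried over for comparison).
#' @export
replay_open_loop <- function(plant, recorded, seed = 1L) {
  if (!inherits(recorded, "oc_trial"))
    stop("`recorded` must be an oc_trial", call. = FALSE)
  if (is.null(recorded$blue) || is.null(recorded$yellow) ||
      length(recorded$blue) == 0L)
    stop("`recorded` lacks optical traces", call. = FALSE)
  dt <- recorded$dt_sim
  n <- recorded$n_steps
  timing <- recorded$config$timing
  controller <- recorded$config$controller
  fsteps <- as.integer(round(timing$filter_step / dt))
  n_units <- plant$params$n_units
  alpha <- compute_alpha(timing$filter_step, controller$tau)

  set.seed(as.integer(seed))
  st <- plant_init(plant, dt)
  f_ms <- numeric(n); counts_ms <- numeric(n)
  buf <- new_spike_buffer()
  f <- 0; acc <- 0
  is_net <- plant$type == "network"
  params <- plant$params
  blue_in <- recorded$blue; yellow_in <- recorded$yellow
  for (k in seq_len(n)) {
    tk <- k * dt
    if (is_net) {
      counts <- network_step(st, params, blue_in[k], yellow_in[k], dt)
      nsp <- sum(counts)
      if (nsp > 0L) {
        nz <- counts > 0L
        push_spikes(buf, tk - dt + stats::runif(nsp) * dt,
                    rep.int(which(nz), counts[nz]))
      }
    } else if (plant$type == "tcu") {
      nsp <- tcu_step(st, params, blue_in[k], 0, dt)
      if (nsp > 0L) push_spikes(buf, tk - dt + stats::runif(1) * dt, 1L)
    } else {
      stop("replay requires a stochastic plant", call. = FALSE)
    }
    counts_ms[k] <- nsp
    acc <- acc + nsp
    if (k %% fsteps == 0L) {
      f <- alpha * (acc / (n_units * timing$filter_step)) + (1 - alpha) * f
      acc <- 0
    }
    f_ms[k] <- f
  }
  out <- recorded
  out$spikes <- spike_buffer_df(buf)
  out$f <- f_ms
  out$counts <- counts_ms
  out$control <- out$control[0, ]
  out$seed <- as.integer(seed)
  out$annotations$replay_of_seed <- recorded$seed
  out$annotations$replay <- TRUE
  out
}

#' Lock the control signal partway through a trial
#'
#' Runs the closed loop normally until `lock_at`, then freezes the control
#' signal (at its most recent value, or at its mean over the first part of
#' the trial) for the remainder.
#'
#' @inheritParams run_closed_loop
#' @param lock_at Time (s, relative to control onset) at which to lock.
#' @return An `oc_trial` whose annotations mark the lock window.
#' @export
lock_control <- function(plant, controller, schedule,
                         lock_mode = c("last-value", "first-half-mean"),
                         lock_at, duration, timing = loop_timing(),
                         seed = 1L, pre_pulse = FALSE) {
  lock_mode <- match.arg(lock_mode)
  if (lock_at >= duration)
    stop("`lock_at` must be smaller than `duration`", call. = FALSE)
  run_closed_loop(plant, controller, schedule, duration, timing = timing,
                  seed = seed, pre_pulse = pre_pulse,
                  lock_at = lock_at, lock_mode = lock_mode)
}

#' RMS tracking error of a trial over a window
#'
#' @param trial An `oc_trial`.
#' @param window Two times (s, relative to control onset); default the
#'   final 30 s of the control epoch (or the whole epoch if shorter).
#' @return RMS of `f - target` over the window, Hz/unit.
#' @export
trial_rms <- function(trial, window = NULL) {
  dur <- trial$annotations$duration
  if (is.null(window)) window <- c(max(0, dur - 30), dur)
  onset <- trial$annotations$control_onset
  rms_tracking_error(trial$f, trial$target, trial$t,
                     window = window + onset)
}

#' Sweep one controller or filter parameter across seeded trials
#'
#' Runs seeded closed-loop trials for each value of a single swept
#' parameter (`K`, `Ti`, or `tau`) and summarizes tracking accuracy and
#' firing-rate dispersion. Instability is flagged where the interquartile
#' range of the 1-s-binned controlled rate exceeds `iqr_multiple` times the
#' IQR at the nominal parameter value (the nominal value is appended to the
#' grid if absent).
#'
#' @param plant An `oc_plant`.
#' @param controller A PI or integral `oc_controller` holding the nominal
#'   parameter values.
#' @param schedule Target schedule or a single target rate.
#' @param grid Named list with exactly one element, e.g. `list(K = c(0.1,
#'   2))`, `list(Ti = ...)`, or `list(tau = ...)`.
#' @param trial_duration Trial length, seconds.
#' @param seeds Integer vector of seeds (one trial per value per seed).
#' @param timing An `oc_loop_timing`.
#' @param iqr_multiple Instability threshold. Default 3.
#' @param rate_bin Bin width (s) of the controlled-rate series whose
#'   dispersion is summarized. Default 1 s; sub-second bins expose
#'   faster oscillatory instabilities.
#' @param rms_window Window for the RMS summary (s, relative to onset);
#'   default the final half of the trial.
#' @return A data.frame with one row per (value, seed): `parameter`,
#'   `value`, `seed`, `rms`, `rate_var`, `rate_iqr`, `settled`, `unstable`.
#' @export
sweep_parameters <- function(plant, controller, schedule, grid,
                             trial_duration, seeds = 1:3,
                             timing = loop_timing(), iqr_multiple = 3,
                             rate_bin = 1, rms_window = NULL) {
  if (!is.list(grid) || length(grid) != 1L || is.null(names(grid)))
    stop("`grid` must be a named list varying exactly one parameter",
         call. = FALSE)
  par <- names(grid)
  if (!par %in% c("K", "Ti", "tau"))
    stop("swept parameter must be one of K, Ti, tau", call. = FALSE)
  values <- grid[[1L]]
  if (length(values) == 0L) stop("`grid` is empty", call. = FALSE)
  nominal <- if (par == "tau") controller$tau else controller$cfg[[par]]
  if (!any(abs(values - nominal) < 1e-12)) values <- c(values, nominal)
  if (is.numeric(schedule)) schedule <- target_schedule(0, schedule)
  if (is.null(rms_window))
    rms_window <- c(trial_duration / 2, trial_duration)

  rows <- list()
  for (v in values) {
    ctl <- controller
    if (par == "tau") ctl$tau <- v else ctl$cfg[[par]] <- v
    for (s in seeds) {
      tr <- run_closed_loop(plant, ctl, schedule, trial_duration,
                            timing = timing, seed = s)
      onset <- tr$annotations$control_onset
      rate1s <- binned_rate(tr$spikes$time, bin = rate_bin,
                            t_start = onset, t_end = onset + trial_duration,
                            n_units = plant$params$n_units)
      stime <- settling_time(tr$t - onset, tr$f,
                             target = target_at(schedule, 0),
                             onset = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, value = v, seed = s,
        rms = trial_rms(tr, rms_window),
        rate_var = stats::var(rate1s),
        rate_iqr = stats::IQR(rate1s),
        settled = is.finite(stime))
    }
  }
  out <- do.call(rbind, rows)
  ref <- stats::median(out$rate_iqr[abs(out$value - nominal) < 1e-12])
  agg <- tapply(out$rate_iqr, out$value, stats::median)
  out$unstable <- agg[as.character(out$value)] > iqr_multiple * ref
  rownames(out) <- NULL
  out
}
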