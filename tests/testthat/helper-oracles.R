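# Independent oracle implementations used to pin the semantics of the
# controllers and metrics: literal step-by-step transcriptions of the
# control equations, and exhaustive O(N^2) pair enumeration for the
# correlogram and synchrony index.

# literal transcription of the rate filter: f <- alpha*r + (1-alpha)*f
oracle_filter_trajectory <- function(n_spikes_seq, dt, tau, n_units, f0 = 0) {
  alpha <- 1 - exp(-dt / tau)
  f <- f0
  out <- numeric(length(n_spikes_seq))
  for (i in seq_along(n_spikes_seq)) {
    r <- n_spikes_seq[i] / (n_units * dt)
    f <- alpha * r + (1 - alpha) * f
    out[i] <- f
  }
  out
}

# literal transcription of the velocity-form PI law, split, and anti-windup
oracle_pi_trajectory <- function(e_seq, K = 0.1, Ti = 1, Ts = 0.01,
                                 d1 = 0.25, d2 = 0.25) {
  u <- 0; ep <- 0
  n <- length(e_seq)
  us <- UC <- UH <- numeric(n)
  for (i in seq_len(n)) {
    e <- e_seq[i]
    u <- u + K * (e - ep + (Ts / Ti) * e)
    ep <- e
    if (u < -d2) u <- -d2
    if (u > 1 - d1) u <- 1 - d1
    us[i] <- u
    UC[i] <- min(max(u + d1, 0), 1)
    UH[i] <- min(max(-u + d2, 0), 1)
  }
  list(u = us, U_C = UC, U_H = UH)
}

# literal transcription of the integral-only law with [0, 1] clipping
oracle_integral_trajectory <- function(e_seq, Ti = 1, Ts = 0.01) {
  u <- 0
  out <- numeric(length(e_seq))
  for (i in seq_along(e_seq)) {
    u <- u + (Ts / Ti) * e_seq[i]
    u <- min(max(u, 0), 1)
    out[i] <- u
  }
  out
}

# literal transcription of the on-off laws: accumulate e*dt, emit pulses
# (excitatory, >= 0.1 s apart while I_f > 0) or gate light (inhibitory,
# I_f < 0)
oracle_onoff_trajectory <- function(e_seq, dt, mode, I_max = 10,
                                    min_interval = 0.1) {
  I <- 0; t_last <- -Inf
  n <- length(e_seq)
  If_out <- numeric(n)
  ev <- logical(n)
  for (i in seq_len(n)) {
    t <- i * dt
    I <- I + e_seq[i] * dt
    if (I > I_max) I <- I_max
    if (I < -I_max) I <- -I_max
    If_out[i] <- I
    if (mode == "excitatory") {
      if (I > 0 && (t - t_last) >= min_interval - 1e-9) {
        ev[i] <- TRUE
        t_last <- t
      }
    } else {
      ev[i] <- I < 0
    }
  }
  list(I_f = If_out, events = ev)
}

# exhaustive pairwise lag enumeration between two trains
brute_force_lags <- function(ti, tj, max_lag) {
  out <- numeric(0)
  for (a in ti) for (b in tj) {
    d <- b - a
    if (abs(d) <= max_lag) out <- c(out, d)
  }
  out
}

brute_force_sync <- function(ti, tj, window = 0.010) {
  ncc <- 0L
  for (a in ti) for (b in tj) if (abs(b - a) <= window) ncc <- ncc + 1L
  ncc / sqrt((length(ti)^2 + length(tj)^2) / 2)
}

brute_force_correlogram <- function(ti, tj, bin, max_lag) {
  nb <- ceiling(max_lag / bin)
  edges <- seq(-nb, nb) * bin
  counts <- numeric(length(edges) - 1L)
  for (a in ti) for (b in tj) {
    d <- b - a
    if (d < edges[1] || d >= edges[length(edges)]) next
    i <- findInterval(d, edges, left.open = TRUE)
    if (i == 0L) i <- 1L  # lag exactly at the lowest edge
    counts[i] <- counts[i] + 1
  }
  counts / (length(ti) * bin)
}

# homogeneous Poisson spike train on [0, dur]
poisson_train <- function(rate, dur) {
  n <- stats::rpois(1, rate * dur)
  sort(stats::runif(n, 0, dur))
}

# a quiet network plant configuration for deterministic-ish checks:
# within-trial drift off, other structure intact
quiet_network <- function(...) {
  network_plant(network_plant_params(excit_sd = 0, ...))
}
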