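# Quantitative readouts of control performance and spike-train structure:
# RMS tracking error, LOWESS settling time, cross-correlograms, pairwise
# synchrony, CV of interspike intervals, spike-triggered averages, FWHM,
# and burst profiles.

#' Spike event list
#'
#' The universal activity record: ordered (time, unit) events.
#'
#' @param time Spike times, seconds (non-decreasing after sorting).
#' @param unit Integer unit ids (1-based).
#' @param t_start,t_end Observation window, seconds.
#' @param n_units Number of units (default: maximum id observed).
#' @return An object of class `oc_spikes`.
#' @export
spike_events <- function(time, unit = rep(1L, length(time)),
                         t_start = 0, t_end = NULL, n_units = NULL) {
  if (length(time) != length(unit))
    stop("`time` and `unit` must have equal length", call. = FALSE)
  o <- order(time)
  time <- time[o]; unit <- as.integer(unit[o])
  if (is.null(t_end)) t_end <- if (length(time)) max(time) else t_start
  if (is.null(n_units)) n_units <- if (length(unit)) max(unit) else 1L
  if (length(unit) && (min(unit) < 1L || max(unit) > n_units))
    stop("unit ids must lie in 1..n_units", call. = FALSE)
  structure(list(time = time, unit = unit,
                 t_start = t_start, t_end = t_end,
                 n_units = as.integer(n_units)),
            class = "oc_spikes")
}

#' Extract the spike events of a trial as an `oc_spikes` object
#'
#' @param trial An `oc_trial`.
#' @param window Optional window (s, absolute trial time) to restrict to.
#' @return An `oc_spikes`.
#' @export
trial_spikes <- function(trial, window = NULL) {
  sp <- trial$spikes
  t0 <- 0; t1 <- trial$n_steps * trial$dt_sim
  if (!is.null(window)) {
    keep <- sp$time >= window[1] & sp$time <= window[2]
    sp <- sp[keep, ]
    t0 <- window[1]; t1 <- window[2]
  }
  spike_events(sp$time, sp$unit, t_start = t0, t_end = t1,
               n_units = trial$config$plant$params$n_units)
}

#' Population firing rate in fixed bins
#'
#' @param times Spike times, seconds (all units pooled).
#' @param bin Bin width, seconds.
#' @param t_start,t_end Window, seconds.
#' @param n_units Number of units for Hz/unit normalization. Default 1.
#' @return Numeric vector of rates, Hz/unit, one per bin.
#' @export
binned_rate <- function(times, bin, t_start, t_end, n_units = 1L) {
  edges <- seq(t_start, t_end, by = bin)
  if (length(edges) < 2L) return(numeric(0))
  h <- graphics::hist(times[times >= t_start & times < edges[length(edges)]],
                      breaks = edges, plot = FALSE)
  h$counts / (n_units * bin)
}

#' Configuration for settling-time estimation
#'
#' @param band Half-width of the acceptance band around the target,
#'   Hz/unit. Default 0.25.
#' @param lowess_window Smoothing window of the LOWESS (tri-cube weight)
#'   smoother, seconds. Default 2.5.
#' @return An object of class `oc_settling_config`.
#' @export
settling_config <- function(band = 0.25, lowess_window = 2.5) {
  if (band <= 0) stop("`band` must be positive", call. = FALSE)
  if (lowess_window <= 0) stop("`lowess_window` must be positive",
                               call. = FALSE)
  structure(list(band = band, lowess_window = lowess_window,
                 weight = "tri-cube"),
            class = "oc_settling_config")
}

#' Configuration for correlogram and synchrony computation
#'
#' @param bin Correlogram bin width, seconds. Default 0.005.
#' @param max_lag Maximum lag, seconds. Default 0.25.
#' @param sync_window Half-width of the coincidence window for the
#'   synchrony index, seconds. Default 0.010.
#' @return An object of class `oc_correlogram_config`.
#' @export
correlogram_config <- function(bin = 0.005, max_lag = 0.25,
                               sync_window = 0.010) {
  if (bin <= 0) stop("`bin` must be positive", call. = FALSE)
  if (sync_window < bin)
    stop("`sync_window` must be at least `bin`", call. = FALSE)
  structure(list(bin = bin, max_lag = max_lag, sync_window = sync_window),
            class = "oc_correlogram_config")
}

#' RMS tracking error between a measured and a target rate trace
#'
#' @param f Measured rate trace, Hz/unit.
#' @param target Target trace (same length as `f`) or a single rate.
#' @param t Times of the samples, seconds.
#' @param window Two times `(t0, t1)` delimiting the evaluation window.
#' @return Root-mean-square of `f - target` over the window, Hz/unit.
#' @export
rms_tracking_error <- function(f, target, t, window) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("`window` must be (t0, t1) with t1 > t0", call. = FALSE)
  if (length(target) == 1L) target <- rep(target, length(f))
  keep <- t >= window[1] & t <= window[2] & !is.na(target)
  if (!any(keep)) stop("empty evaluation window", call. = FALSE)
  sqrt(mean((f[keep] - target[keep])^2))
}

#' Settling time of a controlled rate trace
#'
#' Smooths the rate trace with LOWESS (tri-cube weights, `lowess_window`
#' seconds wide) and returns the first time after `onset` at which the
#' smoothed trace enters the band `target +/- band` and never leaves it
#' again.
#'
#' @param t Sample times, seconds.
#' @param f Rate trace, Hz/unit.
#' @param target Target rate, Hz/unit.
#' @param cfg An `oc_settling_config`.
#' @param onset Control onset time, seconds. Default 0.
#' @return Settling time in seconds after onset, or `NA` if the trace never
#'   settles.
#' @export
settling_time <- function(t, f, target, cfg = settling_config(), onset = 0) {
  keep <- t >= onset
  t <- t[keep]; f <- f[keep]
  if (length(t) < 3L) stop("trace must extend beyond `onset`", call. = FALSE)
  span <- diff(range(t))
  frac <- min(1, cfg$lowess_window / span)
  sm <- stats::lowess(t, f, f = frac, iter = 0L)
  inside <- abs(sm$y - target) <= cfg$band
  if (!any(inside)) return(NA_real_)
  # first index from which the trace stays inside the band
  last_out <- max(c(0L, which(!inside)))
  if (last_out >= length(inside)) return(NA_real_)
  sm$x[last_out + 1L] - onset
}

# lags t_other - t_ref for all pairs within +/- max_lag (sorted inputs)
pair_lags <- function(ref, other, max_lag) {
  if (length(ref) == 0L || length(other) == 0L) return(numeric(0))
  lo <- findInterval(ref - max_lag, other, left.open = TRUE) + 1L
  hi <- findInterval(ref + max_lag, other)
  m <- hi - lo + 1L
  keep <- m > 0L
  if (!any(keep)) return(numeric(0))
  idx <- sequence(m[keep]) + rep(lo[keep] - 1L, m[keep])
  other[idx] - rep(ref[keep], m[keep])
}

#' Average unit-to-unit cross-correlogram
#'
#' Histograms pairwise spike-time lags at `cfg$bin` resolution over
#' `+/- cfg$max_lag`, for every requested unit pair, and averages across
#' pairs. With `normalize = "rate"` each pair's histogram is divided by its
#' reference spike count and the bin width, yielding a conditional firing
#' rate in Hz; `"counts"` returns raw averaged pair counts.
#'
#' @param spikes An `oc_spikes` with at least two units.
#' @param cfg An `oc_correlogram_config`.
#' @param unit_pairs Two-column matrix of unit-id pairs; default all
#'   unordered pairs of units that fired.
#' @param normalize `"rate"` (default) or `"counts"`.
#' @return A list of class `oc_correlogram` with `lag` (bin centers, s),
#'   `value` (pair-averaged), `n_pairs`, and the configuration.
#' @export
cross_correlogram <- function(spikes, cfg = correlogram_config(),
                              unit_pairs = NULL,
                              normalize = c("rate", "counts")) {
  normalize <- match.arg(normalize)
  if (spikes$n_units < 2L)
    stop("cross-correlogram requires at least 2 units", call. = FALSE)
  trains <- split(spikes$time, factor(spikes$unit,
                                      levels = seq_len(spikes$n_units)))
  if (is.null(unit_pairs)) {
    active <- which(vapply(trains, length, 1L) > 0L)
    if (length(active) < 2L)
      stop("cross-correlogram requires at least 2 active units",
           call. = FALSE)
    unit_pairs <- t(utils::combn(active, 2L))
  }
  nb <- ceiling(cfg$max_lag / cfg$bin)
  edges <- seq(-nb, nb) * cfg$bin
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  total <- numeric(length(centers))
  used <- 0L
  for (r in seq_len(nrow(unit_pairs))) {
    i <- unit_pairs[r, 1L]; j <- unit_pairs[r, 2L]
    ti <- trains[[i]]; tj <- trains[[j]]
    if (length(ti) == 0L || length(tj) == 0L) next
    lags <- pair_lags(ti, tj, nb * cfg$bin)
    h <- graphics::hist(lags[lags >= edges[1] & lags < edges[length(edges)]],
                        breaks = edges, plot = FALSE)$counts
    if (normalize == "rate") h <- h / (length(ti) * cfg$bin)
    total <- total + h
    used <- used + 1L
  }
  if (used == 0L) stop("no usable unit pairs", call. = FALSE)
  structure(list(lag = centers, value = total / used, n_pairs = used,
                 cfg = cfg, normalize = normalize),
            class = "oc_correlogram")
}

#' Pairwise synchrony index
#'
#' `Sync_ij = N_cc / sqrt((N_i^2 + N_j^2) / 2)`, where `N_cc` is the number
#' of spike pairs with `|t_i - t_j| <= sync_window` (each pair counted
#' once; a spike may participate in several pairs) and `N_i`, `N_j` are the
#' train spike counts.
#'
#' @param spikes_i,spikes_j Numeric spike-time vectors (seconds), both
#'   non-empty.
#' @param cfg An `oc_correlogram_config` (only `sync_window` is used).
#' @return The dimensionless synchrony index.
#' @export
synchrony_index <- function(spikes_i, spikes_j,
                            cfg = correlogram_config()) {
  if (length(spikes_i) == 0L || length(spikes_j) == 0L)
    stop("both spike trains must be non-empty", call. = FALSE)
  ti <- sort(spikes_i); tj <- sort(spikes_j)
  ncc <- length(pair_lags(ti, tj, cfg$sync_window))
  ncc / sqrt((length(ti)^2 + length(tj)^2) / 2)
}

#' Coefficient of variation of the interspike-interval distribution
#'
#' `CV_ISI = SD(ISI) / mean(ISI)`; by default the population (biased) SD
#' is used.
#'
#' @param spike_times Spike times of one unit, seconds (at least 3 spikes).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return The dimensionless CV (0 for a perfectly regular train, 1 for a
#'   long Poisson train).
#' @export
cv_isi <- function(spike_times, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(spike_times) < 3L)
    stop("at least 3 spikes are required", call. = FALSE)
  isi <- diff(sort(spike_times))
  m <- mean(isi)
  v <- stats::var(isi)
  if (sd_type == "population") v <- v * (length(isi) - 1) / length(isi)
  sqrt(v) / m
}

#' Spike-triggered average of a signal
#'
#' Averages signal segments aligned to spike times over the window
#' `[-t_pre, +t_post]`; spikes whose window is truncated by the trace ends
#' are excluded.
#'
#' @param spike_times Spike times, seconds.
#' @param signal Sampled signal values.
#' @param dt Sample interval of the signal, seconds.
#' @param window `c(t_pre, t_post)`, both positive, seconds.
#' @param t0 Time of the first signal sample. Default 0.
#' @return A list of class `oc_sta` with `lag` (s), `sta`, and `n_spikes`.
#' @export
spike_triggered_average <- function(spike_times, signal, dt,
                                    window = c(0.5, 0.5), t0 = 0) {
  npre <- as.integer(round(window[1] / dt))
  npost <- as.integer(round(window[2] / dt))
  idx <- as.integer(round((spike_times - t0) / dt)) + 1L
  ok <- idx - npre >= 1L & idx + npost <= length(signal)
  idx <- idx[ok]
  if (length(idx) == 0L)
    stop("no spikes with a full window inside the trace", call. = FALSE)
  offs <- -npre:npost
  acc <- numeric(length(offs))
  for (i in idx) acc <- acc + signal[i + offs]
  structure(list(lag = offs * dt, sta = acc / length(idx),
                 n_spikes = length(idx)),
            class = "oc_sta")
}

#' Full width at half maximum of a unimodal curve
#'
#' Subtracts a baseline (by default the mean of the first 10% of samples,
#' i.e. the start of the pre-window for a spike-triggered average), finds
#' the unique global maximum, and returns the width of the interval over
#' which the curve stays at or above half that maximum, with linear
#' interpolation at the crossings. Flat or non-positive-peak curves yield
#' `NA` with a warning.
#'
#' @param x Abscissa values (e.g. STA lags), or an `oc_sta`.
#' @param y Curve values (ignored when `x` is an `oc_sta`).
#' @param baseline Baseline level; default the mean of the first 10% of
#'   samples.
#' @return Width in the units of `x`, or `NA` if undefined.
#' @export
fwhm <- function(x, y = NULL, baseline = NULL) {
  if (inherits(x, "oc_sta")) { y <- x$sta; x <- x$lag }
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must be equal-length vectors (>= 3 samples)",
         call. = FALSE)
  if (is.null(baseline))
    baseline <- mean(y[seq_len(max(1L, floor(length(y) / 10)))])
  yy <- y - baseline
  pk <- max(yy)
  if (!is.finite(pk) || pk <= 0) {
    warning("FWHM undefined: flat curve or no unique maximum above baseline")
    return(NA_real_)
  }
  half <- pk / 2
  imax <- which.max(yy)
  # walk left from the peak to the half crossing
  il <- imax
  while (il > 1L && yy[il - 1L] >= half) il <- il - 1L
  xl <- if (il == 1L) x[1L] else {
    x[il - 1L] + (half - yy[il - 1L]) / (yy[il] - yy[il - 1L]) *
      (x[il] - x[il - 1L])
  }
  ir <- imax
  while (ir < length(yy) && yy[ir + 1L] >= half) ir <- ir + 1L
  xr <- if (ir == length(yy)) x[length(x)] else {
    x[ir] + (yy[ir] - half) / (yy[ir] - yy[ir + 1L]) * (x[ir + 1L] - x[ir])
  }
  xr - xl
}

#' Detect population bursts and average their rate profiles
#'
#' Bursts are maximal intervals during which the smoothed population rate
#' stays at or above a threshold (default twice the median rate); bursts
#' separated by gaps shorter than `min_gap` are merged. Rate profiles are
#' aligned at burst onset and averaged.
#'
#' @param spikes An `oc_spikes`.
#' @param threshold_rate Burst threshold, Hz/unit; default `2 *
#'   median(rate)`.
#' @param min_gap Minimum gap between distinct bursts, s. Default 0.1.
#' @param min_duration Minimum burst duration, s; shorter supra-threshold
#'   blips are discarded after merging. Default 0.05.
#' @param bin Rate bin width, s. Default 0.01.
#' @param smooth_sd Gaussian smoothing SD, s. Default 0.025.
#' @param profile_length Length of the aligned profile, s. Default 1.
#' @return A list of class `oc_bursts` with `bursts` (data.frame of onset,
#'   offset, duration), `profile_t`, `profile` (mean aligned rate), and
#'   `threshold`.
#' @export
burst_profile <- function(spikes, threshold_rate = NULL, min_gap = 0.1,
                          min_duration = 0.05, bin = 0.01,
                          smooth_sd = 0.025, profile_length = 1) {
  rate <- binned_rate(spikes$time, bin, spikes$t_start, spikes$t_end,
                      spikes$n_units)
  if (length(rate) == 0L)
    return(structure(list(bursts = data.frame(onset = numeric(0),
                                              offset = numeric(0),
                                              duration = numeric(0)),
                          profile_t = numeric(0), profile = numeric(0),
                          threshold = NA_real_),
                     class = "oc_bursts"))
  # Gaussian smoothing by discrete convolution
  hw <- max(1L, as.integer(ceiling(3 * smooth_sd / bin)))
  kern <- stats::dnorm(seq(-hw, hw) * bin, sd = smooth_sd)
  kern <- kern / sum(kern)
  sm <- as.numeric(stats::filter(c(rep(rate[1], hw), rate,
                                   rep(rate[length(rate)], hw)),
                                 kern, sides = 2))
  sm <- sm[(hw + 1L):(hw + length(rate))]
  if (is.null(threshold_rate)) threshold_rate <- 2 * stats::median(sm)
  above <- sm >= threshold_rate
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- spikes$t_start + (starts[r$values] - 1L) * bin
  off <- spikes$t_start + ends[r$values] * bin
  # merge bursts separated by short gaps
  if (length(on) > 1L) {
    merged_on <- c(); merged_off <- c()
    cur_on <- on[1]; cur_off <- off[1]
    for (i in seq_along(on)[-1]) {
      if (on[i] - cur_off < min_gap) {
        cur_off <- off[i]
      } else {
        merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
        cur_on <- on[i]; cur_off <- off[i]
      }
    }
    merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
    on <- merged_on; off <- merged_off
  }
  keep <- (off - on) >= min_duration
  on <- on[keep]; off <- off[keep]
  np <- as.integer(round(profile_length / bin))
  prof <- NULL
  if (length(on) > 0L) {
    segs <- matrix(NA_real_, nrow = length(on), ncol = np)
    for (i in seq_along(on)) {
      i0 <- as.integer(round((on[i] - spikes$t_start) / bin)) + 1L
      take <- i0:min(i0 + np - 1L, length(sm))
      segs[i, seq_along(take)] <- sm[take]
    }
    prof <- colMeans(segs, na.rm = TRUE)
  }
  structure(list(bursts = data.frame(onset = on, offset = off,
                                     duration = off - on),
                 profile_t = (seq_len(np) - 1L) * bin,
                 profile = prof %||% numeric(0),
                 threshold = threshold_rate),
            class = "oc_bursts")
}
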