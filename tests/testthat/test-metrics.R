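test_that("RMS tracking error handles constant and sinusoidal offsets", {
  t <- seq(0, 10, by = 0.01)
  f <- rep(3, length(t))
  expect_equal(rms_tracking_error(f, 3, t, c(0, 10)), 0)
  expect_equal(rms_tracking_error(f + 1, 3, t, c(0, 10)), 1)
  # sinusoidal offset over whole periods: RMS = 1/sqrt(2)
  t <- seq(0, 2 * pi, length.out = 20001)[-20001]
  expect_equal(rms_tracking_error(3 + sin(t), 3, t, c(0, 2 * pi)),
               1 / sqrt(2), tolerance = 1e-4)
  expect_error(rms_tracking_error(f, 3, t, c(5, 4)), "window")
})

test_that("settling time finds the band entry of a smoothed step", {
  t <- seq(0, 20, by = 0.01)
  # noiseless step to the target 3.2 s after onset
  f <- ifelse(t < 3.2, 0, 4)
  s <- settling_time(t, f, target = 4)
  expect_lt(abs(s - 3.2), 2.5 / 2)
  # already inside the band: settles immediately
  expect_equal(settling_time(t, rep(4, length(t)), target = 4), 0)
  # oscillating out of the band forever: not settled
  t2 <- seq(0, 19, by = 0.01)  # trace ends at an oscillation extreme
  f_osc <- 4 + sin(2 * pi * 0.25 * t2)
  expect_true(is.na(settling_time(t2, f_osc, target = 4,
                                  cfg = settling_config(band = 0.25,
                                                        lowess_window = 0.5))))
  expect_error(settling_config(band = 0))
})

test_that("correlogram and synchrony match exhaustive pair enumeration", {
  set.seed(13)
  cfg <- correlogram_config(bin = 0.005, max_lag = 0.1)
  for (rep in 1:4) {
    ti <- sort(runif(sample(50:200, 1), 0, 20))
    tj <- sort(runif(sample(50:200, 1), 0, 20))
    got <- cross_correlogram(
      spike_events(c(ti, tj), c(rep(1L, length(ti)), rep(2L, length(tj))),
                   n_units = 2L), cfg)
    expect_equal(got$value, brute_force_correlogram(ti, tj, cfg$bin,
                                                    cfg$max_lag),
                 tolerance = 1e-12)
    expect_equal(synchrony_index(ti, tj, cfg), brute_force_sync(ti, tj),
                 tolerance = 1e-12)
    # symmetry of the index; lag reversal of the correlogram
    expect_equal(synchrony_index(tj, ti, cfg), synchrony_index(ti, tj, cfg))
  }
})

test_that("synchrony is 1 for identical well-separated trains, 0 without coincidences", {
  ti <- seq(0.1, 10, by = 0.05)  # ISIs of 50 ms > 2 * 10 ms window
  expect_equal(synchrony_index(ti, ti), 1)
  expect_equal(synchrony_index(ti, ti + 0.02), 0)
  expect_error(synchrony_index(numeric(0), ti), "non-empty")
})

test_that("correlograms reflect independence, identity, and periodic co-drive", {
  set.seed(17)
  r <- 20
  ti <- poisson_train(r, 200)
  tj <- poisson_train(r, 200)
  sp <- spike_events(c(ti, tj), c(rep(1L, length(ti)), rep(2L, length(tj))),
                     t_end = 200, n_units = 2L)
  cc <- cross_correlogram(sp, correlogram_config(bin = 0.005, max_lag = 0.05))
  # independent stationary trains: flat at the firing rate
  se <- sqrt(r * length(ti) * 0.005) / (length(ti) * 0.005)
  expect_true(all(abs(cc$value - r) < 4 * se))
  # identical trains: dominant zero-lag peak
  sp2 <- spike_events(c(ti, ti), c(rep(1L, length(ti)), rep(2L, length(ti))),
                      t_end = 200, n_units = 2L)
  cc2 <- cross_correlogram(sp2, correlogram_config(bin = 0.005,
                                                   max_lag = 0.05))
  expect_lte(abs(cc2$lag[which.max(cc2$value)]), 0.003)
  # 10 Hz co-driven trains: side peaks at +/- 100 ms
  base <- rep(seq(0.05, 199.95, by = 0.1), each = 1)
  t1 <- base + rnorm(length(base), sd = 0.002)
  t2 <- base + rnorm(length(base), sd = 0.002)
  sp3 <- spike_events(c(t1, t2), c(rep(1L, length(t1)), rep(2L, length(t2))),
                      t_end = 200, n_units = 2L)
  cc3 <- cross_correlogram(sp3, correlogram_config(bin = 0.005,
                                                   max_lag = 0.15))
  v_at <- function(lag) cc3$value[which.min(abs(cc3$lag - lag))]
  expect_gt(v_at(0.1), 5 * v_at(0.05))
  expect_gt(v_at(-0.1), 5 * v_at(-0.05))
})

test_that("CV_ISI distinguishes regular, Poisson, and the hand-worked case", {
  expect_equal(cv_isi(seq(0, 10, by = 0.1)), 0)
  set.seed(19)
  tr <- cumsum(rexp(10000, 20))
  expect_equal(cv_isi(tr), 1, tolerance = 0.05)
  # ISIs {1, 1, 4}: population SD / mean = sqrt(2)/2
  expect_equal(cv_isi(c(0, 1, 2, 6)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cv_isi(c(0, 1, 2, 6), sd_type = "sample"),
               sqrt(3) / 2, tolerance = 1e-12)
  expect_error(cv_isi(c(0, 1)), "3 spikes")
})

test_that("the spike-triggered average recovers constants, noise nulls, and bumps", {
  dt <- 0.001
  n <- 60000
  # constant signal: flat STA at the constant
  sta <- spike_triggered_average(runif(100, 5, 55), rep(2.5, n), dt,
                                 window = c(0.2, 0.2))
  expect_true(all(sta$sta == 2.5))
  # independence: zero-mean noise STA shrinks to 0
  set.seed(23)
  sig <- rnorm(n)
  spikes <- runif(2000, 1, 59)
  sta2 <- spike_triggered_average(spikes, sig, dt, window = c(0.05, 0.05))
  expect_lt(max(abs(sta2$sta)), 4 / sqrt(2000))
  # truncated windows excluded
  sta3 <- spike_triggered_average(c(0.01, 30), rep(1, n), dt,
                                  window = c(0.1, 0.1))
  expect_equal(sta3$n_spikes, 1L)
  expect_error(spike_triggered_average(0.01, rep(1, 100), dt,
                                       window = c(0.5, 0.5)), "window")
})

test_that("STA of spikes at Gaussian bump peaks reproduces the bump, FWHM = 2.3548 sigma", {
  dt <- 0.001
  sigma <- 0.02
  centers <- seq(1, 999, by = 1)
  t <- seq(0, 1000, by = dt)
  sig <- numeric(length(t))
  for (cn in centers) {
    i <- which(t > cn - 4 * sigma & t < cn + 4 * sigma)
    sig[i] <- sig[i] + exp(-(t[i] - cn)^2 / (2 * sigma^2))
  }
  set.seed(29)
  spikes <- centers + rnorm(length(centers), sd = 1e-4)
  sta <- spike_triggered_average(spikes, sig, dt, window = c(0.2, 0.2),
                                 t0 = 0)
  bump <- exp(-sta$lag^2 / (2 * sigma^2))
  expect_lt(max(abs(sta$sta - bump)), 0.05)
  w <- fwhm(sta)
  expect_lt(abs(w - 2.3548 * sigma), dt + 1e-9)
})

test_that("FWHM handles rectangles and flags flat curves", {
  x <- seq(0, 1, by = 0.001)
  y <- as.numeric(x >= 0.4 & x <= 0.6)
  expect_lt(abs(fwhm(x, y) - 0.2), 0.0015)  # within ~one sample
  expect_warning(w <- fwhm(x, rep(1, length(x))), "undefined")
  expect_true(is.na(w))
  # Gaussian closed form
  g <- exp(-(x - 0.5)^2 / (2 * 0.05^2))
  expect_equal(fwhm(x, g), 2.3548 * 0.05, tolerance = 0.002)
})

test_that("burst detection finds injected bursts and merges close ones", {
  set.seed(31)
  # low background with two square bursts of known duration
  bg <- poisson_train(2 * 5, 20)  # 5 units at 2 Hz/unit pooled
  b1 <- poisson_train(60 * 5, 0.5) + 5
  b2 <- poisson_train(60 * 5, 0.5) + 12
  sp <- spike_events(c(bg, b1, b2), t_start = 0, t_end = 20, n_units = 5L)
  bp <- burst_profile(sp, threshold_rate = 10)
  expect_equal(nrow(bp$bursts), 2)
  expect_lt(abs(bp$bursts$duration[1] - 0.5), 0.15)
  expect_lt(abs(bp$bursts$onset[1] - 5), 0.1)
  # two bursts closer than min_gap merge into one
  b3 <- poisson_train(60 * 5, 0.3) + 5.85
  sp2 <- spike_events(c(bg, b1, b3), t_start = 0, t_end = 20, n_units = 5L)
  bp2 <- burst_profile(sp2, threshold_rate = 10, min_gap = 0.5)
  expect_equal(nrow(bp2$bursts), 1)
  # constant sub-threshold activity: no bursts
  bp3 <- burst_profile(spike_events(bg, t_start = 0, t_end = 20,
                                    n_units = 5L), threshold_rate = 10)
  expect_equal(nrow(bp3$bursts), 0)
})

test_that("metrics are invariant under a global time shift", {
  set.seed(37)
  ti <- sort(runif(150, 0, 30))
  tj <- sort(runif(120, 0, 30))
  shift <- 123.456
  expect_equal(synchrony_index(ti, tj), synchrony_index(ti + shift,
                                                        tj + shift))
  expect_equal(cv_isi(ti), cv_isi(ti + shift))
  sp <- spike_events(c(ti, tj), c(rep(1L, 150), rep(2L, 120)), n_units = 2L)
  sps <- spike_events(c(ti, tj) + shift, c(rep(1L, 150), rep(2L, 120)),
                      n_units = 2L)
  expect_equal(cross_correlogram(sp)$value, cross_correlogram(sps)$value)
})
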