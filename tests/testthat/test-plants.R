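# Helper: drive a network plant open loop with constant light and return
# the per-step population counts.
drive_network <- function(plant, blue, yellow, dur, seed, dt = 0.001) {
  set.seed(seed)
  st <- plant_init(plant, dt)
  p <- plant$params
  n <- as.integer(round(dur / dt))
  counts <- numeric(n)
  for (k in seq_len(n))
    counts[k] <- sum(network_step(st, p, blue, yellow, dt))
  counts
}

mean_power_at <- function(U_C) (10 * U_C + 10) * (5 * U_C / 1000) * 13.2 * U_C

test_that("drug conditions modify parameters as printed and keep originals", {
  p <- network_plant_params(spont_rate = 4.0)
  q <- apply_drug(p, "CNQX")
  expect_equal(q$spont_rate, 1.032)          # -74.2%
  expect_equal(p$spont_rate, 4.0)            # untouched
  expect_equal(apply_drug(p, "AP5")$spont_rate, 4.0 * 0.334)
  b <- apply_drug(p, "bicuculline")
  expect_equal(b$spont_rate, 4.0 * 4.57)
  expect_equal(b$dose_max, 5.1)              # capped dynamic range
  expect_identical(apply_drug(p, "none")$spont_rate, p$spont_rate)
  expect_error(apply_drug(p, "TTX"))
})

test_that("plants are deterministic given the seed", {
  pl <- network_plant()
  a <- drive_network(pl, 0.2, 0, 2, seed = 21)
  b <- drive_network(pl, 0.2, 0, 2, seed = 21)
  expect_identical(a, b)
  c <- drive_network(pl, 0.2, 0, 2, seed = 22)
  expect_false(identical(a, c))
})

test_that("zero light yields the spontaneous rate on average", {
  pl <- quiet_network(instance_sd = 0)
  counts <- drive_network(pl, 0, 0, 60, seed = 2)
  rate <- sum(counts) / (30 * 60)
  se <- sqrt(sum(counts)) / (30 * 60)
  # bursting inflates the variance beyond Poisson; allow a wide 3-SE-style band
  expect_lt(abs(rate - 1.5), max(3 * se, 0.35))
})

test_that("driven firing saturates near 12.5 Hz/unit at the U_C = 0.47 drive", {
  pl <- quiet_network()
  pw <- mean_power_at(0.47)
  start_rates <- vapply(1:12, function(s) {
    counts <- drive_network(pl, pw, 0, 3, seed = 300 + s)
    sum(counts) / (30 * 3)
  }, numeric(1))
  expect_equal(mean(start_rates), 12.5, tolerance = 0.10)
})

test_that("sustained saturating drive adapts over a 60-s trial", {
  pl <- quiet_network(instance_sd = 0)
  decline <- vapply(1:3, function(s) {
    counts <- drive_network(pl, mean_power_at(0.47), 0, 60, seed = 76 + s)
    sum(counts[1:10000]) / (30 * 10) - sum(counts[50001:60000]) / (30 * 10)
  }, numeric(1))
  # expected decline ~1.6 Hz/unit (~13% of the driven rate); bursts add
  # per-window noise, so average across seeds
  expect_gt(mean(decline), 1)
})

test_that("yellow light suppresses firing to the 0.04 Hz/unit floor", {
  pl <- quiet_network()
  yellow <- 10.8 * 0.15   # the U_H = 0.15 equivalent power
  rates <- vapply(1:6, function(s) {
    counts <- drive_network(pl, 0, yellow, 30, seed = 400 + s)
    sum(counts[3001:30000]) / (30 * 27)  # skip the settling transient
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.06)  # 0.04 +/- 50%
})

test_that("rate responds monotonically to blue and yellow drive", {
  pl <- quiet_network(instance_sd = 0)
  blues <- c(0, mean_power_at(0.15), mean_power_at(0.3), mean_power_at(0.6))
  rb <- vapply(blues, function(b)
    sum(drive_network(pl, b, 0, 20, seed = 50)) / (30 * 20), numeric(1))
  expect_true(all(diff(rb) > -0.3))  # non-decreasing within noise
  expect_gt(rb[4], rb[1] + 5)
  yellows <- c(0, 0.2, 0.5, 1.6)
  ry <- vapply(yellows, function(y)
    sum(drive_network(pl, 0, y, 20, seed = 51)) / (30 * 20), numeric(1))
  expect_true(all(diff(ry) < 0.3))   # non-increasing within noise
  expect_lt(ry[4], ry[1] / 5)
})

test_that("the TCU plant obeys Poisson thinning under constant drive", {
  p <- tcu_plant_params(adapt_depth = 0, excit_sd = 0, instance_sd = 0,
                        burst_rate = 0)
  pl <- tcu_plant(p)
  dt <- 0.001
  for (pw in c(0, 4, 8)) {
    set.seed(600 + pw)
    st <- plant_init(pl, dt)
    n <- 60000L
    spikes <- 0L
    for (k in seq_len(n)) spikes <- spikes + tcu_step(st, p, pw, 0, dt)
    rate <- spikes / 60
    expected <- p$baseline + p$opsin_gain * pw
    se <- sqrt(spikes) / 60
    expect_lt(abs(rate - expected), 3 * se + 0.05 * expected)
  }
})

test_that("spontaneous TCU firing is bursty; driven firing is Poisson-like", {
  p <- tcu_plant_params(excit_sd = 0, instance_sd = 0)
  pl <- tcu_plant(p)
  dt <- 0.001
  run_tcu <- function(pw, dur, seed) {
    set.seed(seed)
    st <- plant_init(pl, dt)
    tms <- numeric(0)
    for (k in seq_len(as.integer(dur / dt)))
      if (tcu_step(st, p, pw, 0, dt) > 0L) tms <- c(tms, k * dt)
    tms
  }
  spont <- run_tcu(0, 120, 31)
  expect_gt(cv_isi(spont), 1.3)         # burst-dominated spontaneous mode
  p2 <- tcu_plant_params(adapt_depth = 0, excit_sd = 0, instance_sd = 0)
  pl <- tcu_plant(p2); p <- p2
  driven <- run_tcu(10, 120, 32)
  expect_lt(cv_isi(driven), 1.3)        # near-Poisson under steady drive
  expect_gt(cv_isi(driven), 0.7)
})

test_that("whisker deflections evoke short-latency locked spikes", {
  p <- tcu_plant_params(baseline = 0.5, excit_sd = 0, instance_sd = 0,
                        kernel_amplitude = 3)
  pl <- tcu_plant(p)
  dt <- 0.001
  onsets <- seq(1, 29, by = 0.1)   # 10 Hz train
  sens <- optoclamp:::sensory_rate_trace(onsets, p, 30000L, dt)
  set.seed(41)
  st <- plant_init(pl, dt)
  tms <- numeric(0)
  for (k in seq_len(30000L))
    if (tcu_step(st, p, 0, sens[k], dt) > 0L) tms <- c(tms, k * dt)
  # most spikes fall within the kernel window after a deflection onset
  phase <- (tms - 1) %% 0.1
  locked <- mean(phase > p$kernel_latency - 0.004 &
                   phase < p$kernel_latency + 0.004)
  expect_gt(locked, 0.6)
})
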