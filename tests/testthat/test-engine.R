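test_that("trials are deterministic given the seed and honor the latency", {
  pl <- network_plant()
  a <- run_closed_loop(pl, pi_controller(), 3, duration = 5, seed = 8)
  b <- run_closed_loop(pl, pi_controller(), 3, duration = 5, seed = 8)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$f, b$f)
  # changing only the loop latency changes the outcome
  d <- run_closed_loop(pl, pi_controller(), 3, duration = 5, seed = 8,
                       timing = loop_timing(loop_latency = 0.02))
  expect_false(identical(a$spikes, d$spikes))
})

test_that("every emitted spike appears exactly once in the record", {
  tr <- run_closed_loop(network_plant(), pi_controller(), 4, duration = 5,
                        seed = 12)
  expect_equal(nrow(tr$spikes), sum(tr$counts))
  # spike times sit inside their source steps
  expect_true(all(tr$spikes$time >= 0 & tr$spikes$time <= 5))
  expect_true(all(tr$spikes$unit >= 1 & tr$spikes$unit <= 30))
})

test_that("PI control on a static-gain plant nulls the steady-state error", {
  tr <- run_closed_loop(static_gain_plant(10), pi_controller(), 4,
                        duration = 30, seed = 1)
  expect_lt(max(abs(tr$f[tr$t > 25] - 4)) / 4, 0.01)
  # and for a different gain and target
  tr2 <- run_closed_loop(static_gain_plant(30), pi_controller(), 7,
                         duration = 30, seed = 1)
  expect_lt(max(abs(tr2$f[tr2$t > 25] - 7)) / 7, 0.01)
})

test_that("a zero target with inhibitory capability silences the network", {
  tr <- run_closed_loop(network_plant(), pi_controller(), 0, duration = 40,
                        seed = 5)
  final <- tr$t > 10
  expect_lt(sum(tr$counts[final]) / (30 * 30), 0.1)
})

test_that("the control output is continuous across target-segment switches", {
  sc <- target_schedule(c(0, 10), c(2, 5))
  tr <- run_closed_loop(static_gain_plant(10), pi_controller(), sc,
                        duration = 20, seed = 1)
  u <- tr$control$u
  # no reset at the boundary: per-tick jumps bounded by the PI increment
  expect_lt(max(abs(diff(u))), 0.12 * 3 + 1e-9)
  i_before <- max(which(tr$control$t <= 10))
  expect_lt(abs(u[i_before + 1L] - u[i_before]), 0.35)
  expect_gt(min(u[tr$control$t > 15]), u[i_before] - 0.05)
})

test_that("pre-pulse conditioning precedes control onset", {
  tr <- run_closed_loop(network_plant(), pi_controller(), 2, duration = 5,
                        seed = 3, pre_pulse = TRUE)
  expect_equal(tr$annotations$control_onset, 20)
  expect_gt(max(tr$blue[tr$t <= 10]), 13)       # conditioning train on
  expect_equal(max(tr$blue[tr$t > 10 & tr$t <= 19.9]), 0)  # quiet gap
  expect_true(all(is.na(tr$target[tr$t <= 20])))
})

test_that("open-loop replay is exact for the same seed and fails under drift", {
  pl <- network_plant()
  cl <- run_closed_loop(pl, pi_controller(), 4, duration = 20, seed = 44)
  same <- replay_open_loop(pl, cl, seed = 44)
  expect_identical(same$spikes, cl$spikes)
  # re-seeded plant with drifted excitability: worse tracking than closed loop
  drift <- replay_open_loop(pl, cl, seed = 4567)
  expect_gt(trial_rms(drift, c(5, 20)), trial_rms(cl, c(5, 20)))
  # records without optical traces are rejected
  broken <- cl; broken$blue <- numeric(0)
  expect_error(replay_open_loop(pl, broken, seed = 1), "optical")
})

test_that("replay onto a drug-modified plant misses the target", {
  pl <- network_plant()
  cl <- run_closed_loop(pl, pi_controller(), 4, duration = 20, seed = 46)
  drugged <- network_plant(apply_drug(network_plant_params(), "bicuculline"))
  rp <- replay_open_loop(drugged, cl, seed = 46)
  mean_rate <- sum(rp$counts[rp$t > 5]) / (30 * 15)
  expect_gt(abs(mean_rate - 4), 0.5)
})

test_that("locking the control signal degrades tracking on the adapting TCU", {
  pre <- c(7, 15); post <- c(15, 30)
  worse <- 0L
  for (s in 1:3) {
    tr <- lock_control(tcu_plant(), integral_controller(), 30, "last-value",
                       lock_at = 15, duration = 30, seed = 70 + s)
    if (trial_rms(tr, post) > trial_rms(tr, pre)) worse <- worse + 1L
    expect_equal(tr$annotations$lock_window[1], 15)
  }
  expect_gte(worse, 2L)
  # locking on the static plant changes nothing once settled
  tr <- lock_control(static_gain_plant(10), pi_controller(), 4, "last-value",
                     lock_at = 20, duration = 30, seed = 1)
  expect_lt(abs(trial_rms(tr, c(25, 30)) - trial_rms(tr, c(15, 20))), 0.01)
  expect_error(lock_control(tcu_plant(), integral_controller(), 30,
                            "last-value", lock_at = 30, duration = 30),
               "lock_at")
})

test_that("whisker drive evokes locked spikes without breaking rate control", {
  tr <- run_closed_loop(tcu_plant(), integral_controller(), 30,
                        duration = 30, seed = 90,
                        whisker = list(freq = 10, start = 10, stop = 20))
  expect_false(is.null(tr$whisker))
  expect_equal(max(tr$whisker), 8, tolerance = 0.01)
  # mean rate stays near the target through the whisker epoch
  rate_whisk <- sum(tr$counts[tr$t > 12 & tr$t <= 20]) / 8
  expect_lt(abs(rate_whisk - 30), 12)
  expect_error(run_closed_loop(network_plant(), pi_controller(), 3, 5,
                               whisker = list(freq = 10, start = 0,
                                              stop = 2)),
               "whisker")
})

test_that("parameter sweeps summarize per value and flag instability direction", {
  pl <- network_plant()
  sw <- sweep_parameters(pl, pi_controller(), 4, list(K = c(0.1, 2)),
                         trial_duration = 20, seeds = 1:2)
  expect_equal(nrow(sw), 4)
  v_low <- median(sw$rate_iqr[sw$value == 0.1])
  v_high <- median(sw$rate_iqr[sw$value == 2])
  expect_gt(v_high, v_low)
  # singleton grid at the nominal value reduces to plain trials
  sw1 <- sweep_parameters(pl, pi_controller(), 4, list(K = 0.1),
                          trial_duration = 10, seeds = 1)
  expect_equal(nrow(sw1), 1)
  tr <- run_closed_loop(pl, pi_controller(), 4, duration = 10, seed = 1)
  expect_equal(sw1$rms, trial_rms(tr, c(5, 10)), tolerance = 1e-12)
  expect_error(sweep_parameters(pl, pi_controller(), 4, list(), 10),
               "grid")
  expect_error(sweep_parameters(pl, pi_controller(), 4,
                                list(K = 1, Ti = 1), 10), "grid")
})
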