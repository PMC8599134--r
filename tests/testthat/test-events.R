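test_that("accelerometer deviation measures distance of the norm from gravity", {
  expect_equal(accel_deviation(rbind(c(0, 0, 9.81))), 0)
  expect_equal(accel_deviation(rbind(c(0, 0, 0))), 9.81)
  expect_equal(accel_deviation(rbind(c(3, 4, 0))), 4.81)
})

test_that("acausal hysteresis matches the hand-traced example and limits", {
  h <- 0.23
  expect_equal(acausal_hysteresis(rep(0, 20), th = 1, h = h), rep(0L, 20))
  expect_equal(acausal_hysteresis(rep(2, 20), th = 1, h = h), rep(1L, 20))
  # the backward pass clears the trailing in-band hold at index 4
  x <- c(0, 0, 3, 0.5, 0, 3, 0, 0)
  expect_equal(acausal_hysteresis(x, th = 1, h = h),
               c(0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L))
})

test_that("hysteresis and pruning match brute-force oracles on random signals", {
  set.seed(101)
  for (i in 1:500) {
    x <- abs(stats::rnorm(40, sd = 2))
    th <- stats::runif(1, 0.5, 3)
    h <- stats::runif(1, 0, 0.5)
    expect_identical(acausal_hysteresis(x, th, h), oracle_hysteresis(x, th, h))
  }
  for (i in 1:500) {
    r <- sample(0:1, 30, replace = TRUE)
    mz <- sample(0:4, 1)
    mo <- sample(0:4, 1)
    expect_identical(prune_short_phases(r, mz, mo, ts = 1),
                     oracle_prune(r, mz, mo, ts = 1))
  }
})

test_that("hysteresis output is invariant to joint scaling of signal and threshold", {
  set.seed(7)
  x <- abs(stats::rnorm(200))
  for (c_scale in c(0.01, 3, 1e4))
    expect_identical(acausal_hysteresis(c_scale * x, c_scale * 0.8, 0.23),
                     acausal_hysteresis(x, 0.8, 0.23))
})

test_that("short-phase pruning follows the zero-then-one order and spares boundaries", {
  expect_equal(prune_short_phases(rep(1L, 10), 2, 2, ts = 1), rep(1L, 10))
  expect_equal(prune_short_phases(c(1L, 1L, 0L, 1L, 1L), 2, 0, ts = 1), rep(1L, 5))
  expect_equal(prune_short_phases(c(1L, 0L, 0L, 1L, 0L, 1L, 1L), 2, 2, ts = 1),
               c(1L, 0L, 0L, 1L, 1L, 1L, 1L))
  # idempotence
  set.seed(11)
  for (i in 1:50) {
    r <- sample(0:1, 40, replace = TRUE)
    once <- prune_short_phases(r, 3, 2, ts = 1)
    expect_identical(prune_short_phases(once, 3, 2, ts = 1), once)
  }
})

test_that("threshold adaptation reaches the two-level closed form and fixed point", {
  x <- c(rep(0, 60), rep(10, 60))
  expect_equal(auto_threshold(x, w = 0.85, lower_bound = 0), 1.5)
  expect_equal(auto_threshold(x, w = 0.85, lower_bound = 1.8), 1.8)
  expect_equal(auto_threshold(x, w = 0.5, lower_bound = 0), 5)
  # constant signal degenerates to the constant, then the bound applies
  expect_equal(auto_threshold(rep(2, 10), w = 0.8, lower_bound = 0), 2)
  expect_equal(auto_threshold(rep(0.5, 10), w = 0.8, lower_bound = 1.8), 1.8)

  set.seed(21)
  x <- stats::runif(1e4)
  th <- auto_threshold(x, w = 0.85, lower_bound = 0)
  expect_equal(th, oracle_auto_threshold(x, 0.85), tolerance = 1e-14)
  expect_gte(th, min(x))
  expect_lte(th, max(x))
  # fixed-point relation after convergence
  expect_equal(th, 0.85 * mean(x[x <= th]) + 0.15 * mean(x[x > th]),
               tolerance = 1e-9)
})

test_that("tilt-rate recovers the signed rate about the main rotation axis", {
  n <- 50
  w0 <- 1.7
  gyr <- cbind(0, rep(w0, n), 0)
  expect_equal(tilt_rate(gyr, 1, n), rep(w0, n))
  # rotation invariance: dot products and norms only
  set.seed(5)
  gyr2 <- cbind(rnorm(n), rnorm(n), rnorm(n))
  rotm <- random_rotation_matrix()
  expect_equal(tilt_rate(gyr2 %*% t(rotm), 1, n), tilt_rate(gyr2, 1, n),
               tolerance = 1e-12)
  # sign change of a sine rate appears at its zero-crossing
  tt <- seq(0, 1, by = 1 / 110)
  gyr3 <- cbind(0, sin(2 * pi * tt), 0)  # crosses zero at t = 0.5
  g <- tilt_rate(gyr3, 1, length(tt))
  k_cross <- which(g <= 0 & seq_along(g) > 5)[1]
  expect_equal(tt[k_cross], 0.5, tolerance = 2 / 110)
})

test_that("toe-off is the first non-positive tilt-rate after the half-maximum", {
  ts <- 1 / 110
  tt <- seq(0, 1.2, by = ts)
  # positive half-sine rotation followed by reversal at t = 0.6
  rate <- 2 * sin(pi * tt / 0.6)
  rec <- imu_recording(cbind(0, rate, 0), cbind(0, 0, rep(9.81, length(tt))),
                       ts, "left")
  t_to <- detect_toe_off(rec, t_hr = 0, t_fc_next = 1.2)
  expect_lt(abs(t_to - 0.6), 2 * ts)
  # a phase without rotation reversal has no toe-off
  rec2 <- imu_recording(cbind(0, rep(1, length(tt)), 0),
                        cbind(0, 0, rep(9.81, length(tt))), ts, "left")
  expect_true(is.na(detect_toe_off(rec2, 0, 1.2)))
})

test_that("initial contact is found at a jerk transient inside the search window", {
  ts <- 1 / 110
  n <- 111
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n)
  k_step <- 60
  acc[k_step:n, 1] <- 4  # single step change -> jerk impulse at k_step
  rec <- imu_recording(matrix(0, n, 3), acc, ts, "left")
  t_ic <- detect_initial_contact(rec, t_to_prev = 0.1, t_fc = 0.9,
                                 j_win = 0.7, j_th = 0.95)
  expect_equal(t_ic, (k_step - 1) * ts, tolerance = 1e-12)
  # j_th = 1 selects the earliest argmax of the jerk norm
  t_ic1 <- detect_initial_contact(rec, 0.1, 0.9, j_win = 0.7, j_th = 1)
  expect_equal(t_ic1, (k_step - 1) * ts, tolerance = 1e-12)
  # empty window is invalid
  expect_true(is.na(detect_initial_contact(rec, 0.88, 0.9, j_win = 0, j_th = 0.95)))
})

test_that("standing-only recordings yield no strides", {
  n <- 500
  rec <- imu_recording(matrix(0, n, 3),
                       matrix(rep(c(0, 0, 9.81), each = n), n), 1 / 110, "left")
  expect_error(detect_foot_flat(rec), "no motion phases")
  expect_error(detect_gait_events(rec), "insufficient|motion")
})

test_that("combined rest signal dominates its two components before final pruning", {
  sim <- sim_noise_free_30s()
  rs <- imugait:::rest_signals(sim$left, gait_config())
  expect_true(all(rs$r_a <= 1 & rs$r_a >= 0))
  # OR property holds where no phase was pruned away: motion in either
  # channel implies motion in the combination built before pruning
  combined_raw <- as.integer(rs$r_a | rs$r_omega)
  expect_true(all(combined_raw >= rs$r_a))
  expect_true(all(combined_raw >= rs$r_omega))
})

test_that("detected events match simulator ground truth within a few samples", {
  sim <- sim_noise_free_30s()
  for (side in c("left", "right")) {
    rec <- sim[[side]]
    ev <- detect_gait_events(rec)
    s <- ev$strides[ev$strides$valid, ]
    te <- sim$truth[[side]]$events
    expect_gte(nrow(s), nrow(te) - 2L)
    expect_lte(abs(event_offset_samples(s$t_ic, te$t_ic, rec$ts)), 3)
    expect_lte(abs(event_offset_samples(s$t_fc, te$t_fc, rec$ts)), 3)
    expect_lte(abs(event_offset_samples(s$t_hr, te$t_hr, rec$ts)), 3)
    expect_lte(abs(event_offset_samples(s$t_to, te$t_to, rec$ts)), 3)
    # event ordering invariant
    expect_true(all(s$t_ic < s$t_fc & s$t_fc <= s$t_rest &
                      s$t_rest <= s$t_hr & s$t_hr < s$t_to &
                      s$t_to < s$t_ic_next))
  }
})

test_that("event detection is exactly invariant to a fixed sensor rotation", {
  sim <- sim_noise_free_30s()
  set.seed(99)
  rotm <- random_rotation_matrix()
  ev0 <- detect_gait_events(sim$left)
  ev1 <- detect_gait_events(rotate_recording(sim$left, rotm))
  expect_identical(ev1$strides$t_ic, ev0$strides$t_ic)
  expect_identical(ev1$strides$t_fc, ev0$strides$t_fc)
  expect_identical(ev1$strides$t_hr, ev0$strides$t_hr)
  expect_identical(ev1$strides$t_to, ev0$strides$t_to)
})

test_that("time-reversed input does not crash the event detector", {
  sim <- sim_noise_free_30s()
  rec <- sim$left
  rev_rec <- imu_recording(rec$gyr[rec$n:1, ], rec$acc[rec$n:1, ], rec$ts, "left")
  expect_no_error(try_events <- detect_gait_events(rev_rec))
})
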