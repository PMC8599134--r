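test_that("gyroscope bias is recovered from boundary rest segments", {
  n <- 2200  # 20 s at 110 Hz
  ts <- 1 / 110
  b <- c(0.01, -0.02, 0.005)
  gyr <- matrix(rep(b, each = n), n)
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n)
  rec <- imu_recording(gyr, acc, ts, "left")
  rest <- c(rep(0L, 550), rep(1L, 1100), rep(0L, 550))
  be <- estimate_gyro_bias(rec, rest)
  expect_equal(be$bias, b)
  # under noise the mean over ~2x5 s beats 1e-3 accuracy comfortably
  set.seed(42)
  rec2 <- imu_recording(gyr + matrix(rnorm(3 * n, sd = 0.01), n), acc, ts, "left")
  be2 <- estimate_gyro_bias(rec2, rest)
  expect_lt(sqrt(sum((be2$bias - b)^2)), 1e-3)
  # no rest -> zero bias with a warning
  be3 <- estimate_gyro_bias(rec, rep(1L, n))
  expect_equal(be3$bias, c(0, 0, 0))
  expect_match(be3$warnings, "no rest")
  # implausibly large estimates are rejected
  rec4 <- imu_recording(matrix(rep(c(0.6, 0, 0), each = n), n), acc, ts, "left")
  be4 <- estimate_gyro_bias(rec4, rest)
  expect_equal(be4$bias, c(0, 0, 0))
  expect_match(be4$warnings, "implausible")
})

test_that("strapdown integration matches closed forms and a fine-step reference", {
  ts <- 1 / 110
  # zero rate: constant orientation
  q <- strapdown_integrate(matrix(0, 10, 3), ts)
  expect_equal(q, matrix(rep(c(1, 0, 0, 0), each = 10), 10), tolerance = 1e-15)
  # pi about z over exactly 1 s: constant-axis increments compose exactly
  q2 <- strapdown_integrate(matrix(rep(c(0, 0, pi), each = 110), 110), ts)
  expect_lt(min(sqrt(sum((q2[110, ] - c(0, 0, 0, 1))^2)),
                sqrt(sum((q2[110, ] + c(0, 0, 0, 1))^2))), 1e-12)
  # smooth time-varying axis: compare against 100x finer integration
  omega_fun <- function(t)
    cbind(1.5 * sin(2 * pi * 0.7 * t), 2.0 * cos(2 * pi * 0.5 * t),
          0.8 * sin(2 * pi * 1.1 * t + 1))
  t_c <- seq(ts, 10, by = ts)
  ts_f <- ts / 100
  t_f <- seq(ts_f, 10, by = ts_f)
  q_c <- strapdown_integrate(omega_fun(t_c - ts / 2), ts)
  q_f <- strapdown_integrate(omega_fun(t_f - ts_f / 2), ts_f)
  ang <- imugait:::quat_angle_between(q_c[length(t_c), ],
                                      q_f[length(t_f), ])
  expect_lt(ang, 1e-3)
  # unit norm throughout
  expect_lt(max(abs(sqrt(rowSums(q_c^2)) - 1)), 1e-9)
})

test_that("the gravity reference filter preserves constants and is zero-phase", {
  n <- 1500
  ts <- 1 / 110
  q_id <- matrix(rep(c(1, 0, 0, 0), each = n), n)
  acc_const <- matrix(rep(c(1, -2, 9.5), each = n), n)
  a_f <- filtered_gravity_reference(acc_const, q_id, t_a = 8, ts = ts)
  expect_equal(a_f, acc_const, tolerance = 1e-12)
  # fast zero-mean oscillation on top of gravity is suppressed to < 2 %
  tt <- (seq_len(n) - 1) * ts
  acc_osc <- acc_const + 3 * cbind(sin(2 * pi * 2 * tt), cos(2 * pi * 2 * tt), 0)
  a_f2 <- filtered_gravity_reference(acc_osc, q_id, t_a = 8, ts = ts)
  mid <- 300:1200
  expect_lt(max(abs(a_f2[mid, ] - acc_const[mid, ])),
            0.02 * sqrt(sum(acc_const[1, ]^2)))
  # forward+reverse filtering has zero phase lag: a centred impulse maps to
  # a symmetric response
  ma <- function(v, win) imugait:::moving_average_causal(v, win)
  two_pass <- function(v, win) rev(ma(rev(ma(v, win)), win))
  imp <- c(rep(0, 200), 1, rep(0, 200))
  y <- two_pass(imp, 51)
  expect_equal(y, rev(y), tolerance = 1e-12)
})

test_that("inclination correction aligns the reference with the vertical", {
  n <- 300
  # a 30 degree tilted static case: strapdown stays at identity, gravity
  # reference seen 30 degrees off vertical
  tilt <- 30 * pi / 180
  a_f <- matrix(rep(9.81 * c(sin(tilt), 0, cos(tilt)), each = n), n)
  q_id <- matrix(rep(c(1, 0, 0, 0), each = n), n)
  q_a <- inclination_correction(q_id, a_f)
  q <- imugait:::quat_multiply_rows(q_a, q_id)
  up <- imugait:::quat_rotate_rows(q, a_f)
  ang <- acos(pmin(1, up[, 3] / sqrt(rowSums(up^2))))
  expect_lt(max(ang), 1e-6)  # full correction from the first sample on
  # already-vertical reference leaves the correction at identity
  a_v <- matrix(rep(c(0, 0, 9.81), each = n), n)
  q_a2 <- inclination_correction(q_id, a_v)
  expect_equal(q_a2, matrix(rep(c(1, 0, 0, 0), each = n), n), tolerance = 1e-12)
  # antiparallel reference (degenerate axis) is skipped, not corrected
  a_d <- matrix(rep(c(0, 0, -9.81), each = n), n)
  expect_no_error(q_a3 <- inclination_correction(q_id, a_d))
  expect_equal(q_a3[n, ], c(1, 0, 0, 0))
})

test_that("orientation estimation recovers inclination on static and walking data", {
  # static recording under an arbitrary constant orientation
  n <- 3300
  ts <- 1 / 110
  set.seed(8)
  q0 <- imugait:::quat_normalize(rnorm(4))
  acc_sensor <- matrix(rep(imugait:::quat_rotate(imugait:::quat_conjugate(q0),
                                                 c(0, 0, 9.81)), each = n), n)
  rec <- imu_recording(matrix(0, n, 3), acc_sensor, ts, "left")
  est <- estimate_orientation(rec, rest = rep(0L, n))
  up <- imugait:::quat_rotate_rows(est$q, rec$acc)
  ang <- acos(pmin(1, up[, 3] / sqrt(rowSums(up^2))))
  expect_lt(max(ang[-(1:5)]) * 180 / pi, 0.5)
  expect_lt(max(abs(sqrt(rowSums(est$q^2)) - 1)), 1e-9)

  # walking trial: inclination error vs ground truth below 2 degrees RMS
  sim <- sim_noise_free_30s()
  ev <- detect_gait_events(sim$left)
  est2 <- estimate_orientation(sim$left, ev$rest)
  qt <- sim$truth$left$q_true
  ez <- matrix(rep(c(0, 0, 1), each = sim$left$n), sim$left$n)
  down_t <- imugait:::quat_rotate_rows(imugait:::quat_conjugate(qt), ez)
  down_e <- imugait:::quat_rotate_rows(imugait:::quat_conjugate(est2$q), ez)
  ang2 <- acos(pmin(1, rowSums(down_t * down_e)))
  expect_lt(sqrt(mean(ang2^2)) * 180 / pi, 2)
})

test_that("a constant heading offset leaves all scalar gait parameters unchanged", {
  sim <- sim_noise_free_30s()
  rec <- sim$left
  ev <- detect_gait_events(rec)
  est <- estimate_orientation(rec, ev$rest)
  spa0 <- imugait:::stride_spatial_params(rec, ev, est$q)
  # rotate the estimated frame about z by an arbitrary heading
  qz <- imugait:::quat_from_axis_angle(c(0, 0, 1), 1.234)
  q_rot <- imugait:::quat_multiply_rows(
    matrix(qz, nrow(est$q), 4, byrow = TRUE), est$q)
  spa1 <- imugait:::stride_spatial_params(rec, ev, q_rot)
  ok <- stats::complete.cases(spa0$length_m)
  expect_equal(spa1$length_m[ok], spa0$length_m[ok], tolerance = 1e-9)
})
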