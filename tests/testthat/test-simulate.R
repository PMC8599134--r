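test_that("profile arithmetic links speed, cadence and stride length", {
  pr <- gait_profile(speed_kmh = 3, cadence_spm = 110)
  expect_equal(pr$t_stride, 120 / 110)
  expect_equal(pr$stride_length, 3 / 3.6 * 120 / 110)  # ~0.909 m
  expect_error(gait_profile(stance_ratio_left = 1.2))
})

test_that("zero speed produces a constant pose and no strides", {
  pose <- foot_pose_trajectory(gait_profile(speed_kmh = 0, duration = 15),
                               "left", 1 / 110)
  expect_equal(nrow(pose$events), 0L)
  expect_equal(max(abs(pose$acc)), 0)
  expect_true(all(pose$q[, 1] == 1))
})

test_that("stride count follows duration and cadence", {
  pr <- gait_profile(duration = 120)
  pose <- foot_pose_trajectory(pr, "left", 1 / 110)
  expected <- floor((120 - pr$lead_in - pr$lead_out) / pr$t_stride)
  expect_equal(nrow(pose$events), expected)
  expect_gt(expected, 95)  # ~100 strides of 1.09 s in 110 s of walking
})

test_that("pose, velocity and acceleration are mutually consistent", {
  ts <- 1 / 2000
  pose <- foot_pose_trajectory(gait_profile(duration = 12), "left", ts)
  n <- nrow(pose$p)
  # central difference of position vs analytic velocity
  v_num <- (pose$p[-c(1, 2), ] - pose$p[-c(n - 1, n), ]) / (2 * ts)
  err_v <- rowSums(abs(v_num - pose$v[2:(n - 1), ]))
  expect_lt(stats::quantile(err_v, 0.99), 1e-4)
  expect_lt(max(err_v), 0.05)  # isolated samples straddling the impact step
  # central second difference vs analytic acceleration: exact where the
  # trajectory is smooth; isolated samples at segment joins and at the
  # deliberate impact transient carry the jerk discontinuity
  a_num <- (pose$p[-c(1, 2), ] - 2 * pose$p[-c(1, n), ] +
              pose$p[-c(n - 1, n), ]) / ts^2
  err_a <- rowSums(abs(a_num - pose$acc[2:(n - 1), ]))
  expect_lt(stats::quantile(err_a, 0.99), 1e-3)
  expect_lt(max(err_a), 30)  # bounded even across the impact step
})

test_that("noise-free gyroscope channel inverts exactly under strapdown", {
  sim <- sim_noise_free_30s()
  rec <- sim$left
  q <- strapdown_integrate(rec$gyr, rec$ts)
  qt <- sim$truth$left$q_true
  ang <- vapply(seq(1, rec$n, by = 25), function(k)
    imugait:::quat_angle_between(q[k, ], qt[k, ]), numeric(1))
  expect_lt(max(ang), 1e-3)
})

test_that("noise-free accelerometer channel integrates back to the true velocity", {
  pr <- gait_profile(duration = 20)
  pose <- foot_pose_trajectory(pr, "left", 1 / 110)
  sim <- synthesize_imu(pose, nf_sensor(), "left")
  acc_w <- imugait:::quat_rotate_rows(sim$q_true, sim$rec$acc)
  acc_w[, 3] <- acc_w[, 3] - 9.81
  v_rec <- apply(acc_w, 2, cumsum) * sim$rec$ts
  expect_lt(max(abs(v_rec - pose$v)), 1e-9)
})

test_that("static pose with identity mounting measures pure gravity", {
  pose <- foot_pose_trajectory(gait_profile(speed_kmh = 0, duration = 5),
                               "left", 1 / 110)
  sim <- synthesize_imu(pose, nf_sensor(), "left")
  expect_equal(sim$rec$acc,
               matrix(rep(c(0, 0, 9.81), each = sim$rec$n), sim$rec$n),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max(abs(sim$rec$gyr)), 0)
})

test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  pr <- gait_profile(duration = 10)
  s1 <- simulate_gait(pr, sensor_model(), sensor_model(), seed = 5)
  s2 <- simulate_gait(pr, sensor_model(), sensor_model(), seed = 5)
  s3 <- simulate_gait(pr, sensor_model(), sensor_model(), seed = 6)
  expect_identical(s1$left$gyr, s2$left$gyr)
  expect_identical(s1$right$acc, s2$right$acc)
  expect_false(identical(s1$left$gyr, s3$left$gyr))
})

test_that("ground-truth events are ordered and the tilt-rate reverses once", {
  sim <- sim_noise_free_30s()
  te <- sim$truth$left$events
  expect_true(all(te$t_hr < te$t_to & te$t_to < te$t_ic & te$t_ic < te$t_fc))
  expect_true(all(diff(te$t_hr) > 0))
  rec <- sim$left
  # between each heel rise and the next full contact the tilt-rate changes
  # sign exactly once (ignoring the near-zero tail after landing)
  for (j in 1:5) {
    k_hr <- imugait:::time_to_index(rec, te$t_hr[j])
    k_fc <- imugait:::time_to_index(rec, te$t_fc[j])
    g <- tilt_rate(rec$gyr, k_hr, k_fc)
    g <- g[abs(g) > 1e-6]
    expect_equal(sum(diff(sign(g)) != 0), 1L)
  }
})

test_that("asymmetric profiles carry their stance ratios into the ground truth", {
  pr <- gait_profile(duration = 20, stance_ratio_left = 0.65,
                     stance_ratio_right = 0.58)
  sim <- simulate_gait(pr, nf_sensor(), nf_sensor(), seed = 2)
  for (side in c("left", "right")) {
    te <- sim$truth[[side]]$events
    s_true <- sim$truth[[side]]$stance_ratio
    # stance of stride i: initial contact i to toe-off of the next cycle
    stance <- (te$t_to[-1] - te$t_ic[-nrow(te)]) / pr$t_stride
    expect_equal(stance, rep(s_true, nrow(te) - 1), tolerance = 1e-9)
  }
})
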