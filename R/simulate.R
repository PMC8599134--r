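# Two-foot gait simulator with exact ground truth.
#
# Each gait cycle of one foot is generated from four piecewise-smooth
# segments, starting at heel rise:
#   1. heel rise: the foot pitches forward about a toe pivot while the toe
#      stays on the ground; the pitch angle ramps 0 -> heel_rise_angle with a
#      quintic smoothstep (zero rate and angular acceleration at both ends),
#      so the tilt-rate has exactly one sign change, located at toe-off.
#   2. swing: forward displacement follows a quintic with zero velocity and
#      acceleration at the start and a prescribed landing velocity; the
#      vertical component follows a smooth arc; the pitch returns to zero.
#   3. landing: a half-cosine acceleration impact pulse (default 30 ms) at
#      initial contact followed by a smooth braking profile; this produces
#      the jerk-norm peak that the initial-contact detector relies on.
#   4. foot flat: the pose is constant until the next heel rise.
# Velocity is continuous across all transitions and the pose is twice
# continuously differentiable within segments, so the synthesized signals
# are kinematically consistent with the pose to machine precision.

# quintic smoothstep and derivatives (zero 1st and 2nd derivative at 0 and 1)
s5 <- function(u) u^3 * (10 - 15 * u + 6 * u^2)
s5d <- function(u) 30 * u^2 * (1 - u)^2
s5dd <- function(u) 60 * u * (1 - 3 * u + 2 * u^2)

# quintic Hermite basis for the end-velocity boundary condition
h4 <- function(u) u^3 * (-4 + 7 * u - 3 * u^2)
h4d <- function(u) u^2 * (-12 + 28 * u - 15 * u^2)
h4dd <- function(u) u * (-24 + 84 * u - 60 * u^2)

#' Gait profile for the simulator
#'
#' Defines the walking conditions the simulator reproduces. The stride time
#' follows from the cadence (`120 / cadence_spm` seconds) and the stride
#' length from `speed * stride_time`; per-foot stance ratios allow asymmetric
#' gait, and the contralateral foot is shifted by `phase_shift` of a stride.
#' Standing lead-in/lead-out segments emulate the quiet-standing margins of
#' an instrumented-treadmill protocol and provide the rest segments used for
#' gyroscope bias estimation.
#'
#' @param speed_kmh walking speed, km/h.
#' @param cadence_spm cadence, steps per minute (two steps per stride).
#' @param stance_ratio_left,stance_ratio_right stance fraction of the stride
#'   per foot, in (0, 1).
#' @param phase_shift contralateral shift as a fraction of the stride.
#' @param swing_apex additional swing arc apex height, m.
#' @param heel_rise_angle pitch rotation before toe-off, rad.
#' @param impact_jerk peak jerk of the initial-contact impact pulse, m/s^3.
#' @param duration total recording duration, s.
#' @param lead_in,lead_out standing rest before/after walking, s.
#' @param land_speed_factor landing velocity as a fraction of the mean swing
#'   velocity.
#' @return A list of class `gait_profile` including the derived `t_stride`
#'   (s) and `stride_length` (m).
#' @export
gait_profile <- function(speed_kmh = 3,
                         cadence_spm = 110,
                         stance_ratio_left = 0.6,
                         stance_ratio_right = 0.6,
                         phase_shift = 0.5,
                         swing_apex = 0.05,
                         heel_rise_angle = 0.4,
                         impact_jerk = 1200,
                         duration = 120,
                         lead_in = 5,
                         lead_out = 5,
                         land_speed_factor = 0.5) {
  stopifnot(speed_kmh >= 0, cadence_spm > 0,
            stance_ratio_left > 0, stance_ratio_left < 1,
            stance_ratio_right > 0, stance_ratio_right < 1,
            phase_shift >= 0, phase_shift < 1,
            swing_apex >= 0, heel_rise_angle > 0, impact_jerk > 0,
            duration > 0, lead_in >= 0, lead_out >= 0,
            land_speed_factor > 0, land_speed_factor < 1)
  t_stride <- 120 / cadence_spm
  structure(list(
    speed_kmh = speed_kmh, cadence_spm = cadence_spm,
    stance_ratio_left = stance_ratio_left,
    stance_ratio_right = stance_ratio_right,
    phase_shift = phase_shift, swing_apex = swing_apex,
    heel_rise_angle = heel_rise_angle, impact_jerk = impact_jerk,
    duration = duration, lead_in = lead_in, lead_out = lead_out,
    land_speed_factor = land_speed_factor,
    t_stride = t_stride,
    stride_length = speed_kmh / 3.6 * t_stride), class = "gait_profile")
}

#' Sensor error model for the simulator
#'
#' @param gyro_noise_sd white-noise standard deviation per gyroscope axis,
#'   rad/s (typical consumer MEMS: 0.01).
#' @param accel_noise_sd white-noise standard deviation per accelerometer
#'   axis, m/s^2 (typical consumer MEMS: 0.1).
#' @param gyro_bias turn-on bias 3-vector, rad/s; `NULL` draws each
#'   component from U(-0.01, 0.01).
#' @param mounting unit quaternion rotating sensor-frame vectors into the
#'   foot frame (arbitrary sensor attachment); `NULL` draws a uniformly
#'   random rotation.
#' @param fs sampling rate, Hz.
#' @param seed optional RNG seed making this sensor's random draws
#'   reproducible.
#' @return A list of class `sensor_model`.
#' @export
sensor_model <- function(gyro_noise_sd = 0.01, accel_noise_sd = 0.1,
                         gyro_bias = NULL, mounting = NULL, fs = 110,
                         seed = NULL) {
  stopifnot(gyro_noise_sd >= 0, accel_noise_sd >= 0, fs > 0)
  if (!is.null(mounting)) {
    stopifnot(length(mounting) == 4L,
              abs(sqrt(sum(mounting^2)) - 1) < 1e-9)
  }
  structure(list(gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 gyro_bias = gyro_bias, mounting = mounting,
                 fs = fs, seed = seed), class = "sensor_model")
}

# identity error model, convenient for noise-free validation runs
ideal_sensor <- function(fs = 110) {
  sensor_model(gyro_noise_sd = 0, accel_noise_sd = 0,
               gyro_bias = c(0, 0, 0), mounting = c(1, 0, 0, 0), fs = fs)
}

# toe-pivot geometry: sensor sits on the instep, d_px ahead of the heel end
# of the pivot lever and d_pz above the ground
pivot_dx <- 0.12
pivot_dz <- 0.05
# heel-settle height: the foot lands on the heel slightly above its flat
# pose and settles down during the loading phase; the vertical deceleration
# of this settling is what makes the end of loading visible in the
# accelerometer norm (horizontal braking only enters the norm quadratically)
settle_dz <- 0.015

#' Ground-truth pose trajectory of one foot
#'
#' Evaluates the piecewise closed-form pose of one foot on the sample grid:
#' position, analytic acceleration, orientation quaternion (foot frame to
#' world, world z up, x the walking direction) and the exact event times.
#'
#' @param profile a [gait_profile()].
#' @param foot_side `"left"` or `"right"`; the right foot is shifted by
#'   `phase_shift` of a stride.
#' @param ts sampling interval, seconds.
#' @return A list with `t`, `p` (N x 3 positions, m), `acc` (N x 3 analytic
#'   accelerations, m/s^2), `q` (N x 4 foot orientation quaternions),
#'   `events` (data frame `cycle`, `t_hr`, `t_to`, `t_ic`, `t_fc`),
#'   `stride_length`, `t_stride`, `stance_ratio`.
#' @export
foot_pose_trajectory <- function(profile, foot_side = c("left", "right"), ts) {
  foot_side <- match.arg(foot_side)
  pr <- profile
  t_str <- pr$t_stride
  s <- if (foot_side == "left") pr$stance_ratio_left else pr$stance_ratio_right
  n <- as.integer(round(pr$duration / ts)) + 1L
  t <- (seq_len(n) - 1L) * ts
  y0 <- if (foot_side == "left") 0.1 else -0.1

  t_first_hr <- pr$lead_in + (if (foot_side == "right") pr$phase_shift * t_str else 0)
  l_stride <- pr$stride_length
  n_cyc <- floor((pr$duration - t_first_hr - pr$lead_out) / t_str)
  if (pr$speed_kmh <= 0 || n_cyc < 1) {
    q <- matrix(rep(quat_identity(), each = n), n, 4L)
    return(list(t = t, p = cbind(0, y0, 0)[rep(1L, n), , drop = FALSE],
                v = matrix(0, n, 3L), acc = matrix(0, n, 3L), q = q,
                events = data.frame(cycle = integer(0), t_hr = numeric(0),
                                    t_to = numeric(0), t_ic = numeric(0),
                                    t_fc = numeric(0)),
                stride_length = l_stride, t_stride = t_str, stance_ratio = s))
  }

  # segment durations within one cycle (cycle starts at heel rise)
  d_rise <- s * t_str / 3
  d_swing <- (1 - s) * t_str
  d_land <- 0.2 * s * t_str
  d_flat <- t_str - d_rise - d_swing - d_land
  t_imp <- 0.02
  if (d_land <= t_imp || d_flat <= 0 || d_swing <= 0)
    stop("infeasible gait profile: degenerate cycle segment durations")

  theta <- pr$heel_rise_angle
  dx_rise <- pivot_dx * (1 - cos(theta)) + pivot_dz * sin(theta)
  dz_rise <- pivot_dx * sin(theta) + pivot_dz * (cos(theta) - 1)
  v_end <- pr$land_speed_factor * l_stride / d_swing
  # landing deceleration: an attack-decay impact (maximum deceleration at
  # ground contact, released over t_imp) superimposed on a quarter-cosine
  # braking profile that absorbs the remaining landing momentum over the
  # whole loading phase; the acceleration step at initial contact is the
  # jerk transient the detector relies on
  a_imp <- pr$impact_jerk * 2 * t_imp / pi
  a_imp <- min(a_imp, 0.6 * v_end * pi / (2 * t_imp))
  dv_imp <- 2 * a_imp * t_imp / pi
  a_brake <- pi * (v_end - dv_imp) / (2 * d_land)
  disp_land <- v_end * d_land -
    a_imp * (2 * t_imp / pi) * (2 * t_imp / pi + d_land - t_imp) -
    a_brake * (2 * d_land / pi)^2
  disp_swing <- l_stride - dx_rise - disp_land
  if (disp_swing <= 0)
    stop("infeasible gait profile: heel-rise and landing displacement exceed the stride length")

  # per-sample cycle index and time within the cycle
  u_rel <- t - t_first_hr
  cyc <- pmin(pmax(floor(u_rel / t_str), 0), n_cyc - 1)
  tau <- u_rel - cyc * t_str
  walking <- u_rel >= 0 & u_rel < n_cyc * t_str
  tau[!walking] <- -1
  x_base <- cyc * l_stride

  px <- numeric(n); pz <- numeric(n); ax <- numeric(n); az <- numeric(n)
  vx <- numeric(n); vz <- numeric(n)
  th <- numeric(n)
  # before walking: flat at origin; after: flat at final position
  px[!walking & u_rel < 0] <- 0
  px[!walking & u_rel >= 0] <- n_cyc * l_stride

  in_rise <- walking & tau < d_rise
  in_swing <- walking & tau >= d_rise & tau < d_rise + d_swing
  in_land <- walking & tau >= d_rise + d_swing & tau < d_rise + d_swing + d_land
  in_flat <- walking & tau >= d_rise + d_swing + d_land

  if (any(in_rise)) {
    u <- tau[in_rise] / d_rise
    thr <- theta * s5(u)
    thd <- theta * s5d(u) / d_rise
    thdd <- theta * s5dd(u) / d_rise^2
    th[in_rise] <- thr
    px[in_rise] <- x_base[in_rise] +
      pivot_dx * (1 - cos(thr)) + pivot_dz * sin(thr)
    pz[in_rise] <- pivot_dx * sin(thr) + pivot_dz * (cos(thr) - 1)
    lever_s <- pivot_dx * sin(thr) + pivot_dz * cos(thr)
    lever_c <- pivot_dx * cos(thr) - pivot_dz * sin(thr)
    vx[in_rise] <- thd * lever_s
    vz[in_rise] <- thd * lever_c
    ax[in_rise] <- thdd * lever_s + thd^2 * lever_c
    az[in_rise] <- thdd * lever_c - thd^2 * lever_s
  }
  if (any(in_swing)) {
    u <- (tau[in_swing] - d_rise) / d_swing
    th[in_swing] <- theta * (1 - s5(u))
    px[in_swing] <- x_base[in_swing] + dx_rise +
      disp_swing * s5(u) + v_end * d_swing * h4(u)
    vx[in_swing] <- (disp_swing * s5d(u) + v_end * d_swing * h4d(u)) / d_swing
    ax[in_swing] <- (disp_swing * s5dd(u) + v_end * d_swing * h4dd(u)) / d_swing^2
    # sin^3 arc: value, slope and curvature all vanish at the swing
    # boundaries, so the landing impact pulse is the only acceleration
    # transient in the cycle
    pz[in_swing] <- dz_rise * (1 - s5(u)) + pr$swing_apex * sin(pi * u)^3 +
      settle_dz * s5(u)
    vz[in_swing] <- ((settle_dz - dz_rise) * s5d(u) +
                       pr$swing_apex * 3 * pi * sin(pi * u)^2 * cos(pi * u)) / d_swing
    az[in_swing] <- ((settle_dz - dz_rise) * s5dd(u) + pr$swing_apex * 3 * pi^2 *
                       sin(pi * u) * (2 * cos(pi * u)^2 - sin(pi * u)^2)) / d_swing^2
  }
  if (any(in_land)) {
    w <- tau[in_land] - d_rise - d_swing
    # impact component, fully released after t_imp
    imp_a <- ifelse(w < t_imp, -a_imp * cos(pi * w / (2 * t_imp)), 0)
    imp_v <- ifelse(w < t_imp,
                    a_imp * (2 * t_imp / pi) * sin(pi * w / (2 * t_imp)),
                    dv_imp)
    imp_p <- ifelse(w < t_imp,
                    a_imp * (2 * t_imp / pi)^2 * (1 - cos(pi * w / (2 * t_imp))),
                    a_imp * (2 * t_imp / pi) * (2 * t_imp / pi + w - t_imp))
    px[in_land] <- x_base[in_land] + dx_rise + disp_swing + v_end * w -
      imp_p - a_brake * (2 * d_land / pi)^2 * (1 - cos(pi * w / (2 * d_land)))
    vx[in_land] <- v_end - imp_v -
      a_brake * (2 * d_land / pi) * sin(pi * w / (2 * d_land))
    ax[in_land] <- imp_a - a_brake * cos(pi * w / (2 * d_land))
    ul <- w / d_land
    pz[in_land] <- settle_dz * (1 - s5(ul))
    vz[in_land] <- -settle_dz * s5d(ul) / d_land
    az[in_land] <- -settle_dz * s5dd(ul) / d_land^2
  }
  if (any(in_flat)) {
    px[in_flat] <- x_base[in_flat] + l_stride
  }

  q <- cbind(cos(th / 2), 0, sin(th / 2), 0)
  cycles <- seq_len(n_cyc)
  t_hr <- t_first_hr + (cycles - 1) * t_str
  events <- data.frame(cycle = cycles,
                       t_hr = t_hr,
                       t_to = t_hr + d_rise,
                       t_ic = t_hr + d_rise + d_swing,
                       t_fc = t_hr + d_rise + d_swing + d_land)
  list(t = t, p = cbind(px, rep(y0, n), pz), v = cbind(vx, 0, vz),
       acc = cbind(ax, 0, az), q = q,
       events = events, stride_length = l_stride, t_stride = t_str,
       stance_ratio = s)
}

#' Synthesize IMU measurements from a pose trajectory
#'
#' Computes ideal sensor signals from the ground-truth pose — angular rates
#' from the quaternion increments (so that strapdown integration of the
#' noise-free gyroscope reproduces the true orientation exactly) and
#' accelerometer readings as the orientation-rotated specific force
#' `q^-1 ⊗ (p'' + g e_z) ⊗ q` — then applies the sensor error model: an
#' arbitrary constant mounting rotation on both channels, a turn-on bias on
#' the gyroscope, and white Gaussian noise per channel.
#'
#' @param pose output of [foot_pose_trajectory()].
#' @param sensor a [sensor_model()].
#' @param foot_side passed to [imu_recording()].
#' @return A list with `rec` (the [imu_recording()]), `q_true` (N x 4 true
#'   sensor orientation including mounting), `mounting`, `bias`.
#' @export
synthesize_imu <- function(pose, sensor = sensor_model(),
                           foot_side = c("left", "right")) {
  foot_side <- match.arg(foot_side)
  if (!is.null(sensor$seed)) set.seed(sensor$seed)
  n <- length(pose$t)
  ts <- pose$t[2L] - pose$t[1L]
  mounting <- sensor$mounting
  if (is.null(mounting)) {
    mounting <- quat_normalize(stats::rnorm(4))
  }
  bias <- sensor$gyro_bias
  if (is.null(bias)) bias <- stats::runif(3, -0.01, 0.01)

  # true sensor orientation: foot orientation composed with the mounting
  q_sens <- quat_multiply_rows(pose$q, mounting)
  # gyroscope from quaternion increments: dq = q_{k-1}^-1 ⊗ q_k
  dq <- quat_multiply_rows(quat_conjugate(q_sens[-n, , drop = FALSE]),
                           q_sens[-1L, , drop = FALSE])
  # enforce w >= 0 so the extracted angle is the short rotation
  flip <- dq[, 1L] < 0
  dq[flip, ] <- -dq[flip, ]
  vec_norm <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vec_norm, dq[, 1L])
  scale <- ifelse(vec_norm > 0, ang / (vec_norm * ts), 0)
  gyr <- rbind(c(0, 0, 0), dq[, 2:4, drop = FALSE] * scale)

  # accelerometer from velocity increments (interval-averaged specific
  # force), the translational analog of the gyroscope increment convention:
  # right-Riemann integration of the noise-free channel recovers the true
  # velocity exactly
  acc_w <- rbind(c(0, 0, 0), diff(pose$v) / ts)
  g <- matrix(c(0, 0, 9.81), n, 3L, byrow = TRUE)
  acc <- quat_rotate_rows(quat_conjugate(q_sens), acc_w + g)

  gyr <- gyr + matrix(bias, n, 3L, byrow = TRUE)
  if (sensor$gyro_noise_sd > 0)
    gyr <- gyr + matrix(stats::rnorm(3L * n, sd = sensor$gyro_noise_sd), n, 3L)
  if (sensor$accel_noise_sd > 0)
    acc <- acc + matrix(stats::rnorm(3L * n, sd = sensor$accel_noise_sd), n, 3L)

  list(rec = imu_recording(gyr, acc, ts, foot_side),
       q_true = q_sens, mounting = mounting, bias = bias)
}

#' Simulate a complete two-foot walking trial
#'
#' Generates both feet's recordings on a common time base together with the
#' exact ground truth (event times, per-stride length and duration, stance
#' ratios, true orientations and positions).
#'
#' @param profile a [gait_profile()].
#' @param sensor_left,sensor_right [sensor_model()]s for the two feet.
#' @param seed optional overall RNG seed; per-sensor seeds take precedence
#'   within each foot.
#' @return A list of class `gait_simulation`: `left`, `right`
#'   ([imu_recording()]s) and `truth` (per-foot events and trajectories,
#'   profile echo, mounting rotations and biases).
#' @export
simulate_gait <- function(profile = gait_profile(),
                          sensor_left = sensor_model(),
                          sensor_right = sensor_model(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts_l <- 1 / sensor_left$fs
  ts_r <- 1 / sensor_right$fs
  pose_l <- foot_pose_trajectory(profile, "left", ts_l)
  pose_r <- foot_pose_trajectory(profile, "right", ts_r)
  sim_l <- synthesize_imu(pose_l, sensor_left, "left")
  sim_r <- synthesize_imu(pose_r, sensor_right, "right")
  truth <- list(
    profile = unclass(profile),
    left = list(events = pose_l$events, stride_length = pose_l$stride_length,
                t_stride = pose_l$t_stride, stance_ratio = pose_l$stance_ratio,
                q_true = sim_l$q_true, p_true = pose_l$p,
                mounting = sim_l$mounting, bias = sim_l$bias),
    right = list(events = pose_r$events, stride_length = pose_r$stride_length,
                 t_stride = pose_r$t_stride, stance_ratio = pose_r$stance_ratio,
                 q_true = sim_r$q_true, p_true = pose_r$p,
                 mounting = sim_r$mounting, bias = sim_r$bias))
  structure(list(left = sim_l$rec, right = sim_r$rec, truth = truth),
            class = "gait_simulation")
}

#' @export
print.gait_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated gait trial: %.0f s at %.1f km/h, cadence %.0f steps/min, %d + %d strides\n",
    x$truth$profile$duration, x$truth$profile$speed_kmh,
    x$truth$profile$cadence_spm,
    nrow(x$truth$left$events), nrow(x$truth$right$events)))
  invisible(x)
}

# Serialize the ground truth (without the bulky trajectories) to JSON.
write_ground_truth <- function(truth, path) {
  slim <- function(ft) ft[c("events", "stride_length", "t_stride",
                            "stance_ratio", "mounting", "bias")]
  jsonlite::write_json(
    list(profile = truth$profile, left = slim(truth$left),
         right = slim(truth$right)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
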