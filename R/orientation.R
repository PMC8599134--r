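#' Estimate the gyroscope turn-on bias
#'
#' Consumer gyroscopes exhibit a roughly constant offset from power-on. It is
#' estimated as the mean angular-rate vector over the standing-rest segments
#' at the beginning and at the end of the recording (each truncated to at
#' most 5 s), identified from the combined rest signal of the foot-flat
#' detector. If only one boundary rest segment exists it is used alone; if
#' none exists the bias is zero and a warning is recorded. Estimates with a
#' norm of 0.5 rad/s or more are physically implausible for a turn-on bias
#' and are rejected (zero bias, warning).
#'
#' @param rec an [imu_recording()].
#' @param rest integer 0/1 vector (1 = motion), e.g. the combined rest signal
#'   from [detect_foot_flat()] or [detect_gait_events()].
#' @param max_segment longest rest stretch used at each end, seconds.
#' @return A list with `bias` (3-vector, rad/s), `segments` (matrix of
#'   start/end times used) and `warnings`.
#' @export
estimate_gyro_bias <- function(rec, rest, max_segment = 5) {
  stopifnot(length(rest) == rec$n)
  warnings <- character(0)
  rl <- rle(as.integer(rest))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  zero_runs <- which(rl$values == 0L)
  n_max <- max(1L, as.integer(round(max_segment / rec$ts)))
  idx <- integer(0)
  segs <- NULL
  if (length(zero_runs) > 0L) {
    first <- zero_runs[1L]
    a <- starts[first]
    b <- min(ends[first], a + n_max - 1L)
    idx <- a:b
    segs <- rbind(segs, c(index_to_time(rec, a), index_to_time(rec, b)))
    last <- zero_runs[length(zero_runs)]
    if (last != first) {
      b2 <- ends[last]
      a2 <- max(starts[last], b2 - n_max + 1L)
      idx <- c(idx, a2:b2)
      segs <- rbind(segs, c(index_to_time(rec, a2), index_to_time(rec, b2)))
    }
  }
  if (length(idx) == 0L) {
    warnings <- "no rest segments found; gyroscope bias assumed zero"
    return(list(bias = c(0, 0, 0), segments = NULL, warnings = warnings))
  }
  b <- unname(colMeans(rec$gyr[idx, , drop = FALSE]))
  if (sqrt(sum(b^2)) >= 0.5) {
    warnings <- sprintf(
      "implausible gyroscope bias estimate (|b| = %.3g rad/s >= 0.5); assumed zero",
      sqrt(sum(b^2)))
    b <- c(0, 0, 0)
  }
  list(bias = b, segments = segs, warnings = warnings)
}

#' Gyroscope strapdown integration
#'
#' Integrates body-frame angular rates into an orientation quaternion
#' sequence by right-multiplying, per sample, the rotation increment
#' \deqn{q_\omega(t_k) = q_\omega(t_{k-1}) \otimes
#'   \left[\cos(\tfrac{T_s}{2}\lVert\omega\rVert),\;
#'   \tfrac{\omega^\top}{\lVert\omega\rVert}
#'   \sin(\tfrac{T_s}{2}\lVert\omega\rVert)\right]^\top.}
#' A zero rate yields the identity increment. Each step is renormalized so
#' that numerical round-off cannot accumulate over long recordings.
#'
#' @param gyr N x 3 angular-rate matrix, rad/s.
#' @param ts sampling interval, seconds.
#' @param q0 initial unit quaternion; the heading (and, before inclination
#'   correction, the tilt) of the resulting frame is arbitrary.
#' @return N x 4 matrix of unit quaternions (w, x, y, z).
#' @export
strapdown_integrate <- function(gyr, ts, q0 = c(1, 0, 0, 0)) {
  gyr <- as.matrix(gyr)
  n <- nrow(gyr)
  stopifnot(abs(sqrt(sum(q0^2)) - 1) < 1e-6)
  # per-sample increments (vectorized), then a sequential Hamilton product
  ang <- ts / 2 * sqrt(rowSums(gyr^2))
  sinc <- ifelse(ang > 0, sin(ang) / pmax(ang, .Machine$double.xmin), 1)
  dq <- cbind(cos(ang), ts / 2 * gyr * sinc)
  q <- matrix(0, n, 4L)
  cur <- q0 / sqrt(sum(q0^2))
  for (k in seq_len(n)) {
    cur <- quat_multiply(cur, dq[k, ])
    cur <- cur / sqrt(sum(cur^2))
    q[k, ] <- cur
  }
  q
}

# Causal moving average with window `win` samples, truncated at the start
# (shrinking window over the first win-1 samples).
moving_average_causal <- function(x, win) {
  n <- length(x)
  win <- min(win, n)
  cs <- cumsum(x)
  k <- seq_len(n)
  lead <- c(rep(0, win), cs[seq_len(n - win)])
  (cs - lead) / pmin(k, win)
}

#' Zero-phase filtered gravity reference
#'
#' Low-pass filters the acceleration to isolate the gravitational component,
#' which serves as the vertical reference for inclination correction. The
#' measured acceleration is first rotated into the (slowly drifting) frame of
#' the gyroscope strapdown integration, where gravity points in an
#' approximately constant direction and motion accelerations of steady gait
#' average out. Each component is smoothed by a moving-average filter of
#' window length `t_a` run in the forward and then in the reverse direction
#' (zero phase lag); at the sequence edges the window shrinks to the
#' available samples. The filtered signal is finally rotated back into the
#' sensor frame.
#'
#' @param acc N x 3 acceleration matrix, m/s^2.
#' @param q_omega N x 4 strapdown quaternion matrix from
#'   [strapdown_integrate()].
#' @param t_a filter window length, seconds.
#' @param ts sampling interval, seconds.
#' @return N x 3 matrix: the gravity-dominated acceleration in the sensor
#'   frame.
#' @export
filtered_gravity_reference <- function(acc, q_omega, t_a, ts) {
  stopifnot(nrow(acc) == nrow(q_omega), t_a > 0)
  a_w <- quat_rotate_rows(q_omega, as.matrix(acc))
  win <- max(1L, as.integer(round(t_a / ts)))
  a_f <- apply(a_w, 2L, function(x)
    rev(moving_average_causal(rev(moving_average_causal(x, win)), win)))
  quat_rotate_rows(quat_conjugate(q_omega), a_f)
}

#' Accelerometer-based inclination correction
#'
#' Sequentially builds a correction quaternion `q_a` that tilts the
#' strapdown orientation so that the filtered gravity reference maps onto
#' the vertical axis. At each sample the reference acceleration is rotated
#' into the corrected global frame,
#' `a_r = (q_a_prev ⊗ q_omega(t_k)) ⊗ a_f(t_k) ⊗ (...)^-1`; the rotation
#' axis is `n = a_r x e_z` and the angle
#' `alpha = arccos(e_z . a_r / |a_r|)` (argument clamped to \[-1, 1\]);
#' the full angle is applied:
#' `q_a(t_k) = q_a(t_{k-1}) ⊗ [cos(alpha/2), n/|n| sin(alpha/2)]`.
#' Degenerate samples (`|n|` numerically zero, including the antiparallel
#' case alpha = pi, or a vanishing reference) leave `q_a` unchanged.
#'
#' @param q_omega N x 4 strapdown quaternion matrix.
#' @param a_f N x 3 filtered gravity reference in the sensor frame, from
#'   [filtered_gravity_reference()].
#' @return N x 4 matrix of correction quaternions `q_a`.
#' @export
inclination_correction <- function(q_omega, a_f) {
  n_samp <- nrow(q_omega)
  stopifnot(nrow(a_f) == n_samp)
  q_a <- matrix(0, n_samp, 4L)
  cur <- quat_identity()
  ez <- c(0, 0, 1)
  for (k in seq_len(n_samp)) {
    qk <- quat_multiply(cur, q_omega[k, ])
    ar <- quat_rotate(qk, a_f[k, ])
    nr <- sqrt(sum(ar^2))
    if (nr >= 1e-9) {
      axis <- c(ar[2L] * ez[3L] - ar[3L] * ez[2L],
                ar[3L] * ez[1L] - ar[1L] * ez[3L],
                ar[1L] * ez[2L] - ar[2L] * ez[1L])
      an <- sqrt(sum(axis^2))
      if (an >= 1e-12) {
        alpha <- acos(max(-1, min(1, ar[3L] / nr)))
        dq <- c(cos(alpha / 2), axis / an * sin(alpha / 2))
        # the correction axis lives in the inertial frame, so the increment
        # composes on the inertial side; this maps a_r exactly onto e_z and
        # keeps the correction mounting-invariant
        cur <- quat_multiply(dq, cur)
        cur <- cur / sqrt(sum(cur^2))
      }
    }
    q_a[k, ] <- cur
  }
  q_a
}

#' Estimate the sensor orientation of one foot
#'
#' Full orientation pipeline: the gyroscope turn-on bias is removed
#' ([estimate_gyro_bias()]), the corrected rates are integrated by strapdown
#' ([strapdown_integrate()]), a gravity reference is obtained by zero-phase
#' low-pass filtering in the strapdown frame
#' ([filtered_gravity_reference()]), and the strapdown inclination is
#' corrected against that reference ([inclination_correction()]). The final
#' orientation is `q = q_a ⊗ q_omega`, renormalized, mapping sensor-frame
#' vectors to an inertial frame with vertical z-axis and arbitrary heading.
#'
#' @param rec an [imu_recording()].
#' @param rest 0/1 motion signal used for bias estimation (e.g. from
#'   [detect_gait_events()]); `NULL` skips bias removal.
#' @param cfg a [gait_config()].
#' @return A list of class `orientation_estimate` with `q` (N x 4 unit
#'   quaternions), `q_omega`, `q_a`, `bias`, `warnings`.
#' @export
estimate_orientation <- function(rec, rest = NULL, cfg = gait_config()) {
  cfg <- as_gait_config(cfg)
  warnings <- character(0)
  bias <- c(0, 0, 0)
  if (!is.null(rest)) {
    be <- estimate_gyro_bias(rec, rest)
    bias <- be$bias
    warnings <- c(warnings, be$warnings)
  }
  gyr <- sweep(rec$gyr, 2L, bias)
  q_w <- strapdown_integrate(gyr, rec$ts)
  a_f <- filtered_gravity_reference(rec$acc, q_w, cfg$t_a, rec$ts)
  q_a <- inclination_correction(q_w, a_f)
  q <- quat_normalize(quat_multiply_rows(q_a, q_w))
  structure(list(q = q, q_omega = q_w, q_a = q_a, bias = bias,
                 warnings = warnings),
            class = "orientation_estimate")
}
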