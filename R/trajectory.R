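#' Rotate accelerations into the inertial frame
#'
#' @param rec an [imu_recording()].
#' @param q N x 4 orientation quaternion matrix (sensor to inertial), e.g.
#'   from [estimate_orientation()].
#' @return N x 3 matrix of accelerations in the inertial frame, m/s^2.
#' @export
global_acceleration <- function(rec, q) {
  stopifnot(nrow(q) == rec$n)
  quat_rotate_rows(q, rec$acc)
}

#' Integrate the velocity of one stride
#'
#' Assuming the foot is at rest at the rest instant (the midpoint of foot
#' flat), the gravity-subtracted inertial-frame acceleration is summed from
#' one rest instant to the next:
#' \deqn{v(t_k) = T_s \sum_{\tau = t_{rest,i}}^{t_k}
#'   (a_\epsilon(\tau) - (0, 0, 9.81)^\top).}
#' The sum includes the lower bound, so `v(t_rest_i)` equals one sample's
#' increment; this convention is fixed and its effect is below reporting
#' precision.
#'
#' @param a_eps N x 3 inertial-frame acceleration from
#'   [global_acceleration()].
#' @param k_rest,k_rest_next sample indices of the two rest instants.
#' @param ts sampling interval, seconds.
#' @return (k_rest_next - k_rest + 1) x 3 velocity matrix, m/s.
#' @export
integrate_stride_velocity <- function(a_eps, k_rest, k_rest_next, ts) {
  stopifnot(k_rest < k_rest_next, k_rest >= 1L, k_rest_next <= nrow(a_eps))
  a <- a_eps[k_rest:k_rest_next, , drop = FALSE]
  a[, 3L] <- a[, 3L] - 9.81
  apply(a, 2L, cumsum) * ts
}

#' Linear velocity drift correction (zero-velocity update)
#'
#' Accelerometer bias and residual orientation error make the integrated
#' velocity nonzero at the end-of-stride rest instant even though the foot
#' is at rest. The accumulated error is removed by subtracting a linear ramp
#' that is zero at the first rest instant and equals the terminal velocity at
#' the second:
#' \deqn{v_{df}(t_k) = v(t_k) - \frac{t_k - t_{rest,i}}
#'   {t_{rest,i+1} - t_{rest,i}} v(t_{rest,i+1}).}
#' The corrected velocity is exactly zero at the final rest instant; a
#' constant acceleration error is cancelled exactly.
#'
#' @param v M x 3 velocity matrix over one stride, from
#'   [integrate_stride_velocity()].
#' @return M x 3 drift-corrected velocity matrix.
#' @export
drift_correct <- function(v) {
  m <- nrow(v)
  if (m < 2L) return(v)
  ramp <- (seq_len(m) - 1L) / (m - 1L)
  v - outer(ramp, v[m, ])
}

#' Stride position trajectory and stride length
#'
#' Integrates the drift-corrected velocity into a position trajectory
#' anchored at zero and measures the stride length as the horizontal
#' displacement between the two rest instants (vertical displacement is
#' ignored; over level ground it is near zero anyway):
#' \deqn{L = \sqrt{p_x(t_{rest,i+1})^2 + p_y(t_{rest,i+1})^2}.}
#'
#' @param v_df M x 3 drift-corrected velocity from [drift_correct()].
#' @param ts sampling interval, seconds.
#' @return A list with `p` (M x 3 position matrix, m, `p[1, ] = 0` by
#'   construction up to one integration step) and `length` (stride length,
#'   m).
#' @export
stride_position_and_length <- function(v_df, ts) {
  p <- apply(v_df, 2L, cumsum) * ts
  L <- sqrt(p[nrow(p), 1L]^2 + p[nrow(p), 2L]^2)
  list(p = p, length = L)
}

#' Walking speed of one stride
#'
#' @param length stride length, m.
#' @param t_stride stride duration (initial contact to initial contact), s.
#' @return speed in m/s (multiply by 3.6 for km/h).
#' @export
walking_speed <- function(length, t_stride) {
  stopifnot(t_stride > 0)
  length / t_stride
}

# Spatial parameters for all valid strides of one foot. Integration runs
# from rest instant to rest instant (not initial contact to initial
# contact), which keeps the zero-velocity assumption robust; stride
# durations still come from the initial contacts.
stride_spatial_params <- function(rec, events, q) {
  a_eps <- global_acceleration(rec, q)
  s <- events$strides
  out <- data.frame(stride = s$stride, length_m = NA_real_, speed_ms = NA_real_)
  # next stride's rest instant; the last stride has none within the table,
  # so use the rest instant following its final initial contact if the next
  # motion phase completed (t_ic_next row carries it via the next row)
  for (j in seq_len(nrow(s))) {
    if (!s$valid[j]) next
    t_r0 <- s$t_rest[j]
    t_r1 <- if (j < nrow(s)) s$t_rest[j + 1L] else NA_real_
    if (is.na(t_r1) || (j < nrow(s) && !s$valid[j + 1L] &&
                        is.na(s$t_rest[j + 1L]))) next
    k0 <- time_to_index(rec, t_r0)
    k1 <- time_to_index(rec, t_r1)
    if (k1 <= k0) next
    v <- integrate_stride_velocity(a_eps, k0, k1, rec$ts)
    v_df <- drift_correct(v)
    pl <- stride_position_and_length(v_df, rec$ts)
    out$length_m[j] <- pl$length
    out$speed_ms[j] <- walking_speed(pl$length, s$t_ic_next[j] - s$t_ic[j])
  }
  out
}
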