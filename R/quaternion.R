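# Internal quaternion utilities.
#
# Quaternions are stored as length-4 numeric vectors c(w, x, y, z) or as
# N x 4 matrices (one quaternion per row). A quaternion q representing a
# sensor orientation maps sensor-frame vectors to inertial-frame vectors by
# conjugation: v_inertial = q ⊗ v_sensor ⊗ q^-1. The inertial frame has a
# vertical z-axis and arbitrary heading.

quat_identity <- function() c(1, 0, 0, 0)

#' @noRd
quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

# Row-wise Hamilton product of two N x 4 matrices (or matrix and single quat).
quat_multiply_rows <- function(P, Q) {
  if (is.vector(P)) P <- matrix(P, nrow = if (is.matrix(Q)) nrow(Q) else 1L, ncol = 4L, byrow = TRUE)
  if (is.vector(Q)) Q <- matrix(Q, nrow = nrow(P), ncol = 4L, byrow = TRUE)
  cbind(P[, 1L] * Q[, 1L] - P[, 2L] * Q[, 2L] - P[, 3L] * Q[, 3L] - P[, 4L] * Q[, 4L],
        P[, 1L] * Q[, 2L] + P[, 2L] * Q[, 1L] + P[, 3L] * Q[, 4L] - P[, 4L] * Q[, 3L],
        P[, 1L] * Q[, 3L] - P[, 2L] * Q[, 4L] + P[, 3L] * Q[, 1L] + P[, 4L] * Q[, 2L],
        P[, 1L] * Q[, 4L] + P[, 2L] * Q[, 3L] - P[, 3L] * Q[, 2L] + P[, 4L] * Q[, 1L])
}

quat_conjugate <- function(q) {
  if (is.matrix(q)) cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L]) else c(q[1L], -q[2L], -q[3L], -q[4L])
}

quat_normalize <- function(q) {
  if (is.matrix(q)) q / sqrt(rowSums(q^2)) else q / sqrt(sum(q^2))
}

# Rotate a single 3-vector by a single unit quaternion: q ⊗ v ⊗ q^-1.
quat_rotate <- function(q, v) {
  qv <- c(0, v)
  out <- quat_multiply(quat_multiply(q, qv), quat_conjugate(q))
  out[2:4]
}

# Row-wise rotation of N x 3 vectors by N x 4 quaternions (q ⊗ v ⊗ q^-1),
# expanded to avoid building zero-real-part quaternions.
quat_rotate_rows <- function(q, v) {
  if (is.vector(q)) q <- matrix(q, nrow = nrow(v), ncol = 4L, byrow = TRUE)
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  vx <- v[, 1L]; vy <- v[, 2L]; vz <- v[, 3L]
  # t = 2 * (q_vec x v); v' = v + w*t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + (y * tz - z * ty),
        vy + w * ty + (z * tx - x * tz),
        vz + w * tz + (x * ty - y * tx))
}

# Unit quaternion for a rotation of `angle` radians about `axis` (not
# necessarily unit length). Zero axis or zero angle yields the identity.
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps || angle == 0) return(quat_identity())
  c(cos(angle / 2), axis / n * sin(angle / 2))
}

# Rotation angle (radians, in [0, pi]) between two unit quaternions.
quat_angle_between <- function(p, q) {
  d <- abs(sum(p * q))
  2 * acos(min(1, d))
}

# Angle between a 3-vector and the vertical axis, radians.
angle_to_vertical <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(NA_real_)
  acos(max(-1, min(1, v[3L] / n)))
}
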