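#' Construct an IMU recording
#'
#' A recording holds the uniformly sampled raw signals of one foot-worn
#' inertial measurement unit: 3-axis angular rate (rad/s) and 3-axis
#' acceleration (m/s^2). No assumption is made about how the sensor is
#' oriented on the foot.
#'
#' @param gyr numeric matrix, N x 3, angular rate in rad/s.
#' @param acc numeric matrix, N x 3, acceleration (including gravity) in m/s^2.
#' @param ts sampling interval in seconds (e.g. 1/110 for 110 Hz).
#' @param foot_side `"left"` or `"right"`.
#' @param start_time_offset constant time offset in seconds applied to this
#'   foot's time axis, for cross-foot synchronization. Default 0.
#' @return An object of class `imu_recording` with elements `gyr`, `acc`,
#'   `ts`, `n`, `foot_side`, `start_time_offset`.
#' @seealso [read_imu_csv()], [detect_gait_events()]
#' @export
imu_recording <- function(gyr, acc, ts, foot_side = c("left", "right"),
                          start_time_offset = 0) {
  foot_side <- match.arg(foot_side)
  gyr <- as.matrix(gyr)
  acc <- as.matrix(acc)
  storage.mode(gyr) <- "double"
  storage.mode(acc) <- "double"
  if (ncol(gyr) != 3L || ncol(acc) != 3L)
    stop("gyr and acc must have 3 columns")
  if (nrow(gyr) != nrow(acc))
    stop("gyr and acc must have the same number of samples")
  if (nrow(gyr) < 2L)
    stop("a recording needs at least 2 samples")
  if (!is.numeric(ts) || length(ts) != 1L || !is.finite(ts) || ts <= 0)
    stop("ts must be a single positive number")
  if (!all(is.finite(gyr)) || !all(is.finite(acc))) {
    bad <- which(!stats::complete.cases(cbind(gyr, acc)) |
                   rowSums(!is.finite(cbind(gyr, acc))) > 0)[1L]
    stop(sprintf("non-finite sensor values (first offending row: %d)", bad))
  }
  dimnames(gyr) <- list(NULL, c("x", "y", "z"))
  dimnames(acc) <- list(NULL, c("x", "y", "z"))
  structure(
    list(gyr = gyr, acc = acc, ts = ts, n = nrow(gyr),
         foot_side = foot_side, start_time_offset = start_time_offset),
    class = "imu_recording")
}

#' Sample times of a recording
#'
#' @param rec an [imu_recording()].
#' @return numeric vector of length `rec$n`: `start_time_offset + (0:(n-1)) * ts`.
#' @export
recording_times <- function(rec) {
  rec$start_time_offset + (seq_len(rec$n) - 1L) * rec$ts
}

# Nearest sample index (1-based) for a time in seconds; clamped to [1, n].
time_to_index <- function(rec, t) {
  k <- as.integer(round((t - rec$start_time_offset) / rec$ts)) + 1L
  pmin(pmax(k, 1L), rec$n)
}

index_to_time <- function(rec, k) {
  rec$start_time_offset + (k - 1L) * rec$ts
}

# Round a time to the recording's sample grid.
snap_to_grid <- function(rec, t) index_to_time(rec, time_to_index(rec, t))

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording (%s foot): %d samples at %.6g Hz (%.2f s)\n",
              x$foot_side, x$n, 1 / x$ts, x$n * x$ts))
  invisible(x)
}

imu_csv_columns <- c("t", "gyr_x", "gyr_y", "gyr_z", "acc_x", "acc_y", "acc_z")

#' Read an IMU recording from CSV
#'
#' The file must have a header row `t,gyr_x,gyr_y,gyr_z,acc_x,acc_y,acc_z`,
#' time in seconds (strictly increasing, uniformly spaced within 1 % relative
#' jitter), angular rate in rad/s and acceleration in m/s^2. Units are taken
#' as given; no conversion is applied. The sampling interval is set to the
#' median time difference.
#'
#' @param path path to a CSV file.
#' @param foot_side `"left"` or `"right"`.
#' @return An [imu_recording()]. `start_time_offset` is set to the first
#'   time stamp in the file.
#' @export
read_imu_csv <- function(path, foot_side = c("left", "right")) {
  foot_side <- match.arg(foot_side)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(imu_csv_columns, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("format error: missing column(s) %s in %s",
                 paste(missing_cols, collapse = ", "), path))
  df <- df[imu_csv_columns]
  if (nrow(df) < 2L) stop("format error: need at least 2 samples")
  bad <- which(rowSums(!is.finite(as.matrix(df))) > 0)
  if (length(bad) > 0L)
    stop(sprintf("data error: non-finite value in row %d of %s", bad[1L], path))
  t <- df$t
  dt <- diff(t)
  if (any(dt <= 0)) stop("sampling error: time stamps not strictly increasing")
  ts <- stats::median(dt)
  if (max(abs(dt - ts)) > 0.01 * ts)
    stop(sprintf("sampling error: non-uniform sampling (max jitter %.3g%% of T_s)",
                 100 * max(abs(dt - ts)) / ts))
  imu_recording(gyr = as.matrix(df[c("gyr_x", "gyr_y", "gyr_z")]),
                acc = as.matrix(df[c("acc_x", "acc_y", "acc_z")]),
                ts = ts, foot_side = foot_side, start_time_offset = t[1L])
}

#' Write an IMU recording to CSV
#'
#' Writes the format read by [read_imu_csv()] at full double precision, so
#' that a write/read round trip reproduces the signal values bit-identically.
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t = recording_times(rec),
                   gyr_x = rec$gyr[, 1L], gyr_y = rec$gyr[, 2L], gyr_z = rec$gyr[, 3L],
                   acc_x = rec$acc[, 1L], acc_y = rec$acc[, 2L], acc_z = rec$acc[, 3L])
  # %.17g is lossless for IEEE doubles
  lines <- c(paste(imu_csv_columns, collapse = ","),
             do.call(sprintf,
                     c(list("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g"),
                       unname(as.list(df)))))
  writeLines(lines, path)
  invisible(path)
}
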