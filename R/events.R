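#' Deviation of the accelerometer norm from gravity
#'
#' When the foot rests flat on the ground the accelerometer measures only
#' gravity, so the norm of the readings is close to 9.81 m/s^2. The rest
#' detector therefore works on the absolute deviation of the norm from that
#' value,
#' \deqn{a(t_k) = \left| \lVert a(t_k) \rVert - 9.81 \right|.}
#' The constant 9.81 m/s^2 is fixed.
#'
#' @param acc N x 3 acceleration matrix, m/s^2.
#' @return numeric vector of length N, non-negative.
#' @export
accel_deviation <- function(acc) {
  acc <- as.matrix(acc)
  abs(sqrt(rowSums(acc^2)) - 9.81)
}

#' Acausal hysteresis thresholding
#'
#' Converts a non-negative scalar signal into a binary activity signal with a
#' two-sided hysteresis band around a threshold `th`, applied first in the
#' forward and then in the backward direction. The forward pass `r*` switches
#' to 1 where `x > (1+h) th`, to 0 where `x < (1-h) th`, and otherwise holds
#' its previous value (initial value 0). The backward pass keeps every 1 of
#' `r*`, switches to 0 where `x < (1-h) th`, and otherwise takes the value of
#' the *next* sample (last value taken from the forward pass). The backward
#' pass removes the forward pass's tendency to hold a stale 1 through
#' in-band samples that trail an activity burst.
#'
#' @param x numeric vector, the signal (typically a norm, non-negative).
#' @param th positive threshold.
#' @param h hysteresis factor in \[0, 1).
#' @return integer vector of 0/1, same length as `x`.
#' @export
acausal_hysteresis <- function(x, th, h) {
  stopifnot(th > 0, h >= 0, h < 1)
  n <- length(x)
  hi <- x > (1 + h) * th
  lo <- x < (1 - h) * th
  rf <- integer(n)
  prev <- 0L
  for (k in seq_len(n)) {
    if (hi[k]) prev <- 1L else if (lo[k]) prev <- 0L
    rf[k] <- prev
  }
  r <- integer(n)
  nxt <- rf[n]
  for (k in n:1) {
    if (rf[k] == 1L) nxt <- 1L else if (lo[k]) nxt <- 0L
    r[k] <- nxt
  }
  r
}

#' Remove short phases from a binary signal
#'
#' Zero-runs strictly shorter than `min_zero` are set to one first; then
#' one-runs strictly shorter than `min_one` are set to zero. Durations are
#' run length times `ts`. Runs touching either end of the sequence are left
#' untouched: recordings begin and end mid-phase, so a truncated boundary run
#' carries no duration information.
#'
#' @param r integer 0/1 vector.
#' @param min_zero minimum zero-phase duration, seconds.
#' @param min_one minimum one-phase duration, seconds.
#' @param ts sampling interval, seconds.
#' @return integer 0/1 vector.
#' @export
prune_short_phases <- function(r, min_zero, min_one, ts) {
  stopifnot(min_zero >= 0, min_one >= 0, ts > 0)
  r <- prune_runs(r, value = 0L, min_dur = min_zero, ts = ts)
  prune_runs(r, value = 1L, min_dur = min_one, ts = ts)
}

# Replace interior runs of `value` shorter than min_dur with the complement.
prune_runs <- function(r, value, min_dur, ts) {
  if (length(r) == 0L || min_dur <= 0) return(r)
  rl <- rle(r)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  n_runs <- length(rl$lengths)
  for (j in seq_len(n_runs)) {
    if (rl$values[j] == value && j > 1L && j < n_runs &&
        rl$lengths[j] * ts < min_dur) {
      r[starts[j]:ends[j]] <- 1L - value
    }
  }
  r
}

#' Automatic threshold adaptation
#'
#' Determines a detection threshold from the data itself, so that no
#' per-trial manual tuning for gait velocity or sensor characteristics is
#' needed. Starting from the mid-range value, the threshold is iterated as a
#' weighted combination of the mean below and the mean above the current
#' threshold:
#' \deqn{th_{l+1} = w \,\mathrm{mean}(x \le th_l) + (1 - w)\,\mathrm{mean}(x > th_l).}
#' 200 iterations are ample for convergence. If one side of the partition is
#' empty (constant signal), its mean term is taken as the current threshold.
#' The returned value is bounded below by `lower_bound`, applied after the
#' final iteration.
#'
#' @param x numeric vector, non-empty.
#' @param w weighting factor in (0, 1); larger values pull the threshold
#'   toward the low (rest) level.
#' @param lower_bound minimum returned threshold.
#' @param n_iter number of iterations.
#' @return a single threshold value.
#' @export
auto_threshold <- function(x, w, lower_bound = 0, n_iter = 200L) {
  stopifnot(length(x) > 0L, w > 0, w < 1)
  th <- (max(x) + min(x)) / 2
  for (l in seq_len(n_iter)) {
    below <- x <= th
    m_lo <- if (any(below)) mean(x[below]) else th
    m_hi <- if (any(!below)) mean(x[!below]) else th
    th <- w * m_lo + (1 - w) * m_hi
  }
  max(th, lower_bound)
}

# One foot's rest/motion segmentation. Returns the per-channel and combined
# binary signals (1 = motion) plus the auto-tuned thresholds.
rest_signals <- function(rec, cfg) {
  a_dev <- accel_deviation(rec$acc)
  w_norm <- sqrt(rowSums(rec$gyr^2))
  a_th <- auto_threshold(a_dev, cfg$w_a, cfg$a_th_min, cfg$n_threshold_iterations)
  # the angular-rate lower bound may be 0; hysteresis needs th > 0
  w_th <- auto_threshold(w_norm, cfg$w_omega, cfg$omega_th_min,
                         cfg$n_threshold_iterations)
  if (w_th <= 0) w_th <- .Machine$double.eps
  r_a <- prune_short_phases(acausal_hysteresis(a_dev, a_th, cfg$h_a),
                            cfg$t0_min, cfg$t1_min, rec$ts)
  r_w <- prune_short_phases(acausal_hysteresis(w_norm, w_th, cfg$h_omega),
                            cfg$t0_min, cfg$t1_min, rec$ts)
  r <- as.integer(r_a | r_w)
  r <- prune_runs(r, value = 0L, min_dur = cfg$t0_min, ts = rec$ts)
  r <- prune_runs(r, value = 1L, min_dur = 2 * cfg$t1_min, ts = rec$ts)
  list(r = r, r_a = r_a, r_omega = r_w, a_th = a_th, omega_th = w_th)
}

#' Detect foot-flat phases
#'
#' Segments a recording into rest (foot flat on the ground) and motion.
#' Acceleration-norm deviation and angular-rate norm are each auto-thresholded
#' ([auto_threshold()]), binarized with acausal hysteresis
#' ([acausal_hysteresis()]) and cleaned of short phases
#' ([prune_short_phases()]); the two signals are then OR-combined (motion if
#' at least one channel shows motion), zero-phases shorter than `t0_min` are
#' removed, and finally one-phases shorter than `2 t1_min` are removed. Each
#' 0-to-1 transition of the result marks a heel rise, each 1-to-0 transition
#' a full contact; the rest instant of each foot-flat phase is its midpoint,
#' rounded to the sample grid.
#'
#' @param rec an [imu_recording()].
#' @param cfg a [gait_config()].
#' @return A list with elements `rest` (the combined 0/1 motion signal and
#'   its components), `t_hr`, `t_fc` (event times in seconds), `t_rest`
#'   (rest instants of complete foot-flat phases), and the tuned thresholds.
#' @export
detect_foot_flat <- function(rec, cfg = gait_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  cfg <- as_gait_config(cfg)
  if (rec$n * rec$ts <= 2 * (cfg$t0_min + cfg$t1_min))
    stop("recording too short for foot-flat detection")
  rs <- rest_signals(rec, cfg)
  r <- rs$r
  d <- diff(r)
  t <- recording_times(rec)
  t_hr <- t[which(d == 1L) + 1L]   # first motion sample
  t_fc <- t[which(d == -1L) + 1L]  # first rest sample
  if (sum(d == 1L) + sum(d == -1L) == 0L && all(r == 0L))
    stop("insufficient strides: no motion phases detected")
  # rest instants: midpoints of interior foot-flat phases (fc_i .. hr_i)
  t_rest <- numeric(0)
  for (fc in t_fc) {
    hr_after <- t_hr[t_hr > fc]
    if (length(hr_after) > 0L)
      t_rest <- c(t_rest, snap_to_grid(rec, (fc + hr_after[1L]) / 2))
  }
  list(rest = rs, t_hr = t_hr, t_fc = t_fc, t_rest = t_rest,
       a_th = rs$a_th, omega_th = rs$omega_th)
}

#' Tilt-rate signal
#'
#' Projects the instantaneous angular rate onto the direction of the
#' accumulated rotation since a start time:
#' \deqn{\Gamma(t_k) = \omega(t_k)^\top S(t_k) / \lVert S(t_k)\rVert,
#'   \quad S(t_k) = \sum_{\tau = t_{start}}^{t_k} \omega(\tau).}
#' This identifies the foot's main axis of rotation since the last heel rise
#' and measures the signed rotation rate about it, independently of how the
#' sensor is mounted (only dot products and norms are used). Where
#' \eqn{\lVert S \rVert = 0} the tilt-rate is defined as 0.
#'
#' @param gyr N x 3 angular-rate matrix of the recording, rad/s.
#' @param k_start,k_end sample indices (1-based) delimiting the window.
#' @return numeric vector of length `k_end - k_start + 1`.
#' @export
tilt_rate <- function(gyr, k_start, k_end) {
  stopifnot(k_start >= 1L, k_end <= nrow(gyr), k_start < k_end)
  w <- gyr[k_start:k_end, , drop = FALSE]
  s <- apply(w, 2L, cumsum)
  num <- rowSums(w * s)
  den <- sqrt(rowSums(s^2))
  # an accumulated rotation that is numerically zero (relative to the
  # largest accumulation seen) has no meaningful direction
  ifelse(den > 1e-9 * max(den), num / den, 0)
}

#' Detect the toe-off within one motion phase
#'
#' During push-off the foot first rotates as the heel rises, then reverses
#' its direction of rotation when the toes leave the ground. The reversal is
#' found on the tilt-rate signal computed from the heel rise to the next full
#' contact: let \eqn{\Gamma_{max}} be the maximum over the first half of the
#' motion phase; the first sample with \eqn{\Gamma \ge \Gamma_{max}/2} is
#' located, and the first subsequent sample with \eqn{\Gamma \le 0} is taken
#' as the toe-off. Restricting the maximum to the first half and requiring
#' the half-maximum first makes the detection robust against noise right
#' after heel rise and against large swing peaks. If no zero-crossing occurs
#' before full contact the stride is marked invalid (`NA`).
#'
#' @param rec an [imu_recording()].
#' @param t_hr heel-rise time, seconds.
#' @param t_fc_next next full-contact time, seconds.
#' @return toe-off time in seconds, or `NA` if the phase has no detectable
#'   rotation reversal.
#' @export
detect_toe_off <- function(rec, t_hr, t_fc_next) {
  stopifnot(t_hr < t_fc_next)
  k_hr <- time_to_index(rec, t_hr)
  k_fc <- time_to_index(rec, t_fc_next)
  if (k_fc - k_hr < 2L) return(NA_real_)
  gamma <- tilt_rate(rec$gyr, k_hr, k_fc)
  k_half <- time_to_index(rec, (t_hr + t_fc_next) / 2)
  g_max <- max(gamma[seq_len(k_half - k_hr + 1L)])
  i_half <- which(gamma >= g_max / 2)[1L]
  if (is.na(i_half)) return(NA_real_)
  i_zero <- which(gamma[i_half:length(gamma)] <= 0)[1L]
  if (is.na(i_zero)) return(NA_real_)
  index_to_time(rec, k_hr + i_half + i_zero - 2L)
}

#' Detect the initial contact within one swing-to-stance transition
#'
#' The impact of the foot on the ground causes a sharp change of
#' acceleration, so the jerk norm (first-order backward difference of the
#' accelerometer readings divided by the sampling interval) peaks at initial
#' contact. Only a sub-window of the phase between the previous toe-off and
#' the upcoming full contact is searched, starting at
#' `j_win * t_to_prev + (1 - j_win) * t_fc`. The first sample whose jerk norm
#' reaches `j_th` times the window maximum is the initial contact.
#'
#' @param rec an [imu_recording()].
#' @param t_to_prev previous toe-off time, seconds.
#' @param t_fc full-contact time ending the transition, seconds.
#' @param j_win window-start ratio in \[0, 1\].
#' @param j_th relative jerk threshold in (0, 1\].
#' @return initial-contact time in seconds, or `NA` when the window is empty.
#' @export
detect_initial_contact <- function(rec, t_to_prev, t_fc, j_win = 0.7, j_th = 0.95) {
  stopifnot(t_to_prev < t_fc)
  t_win <- j_win * t_to_prev + (1 - j_win) * t_fc
  k_win <- time_to_index(rec, t_win)
  k_fc <- time_to_index(rec, t_fc)
  if (k_win >= k_fc) return(NA_real_)
  jn <- jerk_norm(rec)[k_win:k_fc]
  j_max <- max(jn)
  k_ic <- k_win + which(jn >= j_th * j_max)[1L] - 1L
  index_to_time(rec, k_ic)
}

# Jerk norm, backward difference; the first sample has no predecessor and is 0.
jerk_norm <- function(rec) {
  j <- diff(rec$acc) / rec$ts
  c(0, sqrt(rowSums(j^2)))
}

#' Detect the gait event cycle of one foot
#'
#' Runs the full per-foot event detection: foot-flat segmentation
#' ([detect_foot_flat()]), toe-off detection per motion phase
#' ([detect_toe_off()]) and initial-contact detection per swing
#' ([detect_initial_contact()]). Events are grouped into strides `i` with
#' the ordering
#' `t_ic[i] < t_fc[i] <= t_rest[i] <= t_hr[i] < t_to[i] < t_ic[i+1]`,
#' i.e. stride `i` starts at its initial contact and its heel rise / toe-off
#' are those of the following motion phase. Strides with an undetectable
#' toe-off or initial contact are flagged invalid; the ordering invariant is
#' enforced and violations invalidate the stride.
#'
#' @param rec an [imu_recording()].
#' @param cfg a [gait_config()].
#' @return An object of class `gait_events`: a list with `strides` (data
#'   frame with columns `stride`, `t_ic`, `t_fc`, `t_rest`, `t_hr`, `t_to`,
#'   `t_ic_next`, `valid`), `foot_side`, the combined rest signal, tuned
#'   thresholds, and `warnings`.
#' @export
detect_gait_events <- function(rec, cfg = gait_config()) {
  cfg <- as_gait_config(cfg)
  ff <- detect_foot_flat(rec, cfg)
  warnings <- character(0)

  # motion phases: pair each heel rise with the next full contact
  hr <- ff$t_hr
  fc <- ff$t_fc
  phases <- list()
  for (h in hr) {
    nxt <- fc[fc > h]
    if (length(nxt) > 0L) phases[[length(phases) + 1L]] <- c(hr = h, fc = nxt[1L])
  }
  if (length(phases) < 2L)
    stop("insufficient strides: fewer than 2 complete motion phases")
  ph <- do.call(rbind, phases)

  p_to <- rep(NA_real_, nrow(ph))
  p_ic <- rep(NA_real_, nrow(ph))
  for (j in seq_len(nrow(ph))) {
    p_to[j] <- detect_toe_off(rec, ph[j, "hr"], ph[j, "fc"])
    if (is.na(p_to[j])) {
      warnings <- c(warnings, sprintf(
        "%s foot, motion phase %d (t_hr=%.3f s): no tilt-rate zero-crossing; toe-off invalid",
        rec$foot_side, j, ph[j, "hr"]))
      next
    }
    p_ic[j] <- detect_initial_contact(rec, p_to[j], ph[j, "fc"],
                                      cfg$j_win, cfg$j_th)
    if (is.na(p_ic[j]))
      warnings <- c(warnings, sprintf(
        "%s foot, motion phase %d: empty initial-contact window; stride invalid",
        rec$foot_side, j))
  }

  # stride i: ic/fc from motion phase i, hr/to from motion phase i+1
  m <- nrow(ph) - 1L
  strides <- data.frame(
    stride = seq_len(m),
    t_ic = p_ic[seq_len(m)],
    t_fc = ph[seq_len(m), "fc"],
    t_rest = NA_real_,
    t_hr = ph[seq_len(m) + 1L, "hr"],
    t_to = p_to[seq_len(m) + 1L],
    t_ic_next = p_ic[seq_len(m) + 1L]
  )
  strides$t_rest <- snap_to_grid(rec, (strides$t_fc + strides$t_hr) / 2)
  ok <- !is.na(strides$t_ic) & !is.na(strides$t_to) & !is.na(strides$t_ic_next)
  order_ok <- ok &
    strides$t_ic < strides$t_fc &
    strides$t_fc <= strides$t_rest &
    strides$t_rest <= strides$t_hr &
    strides$t_hr < strides$t_to &
    strides$t_to < strides$t_ic_next
  if (any(ok & !order_ok))
    warnings <- c(warnings, sprintf(
      "%s foot: %d stride(s) violate the event ordering and were invalidated",
      rec$foot_side, sum(ok & !order_ok)))
  strides$valid <- order_ok

  structure(
    list(strides = strides, foot_side = rec$foot_side, ts = rec$ts,
         rest = ff$rest$r, a_th = ff$a_th, omega_th = ff$omega_th,
         warnings = warnings),
    class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events (%s foot): %d strides (%d valid), a_th = %.3g m/s^2, omega_th = %.3g rad/s\n",
              x$foot_side, nrow(x$strides), sum(x$strides$valid),
              x$a_th, x$omega_th))
  if (length(x$warnings) > 0L)
    cat(sprintf("  %d warning(s); first: %s\n", length(x$warnings), x$warnings[1L]))
  invisible(x)
}
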