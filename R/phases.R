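#' Per-stride temporal parameters of one foot
#'
#' For each valid stride, the stride time is the time from one initial
#' contact to the next initial contact of the same foot, the swing time is
#' the time from toe-off to the next initial contact, and the stance time is
#' the remainder. Relative durations are fractions of the stride time and
#' cadence is the number of steps per minute, `120 / T_stride`.
#'
#' @param events a `gait_events` object from [detect_gait_events()].
#' @return Data frame with one row per valid stride: `stride`, `t_ic`,
#'   `t_stride`, `t_swing`, `t_stance` (seconds), `swing_rel`, `stance_rel`
#'   (fractions), `cadence` (steps/min).
#' @export
stride_timings <- function(events) {
  s <- events$strides[events$strides$valid, , drop = FALSE]
  if (nrow(s) < 1L) stop("no valid strides")
  t_stride <- s$t_ic_next - s$t_ic
  t_swing <- s$t_ic_next - s$t_to
  t_stance <- t_stride - t_swing
  data.frame(stride = s$stride, t_ic = s$t_ic,
             t_stride = t_stride, t_swing = t_swing, t_stance = t_stance,
             swing_rel = t_swing / t_stride,
             stance_rel = t_stance / t_stride,
             cadence = 120 / t_stride)
}

#' Bilateral gait phases
#'
#' Splits each ipsilateral stride into the clinically defined phases using
#' events of both feet. Within the stride from `t_ic[i]` to `t_ic[i+1]`:
#' loading response runs from the initial contact to the first contralateral
#' toe-off, mid-stance from there to the ipsilateral heel rise, terminal
#' stance from the heel rise to the next contralateral initial contact,
#' pre-swing from there to the ipsilateral toe-off, and swing for the rest of
#' the stride. Single limb support is mid-stance plus terminal stance (the
#' contralateral foot is in the air). All durations are returned relative to
#' the stride time.
#'
#' When the required event ordering
#' (contra toe-off < ipsi heel rise < contra initial contact < ipsi toe-off)
#' does not hold, the stride is flagged `atypical` and only loading response,
#' single limb support (contra toe-off to contra initial contact), pre-swing
#' and swing are reported; the mid-stance/terminal-stance split is undefined.
#' A contralateral event tie on the sample grid produces a zero-length phase
#' rather than a flag, so the reported percentages always sum to 100.
#'
#' @param ipsi,contra `gait_events` objects for the two feet, sharing a
#'   common time base.
#' @return Data frame with one row per valid ipsilateral stride: relative
#'   durations `lr_rel`, `ms_rel`, `ts_rel`, `sls_rel`, `ps_rel`,
#'   `swing_rel`, `stance_rel` and flags `atypical`, `bilateral` (FALSE when
#'   no matching contralateral events exist and only stance/swing are given).
#' @export
bilateral_phases <- function(ipsi, contra) {
  si <- ipsi$strides[ipsi$strides$valid, , drop = FALSE]
  if (nrow(si) < 1L) stop("no valid ipsilateral strides")
  sc <- contra$strides[contra$strides$valid, , drop = FALSE]
  c_to <- sort(sc$t_to)
  c_ic <- sort(c(sc$t_ic, sc$t_ic_next))

  out <- data.frame(stride = si$stride,
                    lr_rel = NA_real_, ms_rel = NA_real_, ts_rel = NA_real_,
                    sls_rel = NA_real_, ps_rel = NA_real_,
                    swing_rel = NA_real_, stance_rel = NA_real_,
                    atypical = FALSE, bilateral = FALSE)
  for (j in seq_len(nrow(si))) {
    t_ic <- si$t_ic[j]; t_hr <- si$t_hr[j]; t_to <- si$t_to[j]
    t_icn <- si$t_ic_next[j]
    t_str <- t_icn - t_ic
    out$swing_rel[j] <- (t_icn - t_to) / t_str
    out$stance_rel[j] <- (t_to - t_ic) / t_str
    # first contralateral toe-off at/after the ipsilateral initial contact;
    # ties on the grid give a zero-length loading response
    cto <- c_to[c_to >= t_ic & c_to < t_icn][1L]
    if (is.na(cto)) next
    cic <- c_ic[c_ic >= cto & c_ic <= t_icn][1L]
    if (is.na(cic)) next
    out$bilateral[j] <- TRUE
    out$lr_rel[j] <- (cto - t_ic) / t_str
    out$sls_rel[j] <- (cic - cto) / t_str
    out$ps_rel[j] <- (t_to - cic) / t_str
    if (cto <= t_hr && t_hr <= cic && cic <= t_to) {
      out$ms_rel[j] <- (t_hr - cto) / t_str
      out$ts_rel[j] <- (cic - t_hr) / t_str
    } else {
      # ordering violated: the mid-stance/terminal-stance split is
      # undefined; report only the phases delimited by contralateral events
      out$atypical[j] <- TRUE
    }
  }
  out
}

#' Support phases from both feet
#'
#' Labels every sample of the jointly covered interval by how many and which
#' feet are in contact with the ground. A foot is in contact from each
#' initial contact to the same stride's toe-off. Phases are
#' `double_support`, `single_support_left`, `single_support_right` and
#' `zero_contact` (the latter occurring only in running).
#'
#' @param left,right `gait_events` objects for the two feet on a shared time
#'   base.
#' @param ts sampling interval, seconds.
#' @return A list with `segments` (data frame `t_start`, `t_end`, `label`)
#'   and `fractions` (named proportions of the analyzed interval).
#' @export
support_phases <- function(left, right, ts = left$ts) {
  contact_intervals <- function(ev) {
    s <- ev$strides[ev$strides$valid, , drop = FALSE]
    if (nrow(s) < 1L) stop("no valid strides for support-phase analysis")
    cbind(start = s$t_ic, end = s$t_to)
  }
  int_l <- contact_intervals(left)
  int_r <- contact_intervals(right)
  t0 <- max(min(int_l[, "start"]), min(int_r[, "start"]))
  t1 <- min(max(int_l[, "end"]), max(int_r[, "end"]))
  if (t1 <= t0) stop("feet do not overlap in time")
  tt <- seq(t0, t1, by = ts)
  in_contact <- function(ints, tt) {
    res <- logical(length(tt))
    for (j in seq_len(nrow(ints)))
      res <- res | (tt >= ints[j, "start"] & tt < ints[j, "end"])
    res
  }
  cl <- in_contact(int_l, tt)
  cr <- in_contact(int_r, tt)
  label <- ifelse(cl & cr, "double_support",
                  ifelse(cl, "single_support_left",
                         ifelse(cr, "single_support_right", "zero_contact")))
  rl <- rle(label)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  segments <- data.frame(t_start = tt[starts],
                         t_end = tt[starts] + rl$lengths * ts,
                         label = rl$values)
  fractions <- tapply(rep(ts, length(label)), label, sum) / (length(label) * ts)
  all_labels <- c("double_support", "single_support_left",
                  "single_support_right", "zero_contact")
  fr <- stats::setNames(numeric(4), all_labels)
  fr[names(fractions)] <- fractions
  list(segments = segments, fractions = fr,
       t_start = t0, t_end = tt[length(tt)] + ts)
}
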