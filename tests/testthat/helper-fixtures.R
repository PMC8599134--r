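# Shared fixtures and independent oracles for the test suite.

# noise-free sensor at 110 Hz
nf_sensor <- function(fs = 110) {
  sensor_model(gyro_noise_sd = 0, accel_noise_sd = 0,
               gyro_bias = c(0, 0, 0), mounting = c(1, 0, 0, 0), fs = fs)
}

# memoised simulations reused across test files
.fixture_env <- new.env(parent = emptyenv())

sim_noise_free_30s <- function() {
  if (is.null(.fixture_env$nf30))
    .fixture_env$nf30 <- simulate_gait(gait_profile(duration = 30),
                                       nf_sensor(), nf_sensor(), seed = 42)
  .fixture_env$nf30
}

fit_noise_free_30s <- function() {
  if (is.null(.fixture_env$fit30)) {
    sim <- sim_noise_free_30s()
    .fixture_env$fit30 <- gait_analysis(sim$left, sim$right)
  }
  .fixture_env$fit30
}

# brute-force re-implementation of the forward/backward hysteresis passes,
# written directly from the two defining recurrences
oracle_hysteresis <- function(x, th, h) {
  n <- length(x)
  rs <- integer(n)
  for (k in seq_len(n)) {
    prev <- if (k == 1L) 0L else rs[k - 1L]
    rs[k] <- if (x[k] > (1 + h) * th) 1L else if (x[k] < (1 - h) * th) 0L else prev
  }
  r <- integer(n)
  for (k in n:1) {
    nxt <- if (k == n) rs[n] else r[k + 1L]
    r[k] <- if (rs[k] == 1L) 1L else if (x[k] < (1 - h) * th) 0L else nxt
  }
  r
}

# run-length based short-phase removal oracle (boundary runs exempt)
oracle_prune <- function(r, min_zero, min_one, ts) {
  fix <- function(r, val, min_dur) {
    n <- length(r)
    k <- 1L
    while (k <= n) {
      if (r[k] == val) {
        j <- k
        while (j < n && r[j + 1L] == val) j <- j + 1L
        if (k > 1L && j < n && (j - k + 1L) * ts < min_dur)
          r[k:j] <- 1L - val
        k <- j + 1L
      } else k <- k + 1L
    }
    r
  }
  fix(fix(r, 0L, min_zero), 1L, min_one)
}

# independent iteration of the threshold-adaptation recursion
oracle_auto_threshold <- function(x, w, n_iter = 200L) {
  th <- (max(x) + min(x)) / 2
  for (l in seq_len(n_iter)) {
    lo <- x[x <= th]; hi <- x[x > th]
    m_lo <- if (length(lo)) mean(lo) else th
    m_hi <- if (length(hi)) mean(hi) else th
    th <- w * m_lo + (1 - w) * m_hi
  }
  th
}

# build a gait_events object directly from prescribed event times
fake_events <- function(t_ic, t_fc, t_hr, t_to, ts = 1 / 110,
                        foot_side = "left") {
  m <- length(t_ic) - 1L
  strides <- data.frame(
    stride = seq_len(m),
    t_ic = t_ic[seq_len(m)], t_fc = t_fc[seq_len(m)],
    t_rest = (t_fc[seq_len(m)] + t_hr[seq_len(m)]) / 2,
    t_hr = t_hr[seq_len(m)], t_to = t_to[seq_len(m)],
    t_ic_next = t_ic[seq_len(m) + 1L], valid = TRUE)
  structure(list(strides = strides, foot_side = foot_side, ts = ts,
                 rest = integer(0), a_th = NA_real_, omega_th = NA_real_,
                 warnings = character(0)), class = "gait_events")
}

# periodic two-foot event tables: stance fraction s, stride time tt,
# contralateral shift as fraction of the stride
fake_cycle_pair <- function(n = 10, tt = 1, s = 0.6, shift = 0.5,
                            fc_frac = 0.12, hr_frac = 0.4) {
  mk <- function(off) {
    ic <- off + (0:n) * tt
    fake_events(t_ic = ic, t_fc = ic[seq_len(n)] + fc_frac * tt,
                t_hr = ic[seq_len(n)] + hr_frac * tt,
                t_to = ic[seq_len(n)] + s * tt)
  }
  # start the contralateral cycle one stride early so that every ipsilateral
  # stride has contralateral events inside it
  list(ipsi = mk(0), contra = mk((shift - 1) * tt))
}

# median detected-minus-true offset in samples, aligning by nearest event
event_offset_samples <- function(detected, truth, ts) {
  nearest <- vapply(detected, function(v) truth[which.min(abs(truth - v))],
                    numeric(1))
  stats::median((detected - nearest) / ts)
}

# fraction of [t0, t1] covered by segments with a given label
label_fraction_within <- function(sp, label, t0, t1) {
  seg <- sp$segments[sp$segments$label == label, , drop = FALSE]
  covered <- sum(pmax(0, pmin(seg$t_end, t1) - pmax(seg$t_start, t0)))
  covered / (t1 - t0)
}

rotate_recording <- function(rec, rotmat) {
  imu_recording(rec$gyr %*% t(rotmat), rec$acc %*% t(rotmat), rec$ts,
                rec$foot_side, rec$start_time_offset)
}

random_rotation_matrix <- function() {
  q <- imugait:::quat_normalize(stats::rnorm(4))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
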