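#' Algorithm configuration
#'
#' Tuning parameters of the gait-analysis pipeline. The defaults are the
#' single parameter set used for all gait styles and speeds; they are not
#' velocity-specific because the detection thresholds themselves are adapted
#' automatically per trial (see [auto_threshold()]).
#'
#' @param h_a hysteresis factor for the acceleration-based rest signal.
#' @param h_omega hysteresis factor for the angular-rate-based rest signal.
#' @param w_a weighting factor for the acceleration threshold auto-tuning.
#' @param a_th_min lower bound for the acceleration threshold, m/s^2.
#' @param w_omega weighting factor for the angular-rate threshold auto-tuning.
#' @param omega_th_min lower bound for the angular-rate threshold, rad/s.
#' @param t0_min minimum duration of a zero-phase (rest), seconds.
#' @param t1_min minimum duration of a one-phase (motion), seconds.
#' @param j_win ratio defining the start of the initial-contact search window
#'   between the previous toe-off and the upcoming full contact, in \[0, 1\].
#' @param j_th jerk-norm threshold relative to the window maximum, in (0, 1\].
#' @param t_a window length of the zero-phase moving-average filter used for
#'   the gravity reference, seconds.
#' @param n_threshold_iterations iterations of the threshold adaptation.
#' @param n_exclude_strides number of strides dropped at the beginning and at
#'   the end of each foot's stride sequence when averaging over a trial.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(h_a = 0.23,
                        h_omega = 0.23,
                        w_a = 0.85,
                        a_th_min = 1.8,
                        w_omega = 0.8,
                        omega_th_min = 0,
                        t0_min = 0.120,
                        t1_min = 0.180,
                        j_win = 0.7,
                        j_th = 0.95,
                        t_a = 8.0,
                        n_threshold_iterations = 200L,
                        n_exclude_strides = 3L) {
  cfg <- list(h_a = h_a, h_omega = h_omega, w_a = w_a, a_th_min = a_th_min,
              w_omega = w_omega, omega_th_min = omega_th_min,
              t0_min = t0_min, t1_min = t1_min, j_win = j_win, j_th = j_th,
              t_a = t_a,
              n_threshold_iterations = as.integer(n_threshold_iterations),
              n_exclude_strides = as.integer(n_exclude_strides))
  stopifnot(cfg$h_a >= 0, cfg$h_a < 1, cfg$h_omega >= 0, cfg$h_omega < 1,
            cfg$w_a > 0, cfg$w_a < 1, cfg$w_omega > 0, cfg$w_omega < 1,
            cfg$a_th_min >= 0, cfg$omega_th_min >= 0,
            cfg$t0_min >= 0, cfg$t1_min >= 0,
            cfg$j_win >= 0, cfg$j_win <= 1, cfg$j_th > 0, cfg$j_th <= 1,
            cfg$t_a > 0, cfg$n_threshold_iterations >= 1,
            cfg$n_exclude_strides >= 0)
  class(cfg) <- "gait_config"
  cfg
}

#' @export
print.gait_config <- function(x, ...) {
  cat("Gait analysis configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_gait_config <- function(cfg) {
  if (is.null(cfg)) return(gait_config())
  if (inherits(cfg, "gait_config")) return(cfg)
  if (is.list(cfg)) return(do.call(gait_config, cfg))
  stop("cfg must be a gait_config or a list of overrides")
}
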