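summary_fields <- c("stance_pct", "swing_pct", "loading_response_pct",
                    "single_limb_support_pct", "mid_stance_pct",
                    "terminal_stance_pct", "pre_swing_pct",
                    "stride_length_cm", "walking_speed_kmh",
                    "cadence_steps_per_min")

# Assemble the per-stride parameter table of one foot from its timing,
# bilateral-phase and spatial tables (reporting units).
stride_table <- function(timings, bilateral, spatial) {
  tab <- merge(timings, bilateral, by = "stride", suffixes = c("", ".b"))
  tab <- merge(tab, spatial, by = "stride", all.x = TRUE)
  tab <- tab[order(tab$stride), ]
  data.frame(
    stride = tab$stride,
    t_ic = tab$t_ic,
    stance_pct = 100 * tab$stance_rel,
    swing_pct = 100 * tab$swing_rel,
    loading_response_pct = 100 * tab$lr_rel,
    single_limb_support_pct = 100 * tab$sls_rel,
    mid_stance_pct = 100 * tab$ms_rel,
    terminal_stance_pct = 100 * tab$ts_rel,
    pre_swing_pct = 100 * tab$ps_rel,
    stride_length_cm = 100 * tab$length_m,
    walking_speed_kmh = 3.6 * tab$speed_ms,
    cadence_steps_per_min = tab$cadence,
    atypical = tab$atypical,
    row.names = NULL)
}

#' Summarize a trial
#'
#' Averages the per-stride parameters of both feet after discarding the
#' first and last `n_exclude_strides` strides of each foot (gait is not
#' steady while starting and stopping). If a foot has too few strides for
#' the exclusion to leave any, all its strides are used and a warning is
#' recorded. The combined summary pools the retained strides of both feet.
#'
#' @param strides_left,strides_right per-stride parameter tables (as stored
#'   in a [gait_analysis()] object, one row per valid stride).
#' @param cfg a [gait_config()]; only `n_exclude_strides` is used.
#' @return A list of class `trial_summary` with elements `left`, `right`,
#'   `combined` (named numeric vectors over the reported parameters),
#'   `n_strides_used`, `n_strides_excluded` and `warnings`.
#' @export
summarize_trial <- function(strides_left, strides_right, cfg = gait_config()) {
  cfg <- as_gait_config(cfg)
  n_ex <- cfg$n_exclude_strides
  warnings <- character(0)
  trim <- function(tab, side) {
    n <- nrow(tab)
    if (n == 0L) stop("zero valid strides for the ", side, " foot")
    if (n > 2L * n_ex) {
      tab[(n_ex + 1L):(n - n_ex), , drop = FALSE]
    } else {
      warnings <<- c(warnings, sprintf(
        "%s foot: only %d strides; boundary-stride exclusion skipped", side, n))
      tab
    }
  }
  l <- trim(strides_left, "left")
  r <- trim(strides_right, "right")
  col_means <- function(tab) {
    vapply(summary_fields, function(f)
      if (f %in% names(tab)) mean(tab[[f]], na.rm = TRUE) else NA_real_,
      numeric(1))
  }
  structure(list(
    left = col_means(l),
    right = col_means(r),
    combined = col_means(rbind(l[intersect(names(l), names(r))],
                               r[intersect(names(l), names(r))])),
    n_strides_used = c(left = nrow(l), right = nrow(r)),
    n_strides_excluded = c(left = nrow(strides_left) - nrow(l),
                           right = nrow(strides_right) - nrow(r)),
    warnings = warnings), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial summary (%d + %d strides used, %d + %d excluded):\n",
              x$n_strides_used["left"], x$n_strides_used["right"],
              x$n_strides_excluded["left"], x$n_strides_excluded["right"]))
  m <- rbind(left = x$left, right = x$right, combined = x$combined)
  print(round(t(m), 2))
  invisible(x)
}

#' Compare trial summaries to reference values
#'
#' Computes, per parameter, the mean absolute difference (MAD) and the mean
#' and standard deviation (n-1 normalization) of the signed differences
#' between estimated and reference values over a set of trials. This is the
#' agreement measure used when validating against an instrumented treadmill
#' or another reference system.
#'
#' @param estimated,reference data frames with one row per trial, a `trial`
#'   identifier column and matching parameter columns.
#' @return Data frame with columns `parameter`, `mad`, `mean_diff`,
#'   `sd_diff`, `n`.
#' @export
compare_to_reference <- function(estimated, reference) {
  if (!"trial" %in% names(estimated) || !"trial" %in% names(reference))
    stop("both tables need a 'trial' column")
  missing_tr <- setdiff(estimated$trial, reference$trial)
  if (length(missing_tr) > 0L)
    stop("trials missing from reference: ", paste(missing_tr, collapse = ", "))
  m <- merge(estimated, reference, by = "trial", suffixes = c(".est", ".ref"))
  params <- intersect(setdiff(names(estimated), "trial"),
                      setdiff(names(reference), "trial"))
  if (length(params) == 0L) stop("no common parameter columns")
  rows <- lapply(params, function(p) {
    d <- m[[paste0(p, ".est")]] - m[[paste0(p, ".ref")]]
    d <- d[is.finite(d)]
    data.frame(parameter = p, mad = mean(abs(d)), mean_diff = mean(d),
               sd_diff = stats::sd(d), n = length(d))
  })
  do.call(rbind, rows)
}
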