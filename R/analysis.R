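#' Analyze a two-foot IMU walking trial
#'
#' Runs the complete calibration-free gait-analysis pipeline on the raw
#' recordings of two foot-worn IMUs: per-foot gait-event detection
#' ([detect_gait_events()]), orientation estimation
#' ([estimate_orientation()]), per-stride zero-velocity-anchored double
#' integration for stride length and walking speed, bilateral gait phases
#' ([bilateral_phases()]), support phases ([support_phases()]) and the trial
#' summary ([summarize_trial()]). No assumption is made about how either
#' sensor is oriented on its foot, and no magnetometer is used.
#'
#' With only one recording (`right = NULL`), stance/swing, cadence and the
#' spatial parameters are still computed for that foot — they need no
#' contralateral events — but the bilateral phases (loading response, single
#' limb support, mid-stance, terminal stance, pre-swing) and support phases
#' are omitted with a warning.
#'
#' @param left an [imu_recording()] (or the `left` element name of a
#'   `gait_simulation`); both recordings must share a common time origin,
#'   up to their `start_time_offset`s.
#' @param right an [imu_recording()] or `NULL`.
#' @param config a [gait_config()] or a list of overrides.
#' @return An object of class `gait_analysis` with elements `strides`
#'   (named list of per-foot per-stride parameter tables), `summary` (a
#'   `trial_summary`), `events`, `support`, `orientation` (per-foot
#'   `orientation_estimate`s), `config` and `warnings`.
#' @examples
#' sim <- simulate_gait(gait_profile(duration = 30), seed = 1)
#' fit <- gait_analysis(sim$left, sim$right)
#' summary(fit)
#' coef(fit)
#' @export
gait_analysis <- function(left, right = NULL, config = gait_config()) {
  cfg <- as_gait_config(config)
  if (inherits(left, "gait_simulation")) {
    right <- left$right
    left <- left$left
  }
  stopifnot(inherits(left, "imu_recording"))
  warnings <- character(0)

  analyze_foot <- function(rec) {
    ev <- detect_gait_events(rec, cfg)
    or <- estimate_orientation(rec, ev$rest, cfg)
    spatial <- stride_spatial_params(rec, ev, or$q)
    timings <- stride_timings(ev)
    list(events = ev, orientation = or, spatial = spatial, timings = timings)
  }
  fl <- analyze_foot(left)
  warnings <- c(warnings, fl$events$warnings, fl$orientation$warnings)

  if (is.null(right)) {
    warnings <- c(warnings,
                  "single-foot analysis: bilateral gait phases and support phases omitted")
    bil_l <- data.frame(stride = fl$timings$stride,
                        lr_rel = NA_real_, ms_rel = NA_real_, ts_rel = NA_real_,
                        sls_rel = NA_real_, ps_rel = NA_real_,
                        swing_rel = fl$timings$swing_rel,
                        stance_rel = fl$timings$stance_rel,
                        atypical = FALSE, bilateral = FALSE)
    strides_l <- stride_table(fl$timings, bil_l, fl$spatial)
    summ <- summarize_trial(strides_l, strides_l, cfg)
    summ$right <- summ$right * NA_real_
    summ$combined <- summ$left
    warnings <- c(warnings, summ$warnings)
    return(structure(list(
      strides = list(left = strides_l, right = NULL),
      summary = summ, events = list(left = fl$events, right = NULL),
      support = NULL,
      orientation = list(left = fl$orientation, right = NULL),
      config = cfg, warnings = warnings), class = "gait_analysis"))
  }

  stopifnot(inherits(right, "imu_recording"))
  fr <- analyze_foot(right)
  warnings <- c(warnings, fr$events$warnings, fr$orientation$warnings)

  bil_l <- bilateral_phases(fl$events, fr$events)
  bil_r <- bilateral_phases(fr$events, fl$events)
  if (any(bil_l$atypical) || any(bil_r$atypical))
    warnings <- c(warnings, sprintf(
      "atypical bilateral event ordering in %d left / %d right stride(s); mid-stance/terminal-stance split unavailable there",
      sum(bil_l$atypical), sum(bil_r$atypical)))
  support <- support_phases(fl$events, fr$events)

  strides_l <- stride_table(fl$timings, bil_l, fl$spatial)
  strides_r <- stride_table(fr$timings, bil_r, fr$spatial)
  summ <- summarize_trial(strides_l, strides_r, cfg)
  warnings <- c(warnings, summ$warnings)

  structure(list(
    strides = list(left = strides_l, right = strides_r),
    summary = summ,
    events = list(left = fl$events, right = fr$events),
    support = support,
    orientation = list(left = fl$orientation, right = fr$orientation),
    config = cfg, warnings = warnings), class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Calibration-free IMU gait analysis\n")
  n_l <- nrow(x$strides$left)
  n_r <- if (is.null(x$strides$right)) 0L else nrow(x$strides$right)
  cat(sprintf("  strides: %d left, %d right; %d warning(s)\n",
              n_l, n_r, length(x$warnings)))
  cmb <- x$summary$combined
  cat(sprintf("  stance %.1f %% / swing %.1f %%, stride length %.1f cm, speed %.2f km/h, cadence %.1f steps/min\n",
              cmb["stance_pct"], cmb["swing_pct"], cmb["stride_length_cm"],
              cmb["walking_speed_kmh"], cmb["cadence_steps_per_min"]))
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  print(object$summary)
  if (!is.null(object$support)) {
    cat("Support phases (fraction of analyzed interval):\n")
    print(round(object$support$fractions, 4))
  }
  if (length(object$warnings) > 0L) {
    cat("Warnings:\n")
    cat(paste0("  - ", object$warnings, collapse = "\n"), "\n")
  }
  invisible(object$summary)
}

#' @export
coef.gait_analysis <- function(object, which = c("combined", "left", "right"),
                               ...) {
  which <- match.arg(which)
  object$summary[[which]]
}

#' Plot method for gait analyses
#'
#' Plots the per-stride parameter trajectories of both feet (stride length,
#' walking speed, cadence and stance percentage against stride index), a
#' quick visual check for outlier strides and left/right asymmetry.
#'
#' @param x a `gait_analysis` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gait_analysis <- function(x, ...) {
  params <- c("stride_length_cm", "walking_speed_kmh",
              "cadence_steps_per_min", "stance_pct")
  labels <- c("stride length [cm]", "walking speed [km/h]",
              "cadence [steps/min]", "stance [%]")
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (i in seq_along(params)) {
    l <- x$strides$left[[params[i]]]
    r <- if (is.null(x$strides$right)) numeric(0) else x$strides$right[[params[i]]]
    ylim <- range(c(l, r), na.rm = TRUE)
    graphics::plot(x$strides$left$stride, l, type = "b", col = "tomato3",
                   xlab = "stride", ylab = labels[i], ylim = ylim, ...)
    if (length(r) > 0L)
      graphics::lines(x$strides$right$stride, r, type = "b", col = "steelblue4")
  }
  invisible(x)
}

#' Write a gait report
#'
#' Serializes a [gait_analysis()] to a JSON document: configuration,
#' per-stride tables for both feet, per-foot and combined trial means,
#' support-phase fractions, provenance and warnings. Numbers are written at
#' full precision so [read_report()] restores them losslessly.
#'
#' @param fit a `gait_analysis` object.
#' @param path output path.
#' @param inputs optional character vector identifying the input files.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, inputs = NULL) {
  stopifnot(inherits(fit, "gait_analysis"))
  warn <- fit$warnings
  if (sum(nrow(fit$strides$left), nrow(fit$strides$right)) == 0L)
    warn <- c(warn, "report contains zero strides")
  doc <- list(
    software = paste0("imugait ", as.character(utils::packageVersion("imugait"))),
    inputs = inputs,
    config = unclass(fit$config),
    summary = list(left = as.list(fit$summary$left),
                   right = as.list(fit$summary$right),
                   combined = as.list(fit$summary$combined),
                   n_strides_used = as.list(fit$summary$n_strides_used),
                   n_strides_excluded = as.list(fit$summary$n_strides_excluded)),
    support_fractions = if (is.null(fit$support)) NULL else
      as.list(fit$support$fractions),
    strides = list(left = fit$strides$left, right = fit$strides$right),
    warnings = warn)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a gait report
#'
#' @param path a JSON report written by [write_report()].
#' @return A list with the report contents; the per-stride tables are
#'   restored as data frames.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (side in c("left", "right"))
    if (!is.null(doc$strides[[side]]))
      doc$strides[[side]] <- as.data.frame(doc$strides[[side]])
  for (slot in c("left", "right", "combined"))
    doc$summary[[slot]] <- unlist(doc$summary[[slot]])
  doc
}

#' Export the per-stride table as CSV
#'
#' @param fit a `gait_analysis` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stride_csv <- function(fit, path) {
  tabs <- list()
  for (side in c("left", "right")) {
    if (is.null(fit$strides[[side]])) next
    tab <- fit$strides[[side]]
    tab$foot <- side
    tabs[[side]] <- tab
  }
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
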