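# Per-trial derivation: acquisition metrics (%Valid Data, Cal Error) and
# ROI dwell-proportion variables (%Face, %Activity, %Body, %Social, %Bio).
#
# Definitions. A sample is *valid* when it is tracked and lands on screen
# (off-screen-but-tracked samples are treated as not acquired on-stimulus).
# %Valid Data is valid time over stimulus presentation time. Every ROI
# percentage uses valid time as its denominator, except %Bio which is
# bio / (bio + control) and is undefined when neither panel was looked at.
# There is no fixation detection: all metrics are sample-based dwell
# proportions.

#' Compute derived metrics for one trial
#'
#' @param samples data.frame with t_ms, x_px, y_px, tracked_flag
#' @param rois ROI data.frame for this trial's task/day
#' @param trial_duration_ms stimulus presentation time (> 0)
#' @param screen list(width_px, height_px)
#' @param affective whether the trial carries affective content (propagated
#'   to the %BioAffect aggregation)
#' @return one-row data.frame of TrialDerived fields
#' @export
compute_trial_metrics <- function(samples, rois, trial_duration_ms,
                                  screen = list(width_px = 1920L,
                                                height_px = 1200L),
                                  affective = FALSE) {
  stopifnot(trial_duration_ms > 0)
  dt <- trial_duration_ms / max(nrow(samples), 1L)
  tracked <- samples$tracked_flag > 0
  on_screen <- tracked & !is.na(samples$x_px) & !is.na(samples$y_px) &
    samples$x_px >= 0 & samples$x_px < screen$width_px &
    samples$y_px >= 0 & samples$y_px < screen$height_px
  n_valid <- sum(on_screen)
  pct_valid <- 100 * n_valid * dt / trial_duration_ms
  lab <- rep(NA_character_, nrow(samples))
  lab[on_screen] <- assign_sample_to_roi(samples$x_px[on_screen],
                                         samples$y_px[on_screen],
                                         samples$t_ms[on_screen],
                                         rois, screen)
  pct <- function(l) if (n_valid > 0) 100 * sum(lab == l, na.rm = TRUE) /
    n_valid else NA_real_
  bio_ms <- sum(lab == "bio", na.rm = TRUE) * dt
  ctl_ms <- sum(lab == "control", na.rm = TRUE) * dt
  data.frame(
    pct_valid_data = pct_valid,
    pct_face = pct("face"),
    pct_body = pct("body"),
    pct_activity = pct("activity"),
    pct_social = pct("face") + pct("body") + pct("activity"),
    bio_ms = bio_ms, control_ms = ctl_ms,
    pct_bio = if (bio_ms + ctl_ms > 0) 100 * bio_ms / (bio_ms + ctl_ms)
              else NA_real_,
    affective = affective
  )
}

#' Estimate calibration error from validation events
#'
#' Median over events of the median angular distance between tracked gaze
#' and the known target position during the event window, converted to
#' visual degrees.
#'
#' @param samples data.frame with t_ms, x_px, y_px, tracked_flag
#' @param validation_events list of `list(t_window = c(start, end),
#'   target_px = c(x, y))`
#' @param px_per_degree pixels per visual degree
#' @return calibration error in degrees, or NA when no event had tracked
#'   samples
#' @export
estimate_cal_error <- function(samples, validation_events,
                               px_per_degree = 42) {
  per_event <- vapply(validation_events, function(ev) {
    sel <- samples$t_ms >= ev$t_window[1] & samples$t_ms < ev$t_window[2] &
      samples$tracked_flag > 0 & !is.na(samples$x_px)
    if (!any(sel)) return(NA_real_)
    stats::median(sqrt((samples$x_px[sel] - ev$target_px[1])^2 +
                         (samples$y_px[sel] - ev$target_px[2])^2))
  }, numeric(1))
  if (all(is.na(per_event))) return(NA_real_)
  stats::median(per_event, na.rm = TRUE) / px_per_degree
}

#' Derive per-trial metrics for a whole gaze table
#'
#' Vectorised batch version of [compute_trial_metrics()] +
#' [estimate_cal_error()] + the PLR metrics, driven by the gaze CSV alone.
#' Validation-target events (task `VAL`) provide one calibration-error
#' estimate per participant-timepoint-day session, attached to every trial
#' of that session; targets follow [validation_layout()]. PLR trials
#' additionally get latency, constriction and PLR-specific validity.
#'
#' @param gaze gaze sample table (see [read_gaze_table()])
#' @param roi_sets named list of ROI tables (default [default_rois()])
#' @param screen list(width_px, height_px, px_per_degree)
#' @param flash_ms PLR flash onset within a trial
#' @return data.table, one row per trial (TrialDerived)
#' @export
derive_trials <- function(gaze, roi_sets = NULL,
                          screen = list(width_px = 1920L, height_px = 1200L,
                                        px_per_degree = 42),
                          flash_ms = 500) {
  gz <- data.table::as.data.table(gaze)
  if (is.null(roi_sets)) roi_sets <- default_rois(screen)
  W <- screen$width_px; H <- screen$height_px

  gz[, valid := tracked_flag > 0 & !is.na(x_px) & !is.na(y_px) &
       x_px >= 0 & x_px < W & y_px >= 0 & y_px < H]
  gz[, roi := NA_character_]
  for (task_i in setdiff(unique(gz$task), c("VAL"))) {
    for (d in unique(gz$day[gz$task == task_i])) {
      sel <- which(gz$task == task_i & gz$day == d & gz$valid)
      if (!length(sel)) next
      rois <- rois_for(roi_sets, task_i, d)
      if (is.null(rois)) next
      gz[sel, roi := assign_sample_to_roi(x_px, y_px, t_ms, rois, screen)]
    }
  }

  keys <- c("participant_id", "group", "timepoint", "day", "task", "trial")
  trials <- gz[task != "VAL", {
    n <- .N
    nv <- sum(valid)
    bio_n <- sum(roi == "bio", na.rm = TRUE)
    ctl_n <- sum(roi == "control", na.rm = TRUE)
    dt <- (max(t_ms) - min(t_ms)) / max(n - 1L, 1L)
    dur <- n * dt
    pf <- if (nv > 0) 100 * sum(roi == "face", na.rm = TRUE) / nv else NA_real_
    pb <- if (nv > 0) 100 * sum(roi == "body", na.rm = TRUE) / nv else NA_real_
    pa <- if (nv > 0) 100 * sum(roi == "activity", na.rm = TRUE) / nv else NA_real_
    list(n_samples = n,
         duration_ms = dur,
         pct_valid_data = 100 * nv / n,
         pct_face = pf, pct_body = pb, pct_activity = pa,
         pct_social = pf + pb + pa,
         bio_ms = bio_n * dt, control_ms = ctl_n * dt,
         pct_bio = if (bio_n + ctl_n > 0) 100 * bio_n / (bio_n + ctl_n)
                   else NA_real_)
  }, by = keys]

  # session-level calibration error from validation events
  lay <- validation_layout(screen)
  val <- gz[task == "VAL" & tracked_flag > 0 & !is.na(x_px)]
  if (nrow(val)) {
    val[, `:=`(tx = lay$x_px[(trial - 1L) %% 5L + 1L],
               ty = lay$y_px[(trial - 1L) %% 5L + 1L])]
    ev <- val[, list(err_px = stats::median(sqrt((x_px - tx)^2 +
                                                   (y_px - ty)^2))),
              by = c("participant_id", "timepoint", "day", "trial")]
    ses <- ev[, list(cal_error_deg = stats::median(err_px) /
                       screen$px_per_degree),
              by = c("participant_id", "timepoint", "day")]
    trials <- merge(trials, ses,
                    by = c("participant_id", "timepoint", "day"),
                    all.x = TRUE, sort = FALSE)
  } else {
    trials[, cal_error_deg := NA_real_]
  }

  # biomotion affective flag: protocol convention, every fifth trial
  trials[, affective := task == "BM" & (trial - 1L) %% 5L == 0L]

  # PLR metrics
  trials[, `:=`(latency_ms = NA_real_, constriction = NA_real_,
                plr_ok = NA)]
  plr <- gz[task == "PLR"]
  if (nrow(plr)) {
    pm <- plr[, {
      m <- plr_metrics_from_samples(t_ms, ifelse(tracked_flag > 0,
                                                 pupil_au, NA_real_),
                                    flash_ms)
      list(latency_ms = m$latency_ms, constriction = m$constriction,
           plr_ok = m$plr_ok)
    }, by = keys]
    trials[pm, on = keys, `:=`(latency_ms = i.latency_ms,
                               constriction = i.constriction,
                               plr_ok = i.plr_ok)]
  }
  data.table::setkeyv(trials, keys[c(1, 3, 4, 5, 6)])
  trials[]
}
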