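# Quality-control gating and participant-level aggregation.
#
# Gating rules (all boundaries inclusive): a trial is valid when
# %Valid Data >= 50 and Cal Error <= 2.5 degrees (PLR trials must also pass
# the PLR-specific checks); a whole session (participant-timepoint-day) can
# be administratively invalidated; a task at a timepoint is valid when at
# least 25% of its administered trials are valid; the face composite is
# valid only when all three constituent tasks are valid. %Valid Trials uses
# administered trials as denominator, so session-invalidated trials count
# as invalid, and Cal Error is aggregated over all trials with an estimate
# (it is an acquisition metric, not a derived variable).

#' Trial-level validity
#'
#' @param trials TrialDerived table from [derive_trials()]
#' @param qc a [qc_config()]
#' @return logical vector (one per trial)
#' @export
trial_valid <- function(trials, qc = qc_config()) {
  ok <- !is.na(trials$pct_valid_data) &
    trials$pct_valid_data >= qc$valid_data_pct &
    !is.na(trials$cal_error_deg) &
    trials$cal_error_deg <= qc$cal_error_deg
  is_plr <- trials$task == "PLR"
  ok[is_plr] <- ok[is_plr] & !is.na(trials$plr_ok[is_plr]) &
    trials$plr_ok[is_plr]
  ok
}

#' Apply session-level invalidations
#'
#' Marks every trial of a flagged session (counterbalancing error, technical
#' malfunction, non-standardised cueing) invalid before aggregation. The
#' trials remain in the administered denominator.
#'
#' @param trials TrialDerived table with a `valid` column (added when
#'   missing via [trial_valid()])
#' @param sessions data.frame with participant_id, timepoint, day,
#'   session_invalid
#' @param qc a [qc_config()]
#' @return the trial table with `valid` and `session_invalid` columns
#' @export
apply_session_invalidations <- function(trials, sessions = NULL,
                                        qc = qc_config()) {
  tr <- data.table::as.data.table(trials)
  if (!"valid" %in% names(tr)) tr[, valid := trial_valid(tr, qc)]
  tr[, session_invalid := FALSE]
  if (!is.null(sessions)) {
    ses <- data.table::as.data.table(sessions)
    flagged <- ses[session_invalid == TRUE]
    if (nrow(flagged)) {
      tr[flagged, on = c("participant_id", "timepoint", "day"),
         session_invalid := TRUE]
      tr[session_invalid == TRUE, valid := FALSE]
    }
  }
  tr[]
}

#' Summarise a task at a timepoint per participant
#'
#' Means of the derived variables over valid trials (both days pooled),
#' acquisition metrics over all administered trials, and the 25% task
#' validity rule. %Bio means skip trials where it is undefined; %BioAffect
#' is %Bio restricted to affective-flagged trials.
#'
#' @param trials gated trial table (see [apply_session_invalidations()])
#' @param qc a [qc_config()]
#' @return data.table, one row per participant x timepoint x task
#' @export
summarize_task <- function(trials, qc = qc_config()) {
  tr <- data.table::as.data.table(trials)
  if (!"valid" %in% names(tr)) tr <- apply_session_invalidations(tr, NULL, qc)
  mean_valid <- function(x, v) {
    x <- x[v & !is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  out <- tr[, {
    n_total <- .N
    n_valid <- sum(valid)
    pvt <- 100 * n_valid / n_total
    list(
      n_total_trials = n_total,
      n_valid_trials = n_valid,
      pct_valid_trials = pvt,
      mean_pct_valid_data = mean(pct_valid_data, na.rm = TRUE),
      mean_cal_error_deg = if (all(is.na(cal_error_deg))) NA_real_
                           else mean(cal_error_deg, na.rm = TRUE),
      pct_face = mean_valid(pct_face, valid),
      pct_body = mean_valid(pct_body, valid),
      pct_activity = mean_valid(pct_activity, valid),
      pct_social = mean_valid(pct_social, valid),
      pct_bio = mean_valid(pct_bio, valid),
      pct_bio_affect = mean_valid(ifelse(affective, pct_bio, NA_real_),
                                  valid),
      latency_ms = mean_valid(latency_ms, valid),
      constriction = mean_valid(constriction, valid),
      task_valid = n_total > 0 && pvt >= qc$valid_trials_pct
    )
  }, by = c("participant_id", "group", "timepoint", "task")]
  data.table::setkeyv(out, c("participant_id", "timepoint", "task"))
  out[]
}

#' Compute the gaze-to-faces composite (OMI)
#'
#' Equal-weight average of %Face from the AM, SI and SS tasks at a
#' timepoint. Valid only when all three constituent tasks are valid; the
#' value is absent otherwise.
#'
#' @param summaries output of [summarize_task()]
#' @return data.table: participant_id, group, timepoint, omi, omi_valid
#' @export
compute_omi <- function(summaries) {
  sm <- data.table::as.data.table(summaries)
  sub <- sm[task %in% TASKS_FACE]
  out <- sub[, {
    ok <- .N == 3L && all(task_valid) && !anyNA(pct_face)
    list(omi = if (ok) mean(pct_face) else NA_real_, omi_valid = ok)
  }, by = c("participant_id", "group", "timepoint")]
  data.table::setkeyv(out, c("participant_id", "timepoint"))
  out[]
}

#' Acquisition and validity report
#'
#' Per group x task rates of data acquisition (any valid samples acquired)
#' and data validity (all QC criteria passed), mean acquisition metrics,
#' the 70% suitability benchmark, and chi-square tests (without continuity
#' correction or Monte-Carlo) for group and site differences in validity
#' rates. OMI is reported as its own pseudo-task.
#'
#' @param summaries output of [summarize_task()]
#' @param omi output of [compute_omi()]
#' @param clinical table with participant_id and site
#' @param tp which timepoint to report (default 1)
#' @param qc a [qc_config()]
#' @return list with `rates` (data.table) and `tests` (data.table)
#' @export
acquisition_report <- function(summaries, omi, clinical, tp = 1L,
                               qc = qc_config()) {
  sm <- data.table::as.data.table(summaries)[timepoint == tp]
  om <- data.table::as.data.table(omi)[timepoint == tp]
  cl <- data.table::as.data.table(clinical)
  sm <- merge(sm, cl[, c("participant_id", "site")], by = "participant_id",
              sort = FALSE)
  om <- merge(om, cl[, c("participant_id", "site")], by = "participant_id",
              sort = FALSE)
  rates <- sm[, list(
    n = .N,
    acquisition_valid_pct = 100 * mean(mean_pct_valid_data > 0,
                                       na.rm = TRUE),
    signal_valid_pct = 100 * mean(task_valid),
    mean_pct_valid_trials = mean(pct_valid_trials),
    mean_pct_valid_data = mean(mean_pct_valid_data, na.rm = TRUE),
    mean_cal_error_deg = mean(mean_cal_error_deg, na.rm = TRUE)
  ), by = c("group", "task")]
  omir <- om[, list(n = .N,
                    acquisition_valid_pct = 100 * mean(!is.na(omi) |
                                                         omi_valid),
                    signal_valid_pct = 100 * mean(omi_valid),
                    mean_pct_valid_trials = NA_real_,
                    mean_pct_valid_data = NA_real_,
                    mean_cal_error_deg = NA_real_),
             by = "group"]
  omir[, task := "OMI"]
  rates <- rbind(rates, omir, use.names = TRUE)
  rates[, benchmark_pass := signal_valid_pct > qc$benchmark_pct]
  data.table::setorderv(rates, c("task", "group"))

  tests <- sm[, {
    v <- task_valid
    grp_p <- chisq_or_na(table(group, v))
    site_tabs <- lapply(unique(group), function(g)
      table(site[group == g], v[group == g]))
    names(site_tabs) <- unique(group)
    res <- lapply(names(site_tabs), function(g) chisq_or_na(site_tabs[[g]]))
    list(test = c("group", paste0("site_", names(site_tabs))),
         statistic = c(grp_p$stat,
                       vapply(res, function(r) r$stat, numeric(1))),
         df = c(grp_p$df, vapply(res, function(r) r$df, numeric(1))),
         p_value = c(grp_p$p, vapply(res, function(r) r$p, numeric(1))))
  }, by = "task"]
  list(rates = rates[], tests = tests[])
}

# chi-square without continuity correction; NA when degenerate (e.g. 100%
# validity everywhere). Warns on small expected counts instead of
# simulating.
chisq_or_na <- function(tab) {
  if (any(dim(tab) < 2L) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(stat = NA_real_, df = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("chi-square with expected counts < 5; interpret with caution")
  list(stat = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
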