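# File formats, the participant-level biomarker table, the psychometric
# report, and end-to-end orchestration. All interchange formats are plain
# text: CSV for tables, JSON for configuration and ROIs. Units: ms, px,
# degrees; proportions as percentages 0-100 except PLR constriction, which
# stays a fraction of baseline.

GAZE_COLUMNS <- c("participant_id", "group", "timepoint", "day", "task",
                  "trial", "t_ms", "x_px", "y_px", "pupil_au",
                  "tracked_flag")

#' Read and validate a gaze sample table
#'
#' Checks the required columns, coerces types, drops malformed rows
#' (non-finite time, unknown task, missing ids) with a reported count, and
#' sorts by (participant, timepoint, day, task, trial, t).
#'
#' @param path CSV file path
#' @return data.table of gaze samples; attribute `n_malformed` carries the
#'   dropped-row count
#' @export
read_gaze_table <- function(path) {
  if (!file.exists(path)) stop_config("gaze file not found: %s", path)
  gz <- data.table::fread(path)
  if (nrow(gz) == 0L) stop_config("gaze file is empty: %s", path)
  missing_cols <- setdiff(GAZE_COLUMNS, names(gz))
  if (length(missing_cols))
    stop_config("gaze table missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  num_cols <- c("timepoint", "day", "trial", "t_ms", "x_px", "y_px",
                "pupil_au", "tracked_flag")
  for (cl in num_cols)
    if (!is.numeric(gz[[cl]]))
      gz[, (cl) := suppressWarnings(as.numeric(get(cl)))]
  bad <- !is.finite(gz$t_ms) | is.na(gz$participant_id) |
    gz$participant_id == "" | is.na(gz$trial) |
    !gz$task %in% c("AM", "SI", "SS", "BM", "PLR", "VAL")
  n_bad <- sum(bad)
  if (n_bad) {
    message(sprintf("read_gaze_table: dropped %d malformed row(s)", n_bad))
    gz <- gz[!bad]
  }
  if (nrow(gz) == 0L) stop_config("no well-formed gaze rows in %s", path)
  data.table::setkeyv(gz, c("participant_id", "timepoint", "day", "task",
                            "trial", "t_ms"))
  data.table::setattr(gz, "n_malformed", n_bad)
  gz[]
}

#' Assemble the participant-level biomarker table
#'
#' One row per participant x timepoint with the composite, per-task primary
#' and secondary variables, their validity flags, the battery-wide %Valid
#' Data (mean of per-task means), and the clinical/demographic columns.
#'
#' @param summaries output of [summarize_task()]
#' @param omi output of [compute_omi()]
#' @param clinical clinical table
#' @return data.table keyed by (participant_id, timepoint)
#' @export
build_biomarker_table <- function(summaries, omi, clinical) {
  sm <- data.table::as.data.table(summaries)
  wide <- data.table::dcast(
    sm, participant_id + group + timepoint ~ task,
    value.var = c("pct_face", "pct_social", "pct_activity", "pct_bio",
                  "pct_bio_affect", "latency_ms", "constriction",
                  "task_valid", "pct_valid_trials"))
  keep <- c("participant_id", "group", "timepoint",
            "pct_face_AM", "pct_face_SI", "pct_face_SS",
            "pct_social_SI", "pct_social_SS", "pct_activity_AM",
            "pct_bio_BM", "pct_bio_affect_BM",
            "latency_ms_PLR", "constriction_PLR",
            "task_valid_AM", "task_valid_SI", "task_valid_SS",
            "task_valid_BM", "task_valid_PLR")
  wide <- wide[, intersect(keep, names(wide)), with = FALSE]
  pvd <- sm[, list(pct_valid_data = mean(mean_pct_valid_data,
                                         na.rm = TRUE)),
            by = c("participant_id", "timepoint")]
  out <- merge(wide, data.table::as.data.table(omi),
               by = c("participant_id", "group", "timepoint"))
  out <- merge(out, pvd, by = c("participant_id", "timepoint"))
  out <- merge(out, data.table::as.data.table(clinical),
               by = c("participant_id", "group"))
  data.table::setkeyv(out, c("participant_id", "timepoint"))
  out[]
}

# variables analysed by the battery: column stem -> validity column
battery_variables <- function() {
  data.frame(
    variable = c("omi", "pct_face_AM", "pct_face_SI", "pct_face_SS",
                 "pct_bio_BM", "latency_ms_PLR"),
    valid_col = c("omi_valid", "task_valid_AM", "task_valid_SI",
                  "task_valid_SS", "task_valid_BM", "task_valid_PLR"),
    label = c("OMI", "AM %Face", "SI %Face", "SS %Face", "BM %Bio",
              "PLR Latency"),
    stringsAsFactors = FALSE
  )
}

#' Run the full psychometric evaluation battery
#'
#' Construct validity in the TD group at T1 (one-sample tests against the
#' area-based chance levels; one-sided for constriction), six-week
#' stability ICCs per group with ASD age/IQ subgroups, HC3-robust group
#' discrimination at T1 (unadjusted and adjusted for age, IQ, site and
#' %Valid Data), and Spearman clinical correlations in the ASD group with
#' and without rank-based partialing for age, IQ and %Valid Data.
#'
#' @param bt biomarker table from [build_biomarker_table()]
#' @param chance_levels named chance levels for the construct tests
#'   (percent for the looking variables)
#' @param clinical_scores names of score columns (default: those present
#'   from the simulator's repertoire)
#' @return list of class `omi_psychometrics` with elements
#'   `construct_validity`, `stability`, `subgroups`, `discrimination`,
#'   `correlations`
#' @export
run_psychometrics <- function(bt,
                              chance_levels = c(pct_face_AM = 3.2,
                                                pct_face_SI = 8.3,
                                                pct_face_SS = 3.9,
                                                pct_bio_BM = 50,
                                                constriction_PLR = 0),
                              clinical_scores = NULL) {
  bt <- data.table::as.data.table(bt)
  vars <- battery_variables()
  if (is.null(clinical_scores))
    clinical_scores <- intersect(unique(default_clinical_scales()$score),
                                 names(bt))

  # --- construct validity (TD, T1) ------------------------------------
  td1 <- bt[group == "TD" & timepoint == 1L]
  cv <- data.table::rbindlist(lapply(names(chance_levels), function(v) {
    vc <- switch(v, constriction_PLR = "task_valid_PLR",
                 vars$valid_col[match(v, vars$variable)])
    if (is.na(vc) || !v %in% names(td1)) vc <- NULL
    vals <- td1[[v]]
    if (!is.null(vc)) vals <- vals[td1[[vc]] %in% TRUE]
    alt <- if (v == "constriction_PLR") "greater" else "two.sided"
    r <- one_sample_construct_test(vals, mu0 = chance_levels[[v]],
                                   alternative = alt)
    data.table::data.table(variable = v, mu0 = chance_levels[[v]],
                           n = r$n, m = r$m, sd = r$sd,
                           t = r$t, df = r$df, p = r$p, d = r$d)
  }))

  # --- six-week stability ---------------------------------------------
  wide <- stability_wide(bt)
  st <- list()
  for (g in unique(bt$group)) for (v in vars$variable) {
    w <- wide[wide$group == g, ]
    t1 <- w[[paste0(v, "_t1")]]; t2 <- w[[paste0(v, "_t2")]]
    if (sum(is.finite(t1) & is.finite(t2)) < 3) next
    ic <- icc_stability(t1, t2)
    st[[length(st) + 1L]] <- data.table::data.table(
      group = g, variable = v, icc = ic$icc_agreement,
      icc_consistency = ic$icc_consistency, n = ic$n, df = ic$df,
      band = ic$band)
  }
  stability <- data.table::rbindlist(st)
  subgroups <- subgroup_analyses(wide[wide$group == "ASD", ],
                                 vars$variable)

  # --- group discrimination (T1) --------------------------------------
  b1 <- bt[timepoint == 1L]
  disc <- data.table::rbindlist(lapply(seq_len(nrow(vars)), function(i) {
    v <- vars$variable[i]
    sel <- b1[[vars$valid_col[i]]] %in% TRUE & is.finite(b1[[v]])
    dat <- b1[sel]
    un <- group_discrimination(dat[[v]], dat$group)
    ad <- group_discrimination(dat[[v]], dat$group,
                               covariates = data.frame(
                                 age_years = dat$age_years, iq = dat$iq,
                                 site = factor(dat$site),
                                 pct_valid_data = dat$pct_valid_data))
    data.table::data.table(
      variable = v,
      m_asd = un$means[["ASD"]], sd_asd = un$sds[["ASD"]],
      m_td = un$means[["TD"]], sd_td = un$sds[["TD"]],
      F_unadj = un$F, df2_unadj = un$df2, p_unadj = un$p,
      d = un$d, eta_p2_unadj = un$eta_p2,
      F_adj = ad$F, df2_adj = ad$df2, p_adj = ad$p,
      eta_p2_adj = ad$eta_p2)
  }))

  # --- clinical correlations (ASD, T1) --------------------------------
  a1 <- bt[group == "ASD" & timepoint == 1L]
  biom <- vars$variable[vars$variable %in% names(a1)]
  correlations <- NULL
  if (length(clinical_scores)) {
    a1v <- data.table::copy(a1)
    for (i in seq_len(nrow(vars)))  # respect validity flags per variable
      a1v[!get(vars$valid_col[i]) %in% TRUE, (vars$variable[i]) := NA_real_]
    correlations <- list(
      plain = spearman_matrix(a1v, biom, clinical_scores),
      partial = spearman_matrix(a1v, biom, clinical_scores,
                                partial_covariates = c("age_years", "iq",
                                                       "pct_valid_data")))
  }

  structure(list(construct_validity = cv, stability = stability,
                 subgroups = subgroups, discrimination = disc,
                 correlations = correlations),
            class = "omi_psychometrics")
}

# wide (one row per participant) table with <var>_t1 / <var>_t2 columns,
# respecting validity flags
stability_wide <- function(bt) {
  bt <- data.table::as.data.table(bt)
  vars <- battery_variables()
  masked <- data.table::copy(bt)
  for (i in seq_len(nrow(vars))) {
    v <- vars$variable[i]
    masked[!get(vars$valid_col[i]) %in% TRUE, (v) := NA_real_]
  }
  data.table::dcast(masked, participant_id + group + age_years + iq ~
                      paste0("t", timepoint),
                    value.var = vars$variable, sep = "_")
}

#' Run the whole pipeline: simulate, derive, gate, evaluate, report
#'
#' Deterministic given the config (and its seed). Writes, under `outdir`:
#' the cohort CSVs, `rois.json`, `trials.csv`, `summaries.csv`, `omi.csv`,
#' `biomarkers.csv`, acquisition and psychometric report CSVs, and
#' `provenance.json` (config hash, package version, row counts per stage).
#'
#' @param config an [sim_config()]
#' @param outdir output directory
#' @param qc a [qc_config()]
#' @return invisibly, a list with all in-memory results
#' @export
run_pipeline <- function(config, outdir, qc = qc_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate", simulate_cohort(config))
  stage("write", write_cohort(cohort, outdir))
  roi_sets <- default_rois(config$screen, config$roi_area_frac)
  write_roi_json(roi_sets, file.path(outdir, "rois.json"))
  gaze <- stage("read", read_gaze_table(file.path(outdir, "gaze.csv")))
  trials <- stage("derive", derive_trials(gaze, roi_sets, config$screen,
                                          config$flash_ms))
  trials <- stage("qc", apply_session_invalidations(trials,
                                                    cohort$sessions, qc))
  data.table::fwrite(trials, file.path(outdir, "trials.csv"))
  summaries <- stage("qc", summarize_task(trials, qc))
  omi <- stage("qc", compute_omi(summaries))
  data.table::fwrite(summaries, file.path(outdir, "summaries.csv"))
  data.table::fwrite(omi, file.path(outdir, "omi.csv"))
  bt <- stage("qc", build_biomarker_table(summaries, omi, cohort$clinical))
  data.table::fwrite(bt, file.path(outdir, "biomarkers.csv"))
  acq <- stage("report", acquisition_report(summaries, omi,
                                            cohort$clinical, qc = qc))
  data.table::fwrite(acq$rates, file.path(outdir, "acquisition_rates.csv"))
  data.table::fwrite(acq$tests, file.path(outdir, "acquisition_tests.csv"))
  psy <- stage("psychometrics",
               run_psychometrics(bt,
                                 chance_levels = c(
                                   pct_face_AM = 100 * config$roi_area_frac[["AM"]],
                                   pct_face_SI = 100 * config$roi_area_frac[["SI"]],
                                   pct_face_SS = 100 * config$roi_area_frac[["SS"]],
                                   pct_bio_BM = 50,
                                   constriction_PLR = 0),
                                 clinical_scores =
                                   intersect(names(config$clinical_rho_targets),
                                             names(bt))))
  write_psychometrics(psy, outdir)
  prov <- list(
    package_version = as.character(utils::packageVersion("gazeomi")),
    config_md5 = unname(tools::md5sum(file.path(outdir, "config.json"))),
    seed = config$seed,
    rows = list(gaze = nrow(gaze), trials = nrow(trials),
                summaries = nrow(summaries), omi = nrow(omi),
                biomarkers = nrow(bt)))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, trials = trials, summaries = summaries,
                 omi = omi, biomarkers = bt, acquisition = acq,
                 psychometrics = psy))
}

write_psychometrics <- function(psy, outdir) {
  data.table::fwrite(psy$construct_validity,
                     file.path(outdir, "construct_validity.csv"))
  data.table::fwrite(psy$stability, file.path(outdir, "stability.csv"))
  if (nrow(psy$subgroups))
    data.table::fwrite(psy$subgroups, file.path(outdir, "subgroups.csv"))
  data.table::fwrite(psy$discrimination,
                     file.path(outdir, "discrimination.csv"))
  if (!is.null(psy$correlations)) {
    mat_to_dt <- function(m)
      data.table::data.table(variable = rownames(m),
                             data.table::as.data.table(m))
    data.table::fwrite(mat_to_dt(psy$correlations$plain$rho),
                       file.path(outdir, "correlations_rho.csv"))
    data.table::fwrite(mat_to_dt(psy$correlations$partial$rho),
                       file.path(outdir, "correlations_partial_rho.csv"))
  }
  invisible(outdir)
}
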