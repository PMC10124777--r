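# Shared fixtures, built in code.

# tiny but complete cohort configuration (all five tasks, both timepoints)
tiny_cfg <- function(n_asd = 2L, n_td = 2L, seed = 1L, ...) {
  sim_config(n_asd = n_asd, n_td = n_td, seed = seed,
             sample_rate = 10, plr_sample_rate = 50, ...)
}

# simple one-face-rect ROI set: face 200x100 at (100,100), activity
# 200x100 at (100, 400)
fixture_rois <- function() {
  data.frame(
    label = c("face", "activity"),
    shape = "rect",
    x0 = c(100, 100), y0 = c(100, 400),
    x1 = c(300, 300), y1 = c(300, 500),
    t_start_ms = 0, t_end_ms = Inf,
    affective = FALSE, stringsAsFactors = FALSE)
}

# hand-built trial rows for QC gating tests
fixture_trials <- function() {
  data.table::data.table(
    participant_id = "P1", group = "ASD", timepoint = 1L,
    day = rep(1:2, each = 2), task = "AM", trial = c(1:2, 1:2),
    n_samples = 100L, duration_ms = 10000,
    pct_valid_data = c(100, 80, 60, 40),
    pct_face = c(20, 30, 25, 35), pct_body = 0, pct_activity = 0,
    pct_social = c(20, 30, 25, 35),
    bio_ms = 0, control_ms = 0, pct_bio = NA_real_,
    cal_error_deg = c(0.5, 0.5, 0.5, 0.5), affective = FALSE,
    latency_ms = NA_real_, constriction = NA_real_, plr_ok = NA)
}

# brute-force two-way ANOVA ICC oracle via lm/anova (independent of the
# package's closed-form path)
oracle_icc <- function(t1, t2) {
  n <- length(t1)
  long <- data.frame(y = c(t1, t2),
                     subj = factor(rep(seq_len(n), 2)),
                     occ = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::lm(y ~ subj + occ, data = long))
  msr <- a["subj", "Mean Sq"]; msc <- a["occ", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  list(consistency = (msr - mse) / (msr + mse),
       agreement = (msr - mse) / (msr + mse + (2 / n) * (msc - mse)))
}
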