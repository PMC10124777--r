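# QC gating, aggregation, OMI, and the acquisition report.

test_that("trial validity boundaries are inclusive", {
  tr <- fixture_trials()[1:3]
  tr$pct_valid_data <- c(50.0, 49.9, 100)
  tr$cal_error_deg <- c(2.5, 0.1, 2.6)
  expect_equal(trial_valid(tr), c(TRUE, FALSE, FALSE))
})

test_that("PLR trials need the PLR-specific checks too", {
  tr <- fixture_trials()[1:2]
  tr$task <- "PLR"
  tr$plr_ok <- c(TRUE, FALSE)
  expect_equal(trial_valid(tr), c(TRUE, FALSE))
})

test_that("missing calibration error invalidates a trial", {
  tr <- fixture_trials()[1]
  tr$cal_error_deg <- NA_real_
  expect_false(trial_valid(tr))
})

test_that("session invalidations exclude flagged days only", {
  tr <- fixture_trials()
  ses <- data.frame(participant_id = "P1", timepoint = 1L, day = 1:2,
                    session_invalid = c(TRUE, FALSE))
  out <- apply_session_invalidations(tr, ses)
  expect_false(any(out$valid[out$day == 1]))
  expect_equal(out$valid[out$day == 2], c(TRUE, FALSE))  # 40% fails gate
  # no flags: identity
  out2 <- apply_session_invalidations(tr, NULL)
  expect_equal(out2$valid, trial_valid(tr))
  # both days flagged: zero valid trials, task invalid
  ses$session_invalid <- TRUE
  sm <- summarize_task(apply_session_invalidations(tr, ses))
  expect_equal(sm$n_valid_trials, 0L)
  expect_false(sm$task_valid)
})

test_that("gating is idempotent", {
  tr <- apply_session_invalidations(fixture_trials(), NULL)
  tr2 <- apply_session_invalidations(tr, NULL)
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
})

test_that("the 25% task rule is inclusive at the boundary", {
  mk <- function(n_valid, n_total) {
    tr <- fixture_trials()[rep(1L, n_total)]
    tr$trial <- seq_len(n_total); tr$day <- 1L
    tr$pct_valid_data <- c(rep(100, n_valid), rep(0, n_total - n_valid))
    tr
  }
  expect_false(summarize_task(mk(13, 54))$task_valid)   # 24.1%
  expect_true(summarize_task(mk(14, 54))$task_valid)    # 25.9%
  expect_true(summarize_task(mk(1, 4))$task_valid)      # exactly 25%
})

test_that("task summaries average derived variables over valid trials only", {
  tr <- fixture_trials()
  sm <- summarize_task(apply_session_invalidations(tr, NULL))
  # trials 1-3 valid (100/80/60), trial 4 invalid (40)
  expect_equal(sm$n_valid_trials, 3L)
  expect_equal(sm$pct_face, mean(c(20, 30, 25)))
  expect_equal(sm$mean_pct_valid_data, mean(c(100, 80, 60, 40)))
  # undefined %Bio drops out of the mean
  tr$pct_bio <- c(60, NA, 40, 10)
  sm2 <- summarize_task(apply_session_invalidations(tr, NULL))
  expect_equal(sm2$pct_bio, 50)
})

test_that("summaries are invariant to trial order and day partition", {
  tr <- fixture_trials()
  sm1 <- summarize_task(apply_session_invalidations(tr, NULL))
  perm <- tr[c(3, 1, 4, 2)]
  perm$day <- c(2L, 2L, 1L, 1L)   # same trials, different day labels
  sm2 <- summarize_task(apply_session_invalidations(perm, NULL))
  expect_equal(sm1$pct_face, sm2$pct_face)
  expect_equal(sm1$pct_valid_trials, sm2$pct_valid_trials)
})

test_that("OMI is the equal-weight mean and requires all three tasks", {
  mk_sum <- function(faces, valid = c(TRUE, TRUE, TRUE)) {
    data.table::data.table(
      participant_id = "P1", group = "TD", timepoint = 1L,
      task = c("AM", "SI", "SS"), pct_face = faces, task_valid = valid)
  }
  o <- compute_omi(mk_sum(c(20, 25, 30)))
  expect_equal(o$omi, 25.0)
  expect_true(o$omi_valid)
  expect_gte(o$omi, 0); expect_lte(o$omi, 100)
  o2 <- compute_omi(mk_sum(c(27.6, 30.4, 34.9)))
  expect_equal(round(o2$omi, 2), 30.97)                  # ~ published 30.9
  o3 <- compute_omi(mk_sum(c(20, 25, 30), c(TRUE, TRUE, FALSE)))
  expect_false(o3$omi_valid)
  expect_true(is.na(o3$omi))
  # missing task row entirely
  o4 <- compute_omi(mk_sum(c(20, 25, 30))[1:2])
  expect_false(o4$omi_valid)
})

test_that("gating is monotone in thresholds", {
  set.seed(41)
  tr <- fixture_trials()[rep(1:4, 25)]
  tr$trial <- seq_len(nrow(tr))
  tr$pct_valid_data <- stats::runif(100, 0, 100)
  tr$cal_error_deg <- stats::runif(100, 0, 5)
  strict <- sum(trial_valid(tr, qc_config(valid_data_pct = 60,
                                          cal_error_deg = 2)))
  relaxed <- sum(trial_valid(tr, qc_config(valid_data_pct = 50,
                                           cal_error_deg = 2.5)))
  expect_gte(relaxed, strict)
  # zero calibration tolerance kills every trial
  expect_equal(sum(trial_valid(tr, qc_config(cal_error_deg = 0))), 0)
})

test_that("acquisition report computes rates, benchmark, and chi-squares", {
  n <- 80
  sm <- data.table::data.table(
    participant_id = sprintf("P%03d", 1:n),
    group = rep(c("ASD", "TD"), each = n / 2),
    timepoint = 1L, task = "AM",
    n_total_trials = 16L, n_valid_trials = 16L,
    pct_valid_trials = 100, mean_pct_valid_data = 90,
    mean_cal_error_deg = 0.6,
    pct_face = 25, pct_body = 5, pct_activity = 10, pct_social = 40,
    pct_bio = NA_real_, pct_bio_affect = NA_real_,
    latency_ms = NA_real_, constriction = NA_real_,
    task_valid = c(rep(c(TRUE, FALSE), c(24, 16)), rep(TRUE, 40)))
  omi <- data.table::data.table(
    participant_id = sm$participant_id, group = sm$group, timepoint = 1L,
    omi = 25, omi_valid = sm$task_valid)
  # site layout reproducing the hand-computed 2x2 chi-square 3.117 in ASD
  clin <- data.table::data.table(
    participant_id = sm$participant_id,
    site = c(rep("A", 40)[1:40], rep("B", 40))[1:n])
  clin$site[1:40] <- c(rep("A", 30), rep("B", 6), rep("A", 10), rep("B", 34))[1:40]
  rep_ <- suppressWarnings(acquisition_report(sm, omi, clin))
  asd_am <- rep_$rates[group == "ASD" & task == "AM"]
  expect_equal(asd_am$signal_valid_pct, 60)
  expect_false(asd_am$benchmark_pass)                 # 60% < 70%
  td_am <- rep_$rates[group == "TD" & task == "AM"]
  expect_true(td_am$benchmark_pass)
  expect_true(all(c("OMI") %in% rep_$rates$task))
  grp <- rep_$tests[test == "group"]
  expect_false(is.na(grp$statistic))
})

test_that("hand-computed 2x2 chi-square matches", {
  tab <- matrix(c(30, 10, 36, 4), 2, byrow = TRUE)
  expect_equal(gazeomi:::chisq_or_na(tab)$stat, 3.117, tolerance = 1e-3)
})
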