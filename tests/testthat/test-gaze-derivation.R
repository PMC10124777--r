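# ROI assignment, trial metrics, calibration-error estimation, and the
# derivation invariants (denominator contract, mirror invariance,
# conservation).

scr <- list(width_px = 1920L, height_px = 1200L, px_per_degree = 42)

test_that("ROI assignment: containment, off-screen, precedence, polygon", {
  rois <- fixture_rois()
  expect_equal(assign_sample_to_roi(200, 200, 0, rois, scr), "face")
  expect_equal(assign_sample_to_roi(200, 450, 0, rois, scr), "activity")
  expect_true(is.na(assign_sample_to_roi(1000, 1000, 0, rois, scr)))
  expect_true(is.na(assign_sample_to_roi(-5, 200, 0, rois, scr)))
  expect_true(is.na(assign_sample_to_roi(1920, 600, 0, rois, scr)))

  # overlapping face and body: face wins by precedence
  overlap <- rbind(fixture_rois()[1, ],
                   within(fixture_rois()[1, ], label <- "body"))
  overlap$x0[2] <- 50; overlap$x1[2] <- 500; overlap$y1[2] <- 600
  expect_equal(assign_sample_to_roi(200, 200, 0, overlap, scr), "face")
  expect_equal(assign_sample_to_roi(400, 500, 0, overlap, scr), "body")

  # polygon region (triangle) via the JSON reader
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(XX = list(list(
    label = "face", shape = "poly",
    coords = list(x = c(0, 100, 0), y = c(0, 0, 100)),
    t_start_ms = 0, t_end_ms = "inf", affective = FALSE))),
    path, auto_unbox = TRUE)
  tri <- read_roi_json(path)$XX
  expect_equal(assign_sample_to_roi(10, 10, 0, tri, scr), "face")
  expect_true(is.na(assign_sample_to_roi(90, 90, 0, tri, scr)))

  # time windows gate activity
  timed <- fixture_rois()
  timed$t_end_ms <- 1000
  expect_true(is.na(assign_sample_to_roi(200, 200, 1500, timed, scr)))
})

test_that("trial metrics match a hand-counted fixture", {
  # 20 samples: 10 tracked (5 face, 3 activity, 2 unlabelled), 10 lost
  samples <- data.frame(
    t_ms = seq(0, 1900, by = 100),
    x_px = c(rep(200, 5), rep(200, 3), rep(1000, 2), rep(NA, 10)),
    y_px = c(rep(200, 5), rep(450, 3), rep(1000, 2), rep(NA, 10)),
    tracked_flag = c(rep(1L, 10), rep(0L, 10)))
  m <- compute_trial_metrics(samples, fixture_rois(), 2000, scr)
  expect_equal(m$pct_valid_data, 50)
  expect_equal(m$pct_face, 50)
  expect_equal(m$pct_activity, 30)
  expect_equal(m$pct_social, 80)
  expect_true(is.na(m$pct_bio))
  # conservation: labelled shares cannot exceed 100
  expect_lte(m$pct_face + m$pct_body + m$pct_activity, 100)
})

test_that("all-in-face trial is fully valid", {
  samples <- data.frame(t_ms = seq(0, 990, 10), x_px = 200, y_px = 200,
                        tracked_flag = 1L)
  m <- compute_trial_metrics(samples, fixture_rois(), 1000, scr)
  expect_equal(m$pct_valid_data, 100)
  expect_equal(m$pct_face, 100)
})

test_that("calibration error estimation is exact on constructed offsets", {
  mk <- function(dx, dy) data.frame(
    t_ms = seq(0, 990, 10), x_px = 500 + dx, y_px = 500 + dy,
    tracked_flag = 1L)
  ev <- list(list(t_window = c(0, 1000), target_px = c(500, 500)))
  expect_equal(estimate_cal_error(mk(0, 0), ev), 0)
  expect_equal(estimate_cal_error(mk(42, 0), ev), 1.0)
  expect_equal(estimate_cal_error(mk(3 * 42, 4 * 42), ev), 5.0)
  # no tracked samples in window: missing
  none <- mk(0, 0); none$tracked_flag <- 0L
  expect_true(is.na(estimate_cal_error(none, ev)))
})

test_that("ROI percentages are invariant to dropout (denominator contract)", {
  set.seed(21)
  pf <- sapply(c(0, 0.5), function(dr) {
    mean(replicate(30, {
      s <- simulate_gaze_trial(0, duration_s = 15, dropout_rate = dr)
      rois <- data.frame(label = "face", shape = "rect",
                         x0 = 788.5, y0 = 312.4, x1 = 1131.5, y1 = 527.6,
                         t_start_ms = 0, t_end_ms = Inf, affective = FALSE)
      compute_trial_metrics(s, rois, 15000, scr)$pct_face
    }))
  })
  expect_lt(abs(pf[1] - pf[2]), 3)   # both estimate the same stationary 50%
})

test_that("mirroring gaze and ROIs together changes nothing", {
  set.seed(22)
  s <- simulate_gaze_trial(0.3, duration_s = 10,
                           face_rect = c(500, 300, 900, 550))
  rois <- data.frame(label = "face", shape = "rect",
                     x0 = 500, y0 = 300, x1 = 900, y1 = 550,
                     t_start_ms = 0, t_end_ms = Inf, affective = FALSE)
  m1 <- compute_trial_metrics(s, rois, 10000, scr)
  s2 <- s; s2$x_px <- scr$width_px - s$x_px
  m2 <- compute_trial_metrics(s2, roi_mirror_x(rois, scr$width_px),
                              10000, scr)
  expect_equal(m1$pct_face, m2$pct_face)
  expect_equal(m1$pct_valid_data, m2$pct_valid_data)
})

test_that("ROI JSON round-trips geometry and metadata", {
  sets <- default_rois()
  path <- tempfile(fileext = ".json")
  write_roi_json(sets, path)
  back <- read_roi_json(path)
  expect_setequal(names(back), names(sets))
  for (nm in names(sets)) {
    expect_equal(back[[nm]]$label, sets[[nm]]$label)
    expect_equal(back[[nm]]$x0, sets[[nm]]$x0, tolerance = 1e-9)
    expect_equal(back[[nm]]$x1, sets[[nm]]$x1, tolerance = 1e-9)
  }
  # SS day 2 is the mirror of day 1
  expect_equal(back$SS.2$x0, scr$width_px - back$SS.1$x1)
  # schema violations are rejected
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = list(list(label = "face", shape = "rect",
                                          coords = c(10, 10, 10, 50)))),
                       bad, auto_unbox = TRUE)
  expect_error(read_roi_json(bad), "degenerate")
})

test_that("batch derivation agrees with per-trial computation", {
  cfg <- tiny_cfg(n_asd = 1L, n_td = 1L, seed = 13L)
  co <- simulate_cohort(cfg)
  roi_sets <- default_rois(cfg$screen, cfg$roi_area_frac)
  tr <- derive_trials(co$gaze, roi_sets, cfg$screen, cfg$flash_ms)
  one <- co$gaze[participant_id == co$truth$participant_id[1] &
                   timepoint == 1 & day == 1 & task == "AM" & trial == 1]
  m <- compute_trial_metrics(as.data.frame(one), roi_sets$AM,
                             max(one$t_ms) + diff(one$t_ms)[1],
                             cfg$screen)
  row <- tr[participant_id == co$truth$participant_id[1] &
              timepoint == 1 & day == 1 & task == "AM" & trial == 1]
  expect_equal(row$pct_face, m$pct_face)
  expect_equal(row$pct_valid_data, m$pct_valid_data)
  # every percentage in bounds
  for (cl in c("pct_valid_data", "pct_face", "pct_body", "pct_activity",
               "pct_bio"))
    expect_true(all(is.na(tr[[cl]]) | (tr[[cl]] >= 0 & tr[[cl]] <= 100)),
                label = cl)
})
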