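# Simulation and pipeline configuration.
#
# Defaults describe the cohort the package is designed around: two diagnostic
# groups (ASD n = 280, TD n = 119) of 6-11.5-year-olds assessed at two
# timepoints six weeks apart, each timepoint spanning two days of eye-tracking
# sessions (54 trials/day across five tasks), on a 1920 x 1200 display at
# 65 cm where 1 visual degree = 42 pixels.

#' Default per-day trial plan
#'
#' One session (day) administers 54 trials: ActivityMonitoring (AM) 4 static
#' 10-s + 4 video 20-s trials, SocialInteractive (SI) 11 x 15 s, StaticScenes
#' (SS) 6 x 20 s (repeated each day with day-2 horizontally mirrored regions),
#' Biomotion (BM) 20 x 10 s, and PLR 9 x 2.5 s. `day = 0` means the block is
#' run on both days of a timepoint.
#'
#' @return data.frame with columns task, n_trials, duration_s, day
#' @export
default_trial_plan <- function() {
  data.frame(
    task       = c("AM", "AM", "SI", "SS", "BM", "PLR"),
    n_trials   = c(4L, 4L, 11L, 6L, 20L, 9L),
    duration_s = c(10, 20, 15, 20, 10, 2.5),
    day        = 0L,
    stringsAsFactors = FALSE
  )
}

#' Default per-group looking-percentage targets
#'
#' Group means and SDs (percentage points) that the simulator is calibrated
#' to realize for each ROI-based primary variable: %Face for AM/SI/SS and
#' %Bio for BM.
#'
#' @return data.frame with columns task, group, mean_pct, sd_pct
#' @export
default_face_targets <- function() {
  data.frame(
    task     = rep(c("AM", "SI", "SS", "BM"), each = 2L),
    group    = rep(c("ASD", "TD"), 4L),
    mean_pct = c(18.7, 27.6, 24.2, 30.4, 29.9, 34.9, 53.4, 54.8),
    sd_pct   = c(8.7, 8.5, 10.7, 9.6, 9.8, 8.0, 6.8, 6.1),
    stringsAsFactors = FALSE
  )
}

# Clinical score scales (group mean/SD on the instrument's native scale).
# Scores listed in clinical_rho_targets are coupled to the face latent;
# anything else would be generated as pure noise.
default_clinical_scales <- function() {
  data.frame(
    score   = rep(c("face_memory_ss", "ados_sa", "vabs3_com_ss",
                    "pddbi_reprit_t", "srs_sci_t"), each = 2L),
    group   = rep(c("ASD", "TD"), 5L),
    mean    = c(7.86, 10.53, 7.34, 1.91, 76.44, 103.44, 49.6, 28.03,
                72.65, 42.47),
    sd      = c(3.67, 3.49, 1.79, 1.34, 15.07, 9.16, 11.52, 2.61,
                10.83, 5.05),
    stringsAsFactors = FALSE
  )
}

#' Build a cohort simulation configuration
#'
#' All arguments have calibrated defaults; override only what an experiment
#' needs. Fractions are in [0, 1], angles in visual degrees, times in ms
#' unless suffixed otherwise.
#'
#' @param n_asd,n_td group sizes
#' @param face_targets data.frame of per-task, per-group realized mean/SD
#'   targets on the percentage scale (see [default_face_targets()])
#' @param trait_variance_fraction fraction of between-participant latent
#'   variance that is stable trait (controls the population ICC between the
#'   two timepoints; default 0.836)
#' @param shared_task_fraction fraction of each face-task latent variance
#'   carried by a participant-level latent shared across AM/SI/SS (drives the
#'   cross-task correlation and hence the SD of the task-average composite;
#'   default 0.64)
#' @param trial_noise_sd SD of the per-trial logit-scale disturbance
#' @param dwell_mean_ms mean in-state dwell of the two-state gaze chain
#' @param dropout_mean,dropout_sd per-group mean/SD of the participant-level
#'   per-sample tracking-loss probability (named ASD/TD)
#' @param cal_error_scale per-group per-axis SD (degrees) of the constant
#'   participant-day calibration offset; offset magnitude is then Rayleigh
#'   with mean `scale * sqrt(pi/2)`
#' @param plr_latency_mean,plr_latency_sd per-group pupillary light reflex
#'   latency distribution (ms)
#' @param plr_constriction_mean,plr_constriction_sd relative constriction
#'   (fraction of baseline diameter), common to both groups
#' @param plr_tau_ms time constant of the sigmoidal constriction
#' @param plr_baseline_au,plr_baseline_sd_au baseline pupil size (arbitrary
#'   units) distribution across participants
#' @param plr_noise_frac white-noise SD as a fraction of baseline
#' @param plr_blink_prob probability that a PLR trial contains a blink gap
#' @param plr_sample_rate sampling rate for PLR trials (Hz)
#' @param clinical_rho_targets named vector of target Spearman correlations
#'   between each clinical score and the T1 face latent (|rho| < 1)
#' @param sample_rate gaze sampling rate (Hz); proportions of looking time
#'   are rate-invariant, so the default 50 Hz keeps desk-scale runtimes (the
#'   hardware-native 500 Hz is available by configuration)
#' @param trial_plan per-day trial plan (see [default_trial_plan()])
#' @param screen list(width_px, height_px, px_per_degree)
#' @param roi_area_frac named fractions of screen area occupied by the face
#'   region per task (the area-based chance levels)
#' @param session_invalid_prob probability that a participant-timepoint-day
#'   session is administratively invalidated
#' @param flash_ms PLR flash onset within a trial (baseline window precedes)
#' @param n_validation_events validation-target events per session day
#' @param seed integer seed; identical config + seed gives identical output
#' @return object of class `omi_sim_config`
#' @export
sim_config <- function(n_asd = 280L,
                       n_td = 119L,
                       face_targets = default_face_targets(),
                       trait_variance_fraction = 0.836,
                       shared_task_fraction = 0.64,
                       trial_noise_sd = 0.2,
                       dwell_mean_ms = 300,
                       dropout_mean = c(ASD = 0.129, TD = 0.060),
                       dropout_sd = c(ASD = 0.10, TD = 0.05),
                       cal_error_scale = c(ASD = 0.484, TD = 0.426),
                       plr_latency_mean = c(ASD = 285, TD = 279),
                       plr_latency_sd = c(ASD = 15, TD = 15),
                       plr_constriction_mean = 0.505,
                       plr_constriction_sd = 0.074,
                       plr_tau_ms = 100,
                       plr_baseline_au = 1000,
                       plr_baseline_sd_au = 100,
                       plr_noise_frac = 0.003,
                       plr_blink_prob = 0.05,
                       plr_sample_rate = 500,
                       clinical_rho_targets = c(face_memory_ss = 0.316,
                                                ados_sa = -0.165,
                                                vabs3_com_ss = 0.182,
                                                pddbi_reprit_t = -0.238,
                                                srs_sci_t = -0.070),
                       sample_rate = 50,
                       trial_plan = default_trial_plan(),
                       screen = list(width_px = 1920L, height_px = 1200L,
                                     px_per_degree = 42),
                       roi_area_frac = c(AM = 0.032, SI = 0.083, SS = 0.039),
                       session_invalid_prob = 0,
                       flash_ms = 500,
                       n_validation_events = 5L,
                       seed = 1L) {
  cfg <- list(
    n_asd = as.integer(n_asd), n_td = as.integer(n_td),
    face_targets = face_targets,
    trait_variance_fraction = trait_variance_fraction,
    shared_task_fraction = shared_task_fraction,
    trial_noise_sd = trial_noise_sd,
    dwell_mean_ms = dwell_mean_ms,
    dropout_mean = dropout_mean, dropout_sd = dropout_sd,
    cal_error_scale = cal_error_scale,
    plr_latency_mean = plr_latency_mean, plr_latency_sd = plr_latency_sd,
    plr_constriction_mean = plr_constriction_mean,
    plr_constriction_sd = plr_constriction_sd,
    plr_tau_ms = plr_tau_ms,
    plr_baseline_au = plr_baseline_au,
    plr_baseline_sd_au = plr_baseline_sd_au,
    plr_noise_frac = plr_noise_frac,
    plr_blink_prob = plr_blink_prob,
    plr_sample_rate = plr_sample_rate,
    clinical_rho_targets = clinical_rho_targets,
    sample_rate = sample_rate,
    trial_plan = trial_plan,
    screen = screen,
    roi_area_frac = roi_area_frac,
    session_invalid_prob = session_invalid_prob,
    flash_ms = flash_ms,
    n_validation_events = as.integer(n_validation_events),
    seed = as.integer(seed)
  )
  class(cfg) <- "omi_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_asd <= 0L || cfg$n_td <= 0L)
    stop_config("group sizes must be positive (n_asd = %d, n_td = %d)",
                cfg$n_asd, cfg$n_td)
  need <- c("AM", "SI", "SS", "BM", "PLR")
  have <- unique(cfg$trial_plan$task)
  if (!all(need %in% have))
    stop_config("trial_plan must cover tasks %s; missing: %s",
                paste(need, collapse = ", "),
                paste(setdiff(need, have), collapse = ", "))
  fracs <- c(cfg$trait_variance_fraction, cfg$shared_task_fraction,
             cfg$dropout_mean, cfg$plr_constriction_mean,
             cfg$session_invalid_prob, cfg$plr_blink_prob)
  if (any(fracs < 0 | fracs > 1))
    stop_config("all fractions must lie in [0, 1]")
  if (cfg$sample_rate <= 0 || cfg$plr_sample_rate <= 0)
    stop_config("sample rates must be positive")
  if (any(c(cfg$dropout_sd, cfg$plr_latency_sd, cfg$trial_noise_sd) < 0))
    stop_config("variances/SDs must be non-negative")
  if (any(abs(cfg$clinical_rho_targets) >= 1))
    stop_config("clinical rho targets must have |rho| < 1")
  for (g in c("ASD", "TD"))
    for (nm in c("dropout_mean", "dropout_sd", "cal_error_scale",
                 "plr_latency_mean", "plr_latency_sd"))
      if (is.na(cfg[[nm]][g]))
        stop_config("%s must be named with ASD and TD entries", nm)
  invisible(cfg)
}

#' Quality-control thresholds and reporting options
#'
#' @param valid_data_pct minimum per-trial %Valid Data (inclusive)
#' @param cal_error_deg maximum per-trial calibration error in degrees
#'   (inclusive)
#' @param valid_trials_pct minimum per-task %Valid Trials for a timepoint to
#'   count as valid (inclusive)
#' @param benchmark_pct group-level data-validity benchmark
#' @return object of class `omi_qc_config`
#' @export
qc_config <- function(valid_data_pct = 50, cal_error_deg = 2.5,
                      valid_trials_pct = 25, benchmark_pct = 70) {
  cfg <- list(valid_data_pct = valid_data_pct,
              cal_error_deg = cal_error_deg,
              valid_trials_pct = valid_trials_pct,
              benchmark_pct = benchmark_pct)
  class(cfg) <- "omi_qc_config"
  cfg
}
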