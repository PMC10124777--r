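# Synthetic cohort simulator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: two diagnostic groups with per-task face-looking propensities on
# the logit scale (trait + state decomposition across two timepoints, and a
# shared-across-tasks component driving the composite's SD), participant-level
# tracking loss, constant participant-day calibration offsets, sigmoidal
# pupil flash responses, and clinical scores rank-coupled to the face latent
# through a Gaussian copula. It does not attempt realistic saccade
# kinematics, stimulus content, or pupil physiology beyond the sigmoid.

TASKS_FACE <- c("AM", "SI", "SS")
PLR_TRIAL_JITTER_SD <- 8    # ms, within-participant trial-to-trial latency
LOGISTIC_ACCEL_ARGMIN <- log((3 - sqrt(3)) / (3 + sqrt(3)))  # -1.316958

#' Five-point validation-target layout
#'
#' Fixed protocol convention shared by the simulator and the derivation
#' stage: validation events within a session cycle through these targets in
#' order.
#'
#' @param screen list(width_px, height_px)
#' @return data.frame with columns x_px, y_px (5 rows)
#' @export
validation_layout <- function(screen) {
  W <- screen$width_px; H <- screen$height_px
  data.frame(x_px = c(0.5, 0.2, 0.8, 0.2, 0.8) * W,
             y_px = c(0.5, 0.2, 0.2, 0.8, 0.8) * H)
}

# Two-state stationary Markov chain, vectorised across trials.
# p: per-trial stationary in-state probability; returns n_trials x n_steps
# logical matrix. Mean in-state dwell is dwell_ms (capped by stationarity
# when p is extreme).
gen_markov_states <- function(p, n_steps, dt_ms, dwell_ms) {
  n <- length(p)
  S <- matrix(FALSE, n, n_steps)
  if (n == 0L || n_steps == 0L) return(S)
  p <- pmin(pmax(p, 0), 1)
  q_out <- rep(1 - exp(-dt_ms / dwell_ms), n)
  q_in <- q_out * p / (1 - p)
  hi <- !is.finite(q_in) | q_in > 1
  q_in[hi] <- 1
  q_out[hi] <- (1 - p[hi]) / pmax(p[hi], 1e-12)
  s <- stats::runif(n) < p
  S[, 1] <- s
  for (t in seq_len(n_steps)[-1]) {
    u <- stats::runif(n)
    s <- (s & u >= q_out) | (!s & u < q_in)
    S[, t] <- s
  }
  S[p <= 0, ] <- FALSE
  S[p >= 1, ] <- TRUE
  S
}

# Uniform draws inside per-sample rectangles.
runif_rect <- function(x0, y0, w, h) {
  list(x = x0 + stats::runif(length(x0)) * w,
       y = y0 + stats::runif(length(y0)) * h)
}

# Uniform draws on the screen excluding per-sample rectangles (rejection).
runif_outside_rect <- function(n, x0, y0, x1, y1, W, H) {
  x <- stats::runif(n) * W; y <- stats::runif(n) * H
  for (it in 1:100) {
    bad <- x >= x0 & x < x1 & y >= y0 & y < y1
    if (!any(bad)) break
    nb <- sum(bad)
    x[bad] <- stats::runif(nb) * W
    y[bad] <- stats::runif(nb) * H
  }
  list(x = x, y = y)
}

rbeta_moments <- function(n, m, s) {
  if (m <= 0) return(rep(0, n))
  if (m >= 1) return(rep(1, n))
  m <- min(max(m, 1e-3), 1 - 1e-3)
  v <- min(s^2, 0.9 * m * (1 - m))
  if (v <= 0) return(rep(m, n))
  nu <- m * (1 - m) / v - 1
  stats::rbeta(n, m * nu, (1 - m) * nu)
}

#' Simulate a complete synthetic cohort
#'
#' Generates the full data bundle for two timepoints x two days: a gaze
#' sample table (all tasks plus validation-target events), a clinical /
#' demographic table, session metadata, and the ground-truth latents. Output
#' is bit-reproducible given identical config (including its seed).
#'
#' @param config an [sim_config()] object
#' @return list of class `omi_cohort` with elements `gaze`, `clinical`,
#'   `sessions`, `truth`, `calibration`, `config`
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  scr <- cfg$screen
  roi_sets <- default_rois(scr, cfg$roi_area_frac)
  cal <- calibrate_cohort_latents(cfg, roi_sets)

  n <- cfg$n_asd + cfg$n_td
  ids <- sprintf("P%04d", seq_len(n))
  group <- c(rep("ASD", cfg$n_asd), rep("TD", cfg$n_td))
  site <- sample(paste0("S", 1:5), n, replace = TRUE)
  age <- round(stats::runif(n, 6.0, 11.5), 2)
  iq <- ifelse(group == "ASD",
               pmin(pmax(round(stats::rnorm(n, 96.58, 18.11)), 60), 150),
               pmin(pmax(round(stats::rnorm(n, 115.12, 12.55)), 80), 150))

  # trait share inflated per group so the downstream ICC (after finite-trial
  # measurement noise) matches the configured trait_variance_fraction
  f_grp <- vapply(c(ASD = "ASD", TD = "TD"),
                  function(g) effective_trait_fraction(cfg, g), numeric(1))
  f <- unname(f_grp[group])
  lam <- cfg$shared_task_fraction
  # shared and task-unique standard-normal latents, each trait + state
  mix_ts <- function(trait, state) sqrt(f) * trait + sqrt(1 - f) * state
  sh_trait <- stats::rnorm(n)
  sh_state <- matrix(stats::rnorm(2 * n), n, 2)
  theta <- array(NA_real_, c(n, 4L, 2L),
                 dimnames = list(NULL, c(TASKS_FACE, "BM"), NULL))
  z_shared <- vapply(1:2, function(tp) mix_ts(sh_trait, sh_state[, tp]),
                     numeric(n))
  for (task in c(TASKS_FACE, "BM")) {
    u_trait <- stats::rnorm(n)
    u_state <- matrix(stats::rnorm(2 * n), n, 2)
    for (tp in 1:2) {
      z_u <- mix_ts(u_trait, u_state[, tp])
      z <- if (task == "BM") z_u
           else sqrt(lam) * z_shared[, tp] + sqrt(1 - lam) * z_u
      ci <- cal[cal$task == task, ]
      mu <- ci$mu[match(group, ci$group)]
      sg <- ci$sigma[match(group, ci$group)]
      theta[, task, tp] <- mu + sg * z
    }
  }

  dropout <- pmin(ifelse(group == "ASD",
                         rbeta_moments(n, cfg$dropout_mean[["ASD"]],
                                       cfg$dropout_sd[["ASD"]]),
                         rbeta_moments(n, cfg$dropout_mean[["TD"]],
                                       cfg$dropout_sd[["TD"]])), 0.95)
  off_sd_px <- cfg$cal_error_scale[group] * scr$px_per_degree
  offs <- array(stats::rnorm(n * 2 * 2 * 2), c(n, 2, 2, 2)) *
    as.vector(off_sd_px)  # [participant, tp, day, axis]

  plr_lat <- stats::rnorm(n, cfg$plr_latency_mean[group],
                          cfg$plr_latency_sd[group])
  plr_con <- pmin(pmax(stats::rnorm(n, cfg$plr_constriction_mean,
                                    cfg$plr_constriction_sd), 0.02), 0.95)
  plr_base <- pmax(stats::rnorm(n, cfg$plr_baseline_au,
                                cfg$plr_baseline_sd_au), 100)

  sessions <- data.table::CJ(participant_id = ids, timepoint = 1:2, day = 1:2)
  sessions[, session_invalid :=
             stats::runif(nrow(sessions)) < cfg$session_invalid_prob]

  trials <- build_trial_table(cfg, ids, group, theta, dropout, offs,
                              plr_lat, plr_con, plr_base, roi_sets)
  gaze <- generate_gaze(cfg, trials, roi_sets)

  # clinical coupling latent: standardised within group from the T1 face
  # composite (average of z-scored AM/SI/SS latents)
  zt <- sapply(TASKS_FACE, function(task) {
    ci <- cal[cal$task == task, ]
    (theta[, task, 1] - ci$mu[match(group, ci$group)]) /
      ci$sigma[match(group, ci$group)]
  })
  comp <- rowMeans(zt)
  face_latent <- stats::ave(comp, group,
                            FUN = function(v) (v - mean(v)) / stats::sd(v))

  truth <- data.table::data.table(
    participant_id = ids, group = group, site = site,
    age_years = age, iq = iq,
    dropout_rate = dropout,
    cal_off_x_t1_d1_deg = offs[, 1, 1, 1] / scr$px_per_degree,
    cal_off_y_t1_d1_deg = offs[, 1, 1, 2] / scr$px_per_degree,
    cal_off_x_t1_d2_deg = offs[, 1, 2, 1] / scr$px_per_degree,
    cal_off_y_t1_d2_deg = offs[, 1, 2, 2] / scr$px_per_degree,
    cal_off_x_t2_d1_deg = offs[, 2, 1, 1] / scr$px_per_degree,
    cal_off_y_t2_d1_deg = offs[, 2, 1, 2] / scr$px_per_degree,
    cal_off_x_t2_d2_deg = offs[, 2, 2, 1] / scr$px_per_degree,
    cal_off_y_t2_d2_deg = offs[, 2, 2, 2] / scr$px_per_degree,
    plr_latency_ms = plr_lat,
    plr_constriction = plr_con,
    plr_min_accel_ms = cfg$flash_ms + plr_lat,
    face_latent_t1 = face_latent
  )
  for (task in c(TASKS_FACE, "BM"))
    for (tp in 1:2)
      truth[, paste0("theta_", task, "_t", tp) := theta[, task, tp]]

  clinical <- simulate_clinical_scores(truth, cfg)

  out <- list(gaze = gaze, clinical = clinical, sessions = sessions,
              truth = truth, calibration = cal, config = cfg)
  class(out) <- "omi_cohort"
  out
}

# Expand the per-day plan into one row per trial with all latent attributes
# the sample generator needs.
build_trial_table <- function(cfg, ids, group, theta, dropout, offs,
                              plr_lat, plr_con, plr_base, roi_sets) {
  scr <- cfg$screen
  n <- length(ids)
  plan <- cfg$trial_plan
  chunks <- list()
  for (tp in 1:2) for (day in 1:2) {
    rows <- plan[plan$day == 0L | plan$day == day, , drop = FALSE]
    per_session <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
      data.frame(task = rows$task[i], duration_s = rows$duration_s[i],
                 idx = seq_len(rows$n_trials[i]))))
    # trial ids consecutive within task across plan rows
    per_session$trial <- stats::ave(seq_len(nrow(per_session)),
                                    per_session$task, FUN = seq_along)
    # validation events appended as their own pseudo-task
    val <- data.frame(task = "VAL", duration_s = 1,
                      idx = seq_len(cfg$n_validation_events),
                      trial = seq_len(cfg$n_validation_events))
    per_session <- rbind(per_session, val)
    m <- nrow(per_session)
    ch <- data.table::data.table(
      participant_id = rep(ids, each = m),
      pi = rep(seq_len(n), each = m),
      group = rep(group, each = m),
      timepoint = tp, day = day,
      task = rep(per_session$task, n),
      trial = rep(per_session$trial, n),
      duration_ms = rep(per_session$duration_s, n) * 1000
    )
    ch[, off_x := offs[cbind(pi, tp, day, 1L)]]
    ch[, off_y := offs[cbind(pi, tp, day, 2L)]]
    chunks[[length(chunks) + 1L]] <- ch
  }
  trials <- data.table::rbindlist(chunks)
  trials[, dropout_rate := dropout[pi]]
  # stationary probabilities with per-trial logit noise
  trials[, p_stat := NA_real_]
  for (task in c(TASKS_FACE, "BM")) {
    sel <- trials$task == task
    th <- theta[cbind(trials$pi[sel], match(task, c(TASKS_FACE, "BM")),
                      trials$timepoint[sel])]
    trials[sel, p_stat := invlogit(th + stats::rnorm(sum(sel), 0,
                                                     cfg$trial_noise_sd))]
  }
  # face-rect geometry per trial (SS mirrored on day 2)
  trials[, `:=`(fx0 = NA_real_, fy0 = NA_real_, fx1 = NA_real_,
                fy1 = NA_real_)]
  for (task in TASKS_FACE) for (d in 1:2) {
    sel <- trials$task == task & trials$day == d
    if (!any(sel)) next
    fr <- rois_for(roi_sets, task, d)
    fr <- fr[fr$label == "face", ][1, ]
    trials[sel, `:=`(fx0 = fr$x0, fy0 = fr$y0, fx1 = fr$x1, fy1 = fr$y1)]
  }
  # biomotion affective subset: 20% of trials
  trials[, affective := FALSE]
  bm <- which(trials$task == "BM")
  trials[bm, affective := (trial - 1L) %% 5L == 0L]
  # PLR latents (per-trial latency jitter)
  trials[, `:=`(plr_latency = NA_real_, plr_constr = NA_real_,
                plr_baseline = NA_real_)]
  pl <- which(trials$task == "PLR")
  trials[pl, `:=`(
    plr_latency = plr_lat[pi] + stats::rnorm(length(pl), 0,
                                             PLR_TRIAL_JITTER_SD),
    plr_constr = plr_con[pi],
    plr_baseline = plr_base[pi]
  )]
  # validation targets cycle through the five-point layout
  lay <- validation_layout(scr)
  trials[, `:=`(val_x = NA_real_, val_y = NA_real_)]
  vl <- which(trials$task == "VAL")
  trials[vl, `:=`(val_x = lay$x_px[(trial - 1L) %% 5L + 1L],
                  val_y = lay$y_px[(trial - 1L) %% 5L + 1L])]
  trials
}

# Generate the long gaze-sample table from the trial table.
generate_gaze <- function(cfg, trials, roi_sets) {
  scr <- cfg$screen
  W <- scr$width_px; H <- scr$height_px
  bm_rois <- rois_for(roi_sets, "BM", 1L)
  bio_r <- bm_rois[bm_rois$label == "bio", ][1, ]
  ctl_r <- bm_rois[bm_rois$label == "control", ][1, ]
  out <- vector("list", 0L)

  trials[, chunk := paste(ifelse(task %in% c(TASKS_FACE, "BM"), task,
                                 task), duration_ms)]
  for (ck in unique(trials$chunk)) {
    tr <- trials[trials$chunk == ck, ]
    task <- tr$task[1]
    rate <- if (task == "PLR") cfg$plr_sample_rate else cfg$sample_rate
    dt <- 1000 / rate
    n_steps <- max(1L, as.integer(round(tr$duration_ms[1] / dt)))
    n_tr <- nrow(tr)
    n_smp <- n_tr * n_steps
    t_step <- (seq_len(n_steps) - 1) * dt
    if (all(t_step == round(t_step))) t_step <- as.integer(t_step)
    t_ms <- rep(t_step, times = n_tr)
    rep_tr <- function(v) rep(v, each = n_steps)

    if (task %in% c(TASKS_FACE, "BM")) {
      S <- gen_markov_states(tr$p_stat, n_steps, dt, cfg$dwell_mean_ms)
      s <- as.vector(t(S))
      if (task == "BM") {
        x <- numeric(n_smp); y <- numeric(n_smp)
        pin <- runif_rect(rep(bio_r$x0, sum(s)), rep(bio_r$y0, sum(s)),
                          bio_r$x1 - bio_r$x0, bio_r$y1 - bio_r$y0)
        x[s] <- pin$x; y[s] <- pin$y
        pout <- runif_rect(rep(ctl_r$x0, sum(!s)), rep(ctl_r$y0, sum(!s)),
                           ctl_r$x1 - ctl_r$x0, ctl_r$y1 - ctl_r$y0)
        x[!s] <- pout$x; y[!s] <- pout$y
      } else {
        fx0 <- rep_tr(tr$fx0); fy0 <- rep_tr(tr$fy0)
        fx1 <- rep_tr(tr$fx1); fy1 <- rep_tr(tr$fy1)
        x <- numeric(n_smp); y <- numeric(n_smp)
        pin <- runif_rect(fx0[s], fy0[s], (fx1 - fx0)[s], (fy1 - fy0)[s])
        x[s] <- pin$x; y[s] <- pin$y
        pout <- runif_outside_rect(sum(!s), fx0[!s], fy0[!s], fx1[!s],
                                   fy1[!s], W, H)
        x[!s] <- pout$x; y[!s] <- pout$y
      }
      pupil <- cfg$plr_baseline_au *
        (1 + stats::rnorm(n_smp, 0, cfg$plr_noise_frac))
    } else if (task == "PLR") {
      t0 <- rep_tr(tr$plr_latency) + cfg$flash_ms -
        LOGISTIC_ACCEL_ARGMIN * cfg$plr_tau_ms
      B <- rep_tr(tr$plr_baseline)
      pupil <- B * (1 - rep_tr(tr$plr_constr) *
                      invlogit((t_ms - t0) / cfg$plr_tau_ms) +
                      stats::rnorm(n_smp, 0, cfg$plr_noise_frac))
      x <- W / 2 + stats::rnorm(n_smp, 0, 20)
      y <- H / 2 + stats::rnorm(n_smp, 0, 20)
      # blink gaps
      blink_tr <- stats::runif(n_tr) < cfg$plr_blink_prob
      if (any(blink_tr)) {
        bstart <- stats::runif(n_tr, 0, tr$duration_ms - 150)
        rel_t <- t_ms - rep_tr(bstart)
        blink <- rep_tr(blink_tr) & rel_t >= 0 & rel_t < 120
        pupil[blink] <- NA_real_
        x[blink] <- NA_real_; y[blink] <- NA_real_
      }
    } else { # VAL
      x <- rep_tr(tr$val_x) + stats::rnorm(n_smp, 0, 8)
      y <- rep_tr(tr$val_y) + stats::rnorm(n_smp, 0, 8)
      pupil <- cfg$plr_baseline_au *
        (1 + stats::rnorm(n_smp, 0, cfg$plr_noise_frac))
    }

    x <- x + rep_tr(tr$off_x)
    y <- y + rep_tr(tr$off_y)
    tracked <- stats::runif(n_smp) >= rep_tr(tr$dropout_rate)
    tracked <- tracked & !is.na(x) & !is.na(pupil)
    x[!tracked] <- NA_real_; y[!tracked] <- NA_real_
    pupil[!tracked] <- NA_real_

    out[[length(out) + 1L]] <- data.table::data.table(
      participant_id = rep_tr(tr$participant_id),
      group = rep_tr(tr$group),
      timepoint = rep_tr(tr$timepoint),
      day = rep_tr(tr$day),
      task = task,
      trial = rep_tr(tr$trial),
      t_ms = t_ms,
      # truncate instead of round: a boundary sample must not be pushed
      # past the half-open screen bounds
      x_px = floor(x * 10) / 10, y_px = floor(y * 10) / 10,
      pupil_au = round(pupil, 2),
      tracked_flag = as.integer(tracked)
    )
  }
  trials[, chunk := NULL]
  # deterministic chunk-major order; consumers key on read
  data.table::rbindlist(out)
}

#' Simulate one gaze trial
#'
#' Single-trial convenience wrapper around the cohort generator's sampling
#' scheme: a two-state dwell chain whose stationary in-face probability is
#' `invlogit(theta)`, i.i.d. per-sample dropout, and a constant calibration
#' offset added to emitted coordinates.
#'
#' @param theta logit of the stationary in-face probability
#' @param duration_s trial duration in seconds
#' @param face_rect numeric `c(x0, y0, x1, y1)` of the face region
#' @param sample_rate sampling rate in Hz
#' @param dwell_mean_ms mean in-state dwell
#' @param dropout_rate per-sample probability of tracking loss
#' @param offset_px numeric `c(dx, dy)` calibration offset
#' @param screen list(width_px, height_px)
#' @return data.frame of samples (t_ms, x_px, y_px, tracked_flag, in_face)
#' @export
simulate_gaze_trial <- function(theta, duration_s,
                                face_rect = c(788.5, 312.4, 1131.5, 527.6),
                                sample_rate = 50, dwell_mean_ms = 300,
                                dropout_rate = 0, offset_px = c(0, 0),
                                screen = list(width_px = 1920L,
                                              height_px = 1200L)) {
  stopifnot(duration_s > 0)
  dt <- 1000 / sample_rate
  n <- max(1L, as.integer(round(duration_s * 1000 / dt)))
  p <- invlogit(theta)
  s <- as.vector(gen_markov_states(p, n, dt, dwell_mean_ms)[1, ])
  x <- numeric(n); y <- numeric(n)
  pin <- runif_rect(rep(face_rect[1], sum(s)), rep(face_rect[2], sum(s)),
                    face_rect[3] - face_rect[1], face_rect[4] - face_rect[2])
  x[s] <- pin$x; y[s] <- pin$y
  pout <- runif_outside_rect(sum(!s), rep(face_rect[1], sum(!s)),
                             rep(face_rect[2], sum(!s)),
                             rep(face_rect[3], sum(!s)),
                             rep(face_rect[4], sum(!s)),
                             screen$width_px, screen$height_px)
  x[!s] <- pout$x; y[!s] <- pout$y
  x <- x + offset_px[1]; y <- y + offset_px[2]
  tracked <- stats::runif(n) >= dropout_rate
  x[!tracked] <- NA_real_; y[!tracked] <- NA_real_
  data.frame(t_ms = (seq_len(n) - 1) * dt, x_px = x, y_px = y,
             tracked_flag = as.integer(tracked), in_face = s)
}

#' Simulate one pupillary-light-reflex trial
#'
#' The diameter follows `B * (1 - c * S((t - t0)/tau))` with `S` the logistic
#' sigmoid, shifted so that the analytic time of minimum second derivative
#' (maximum constriction acceleration) is exactly `flash_ms + latency_ms`.
#'
#' @param latency_ms planted latency from flash to minimum pupil-size
#'   acceleration
#' @param constriction relative constriction amplitude (fraction of baseline)
#' @param baseline_au baseline pupil size
#' @param tau_ms sigmoid time constant
#' @param flash_ms flash onset within the trace
#' @param duration_ms trace length (baseline + >= 2 s post flash)
#' @param sample_rate Hz
#' @param noise_frac white-noise SD as a fraction of baseline
#' @return object of class `pupil_trace`: list(t_ms, diameter, flash_ms,
#'   baseline_window, true_min_accel_ms)
#' @export
simulate_plr_trial <- function(latency_ms, constriction,
                               baseline_au = 1000, tau_ms = 100,
                               flash_ms = 500, duration_ms = 2500,
                               sample_rate = 100, noise_frac = 0) {
  stopifnot(duration_ms - flash_ms >= 2000)
  dt <- 1000 / sample_rate
  t_ms <- seq(0, duration_ms - dt, by = dt)
  t0 <- flash_ms + latency_ms - LOGISTIC_ACCEL_ARGMIN * tau_ms
  d <- baseline_au * (1 - constriction * invlogit((t_ms - t0) / tau_ms))
  if (noise_frac > 0)
    d <- d + stats::rnorm(length(d), 0, noise_frac * baseline_au)
  structure(list(t_ms = t_ms, diameter = d, flash_ms = flash_ms,
                 baseline_window = c(0, flash_ms),
                 true_min_accel_ms = flash_ms + latency_ms),
            class = "pupil_trace")
}

#' Simulate clinical scores coupled to the face latent
#'
#' Each configured score is `r * z + sqrt(1 - r^2) * noise` on a standardised
#' scale (z = within-group standardised T1 face latent), rescaled to the
#' instrument's group mean/SD and rounded to integers last. The weight `r`
#' is the Gaussian-copula solution `r = 2 * sin(pi * rho_s / 6)` so the
#' population Spearman correlation with the latent equals the target.
#'
#' @param truth ground-truth table with `participant_id`, `group`, `site`,
#'   `age_years`, `iq` and `face_latent_t1`
#' @param config an [sim_config()] object
#' @return data.table: participant_id, group, age_years, iq, site, scores
#' @export
simulate_clinical_scores <- function(truth, config) {
  rho <- config$clinical_rho_targets
  if (any(abs(rho) >= 1)) stop_config("|rho| targets must be < 1")
  scales <- default_clinical_scales()
  out <- data.table::as.data.table(
    truth[, c("participant_id", "group", "age_years", "iq", "site")])
  z <- truth$face_latent_t1
  n <- length(z)
  for (sc in names(rho)) {
    r <- 2 * sin(pi * rho[[sc]] / 6)
    raw <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    sl <- scales[scales$score == sc, ]
    if (nrow(sl)) {
      m <- sl$mean[match(truth$group, sl$group)]
      s <- sl$sd[match(truth$group, sl$group)]
    } else { m <- 50; s <- 10 }
    out[, (sc) := round(m + s * raw)]
  }
  out[]
}

#' Write a simulated cohort to delimited text files
#'
#' Emits gaze.csv, clinical.csv, sessions.csv, truth.csv and config.json
#' into `dir`.
#'
#' @param cohort an `omi_cohort` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$gaze, file.path(dir, "gaze.csv"))
  data.table::fwrite(cohort$clinical, file.path(dir, "clinical.csv"))
  data.table::fwrite(cohort$sessions, file.path(dir, "sessions.csv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  cfg <- cohort$config
  cfg$face_targets <- as.list(cfg$face_targets)
  cfg$trial_plan <- as.list(cfg$trial_plan)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
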