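# Calibration of logit-scale latent distributions so that the *realized*
# looking percentages downstream of ROI derivation match configured group
# means/SDs.
#
# Two corrections connect the latent stationary probability p to the realized
# %Face a deriver measures:
#   1. A constant participant-day calibration offset v = (dx, dy) shifts all
#      emitted coordinates. Face-drawn points (uniform in the face rect of
#      width Wf, height Hf) stay inside the original rect with probability
#      rho(v) = max(0, 1 - |dx|/Wf) * max(0, 1 - |dy|/Hf); points drawn
#      outside the face drift into it with probability ~ kappa * (1 - rho),
#      kappa = face_area / (screen_area - face_area); and outside points near
#      the screen edge are pushed off screen (removed from the valid-time
#      denominator) with probability phi(v).
#   2. A per-trial logit disturbance (trial_noise_sd) makes the participant's
#      expected realized fraction a smoothed function of the latent.
# Expectations over both are evaluated with Gauss-Hermite quadrature and the
# latent mean/SD solved by Nelder-Mead. The Markov sampling noise of finite
# trials is mean-zero and is deliberately not folded into the SD target.

realized_face_fraction <- function(p, rho, kappa, phi) {
  face_mass <- p * rho + (1 - p) * kappa * (1 - rho)
  valid_mass <- p + (1 - p) * (1 - phi)
  face_mass / valid_mass
}

# Expected retention/leakage terms for a group given the per-axis offset SD
# (degrees), using E|d| = sigma * sqrt(2/pi) for a centred normal axis.
offset_correction <- function(offset_sd_deg, px_per_degree, face_w, face_h,
                              screen_w, screen_h) {
  ed <- offset_sd_deg * px_per_degree * sqrt(2 / pi)
  rho <- max(0, 1 - ed / face_w) * max(0, 1 - ed / face_h)
  a <- face_w * face_h
  A <- screen_w * screen_h
  kappa <- a / (A - a)
  phi <- (1 - (1 - ed / screen_w) * (1 - ed / screen_h)) * A / (A - a)
  list(rho = rho, kappa = kappa, phi = min(phi, 1))
}

#' Solve latent logit mean/SD for a realized percentage target
#'
#' Finds (mu, sigma) of the participant-level logit latent such that the
#' population mean and SD of the expected realized looking fraction match
#' `mean_pct` / `sd_pct` (percentage scale), given the ROI retention terms
#' and the per-trial logit noise.
#'
#' @param mean_pct,sd_pct realized targets in percentage points
#' @param rho,kappa,phi offset-correction terms (identity: 1, 0, 0)
#' @param trial_noise_sd per-trial logit disturbance SD
#' @return list(mu, sigma) on the logit scale
#' @keywords internal
calibrate_logit <- function(mean_pct, sd_pct, rho = 1, kappa = 0, phi = 0,
                            trial_noise_sd = 0) {
  gh_b <- gauss_hermite_normal(21L)
  gh_w <- gauss_hermite_normal(11L)
  m0 <- mean_pct / 100; s0 <- sd_pct / 100
  # participant expected realized fraction given latent theta
  expect_realized <- function(theta) {
    if (trial_noise_sd > 0) {
      p <- invlogit(outer(theta, gh_w$z * trial_noise_sd, `+`))
      drop(realized_face_fraction(p, rho, kappa, phi) %*% gh_w$w)
    } else {
      realized_face_fraction(invlogit(theta), rho, kappa, phi)
    }
  }
  moments <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    r <- expect_realized(mu + sigma * gh_b$z)
    m <- sum(gh_b$w * r)
    v <- sum(gh_b$w * (r - m)^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    ms <- moments(par)
    (ms[1] - m0)^2 + (ms[2] - s0)^2
  }
  # delta-method start values
  mu0 <- logit(min(max(m0, 1e-4), 1 - 1e-4))
  sig0 <- s0 / (m0 * (1 - m0))
  fit <- stats::optim(c(mu0, log(sig0)), obj,
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-8)
    warning("logit calibration did not fully converge (residual ",
            signif(sqrt(fit$value), 3), ")")
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Expected measurement variance of the realized task-average composite at
# one timepoint (fraction^2 scale), from the dwell chain and per-trial
# disturbance. For a two-state chain with in-state dwell tau_in and
# stationary p, the time-average over a trial of length T has variance
# ~ 2 p (1-p) tau_c / T with relaxation time tau_c = tau_in (1-p); the
# per-trial logit disturbance contributes (p (1-p) sigma_tr)^2 by the delta
# method. Averaging n trials divides by n^2 per trial sum; the three-task
# composite divides by 9. Used to inflate the latent trait share so that
# the *downstream* two-occasion ICC matches the configured value.
measurement_variance_omi <- function(cfg, group) {
  plan <- cfg$trial_plan
  tau_in <- cfg$dwell_mean_ms / 1000
  total <- 0
  for (task in TASKS_FACE) {
    tgt <- cfg$face_targets
    p <- tgt$mean_pct[tgt$task == task & tgt$group == group] / 100
    rows <- plan[plan$task == task, , drop = FALSE]
    per_trial <- rep(rows$duration_s, rows$n_trials * 2L)  # both days
    v_tr <- 2 * p * (1 - p) * tau_in * (1 - p) / per_trial +
      (p * (1 - p) * cfg$trial_noise_sd)^2
    total <- total + sum(v_tr) / length(per_trial)^2
  }
  total / 9
}

latent_variance_omi <- function(cfg, group) {
  tgt <- cfg$face_targets
  s <- tgt$sd_pct[tgt$task %in% TASKS_FACE & tgt$group == group] / 100
  lam <- cfg$shared_task_fraction
  (sum(s^2) + 2 * lam * (s[1] * s[2] + s[1] * s[3] + s[2] * s[3])) / 9
}

# trait fraction to plant on the latent scale so that the realized ICC
# (latent + measurement noise) equals the configured target
effective_trait_fraction <- function(cfg, group) {
  f <- cfg$trait_variance_fraction
  v_lat <- latent_variance_omi(cfg, group)
  v_meas <- measurement_variance_omi(cfg, group)
  min(f * (1 + v_meas / v_lat), 0.98)
}

# Calibrate every (group, task) cell of the face-target table against the
# configured ROI geometry. BM side preference needs no offset correction
# because %Bio is a ratio of two large panels losing edge mass symmetrically.
calibrate_cohort_latents <- function(cfg, roi_sets) {
  scr <- cfg$screen
  out <- cfg$face_targets
  out$mu <- NA_real_; out$sigma <- NA_real_
  for (i in seq_len(nrow(out))) {
    task <- out$task[i]; grp <- out$group[i]
    if (task == "BM") {
      corr <- list(rho = 1, kappa = 0, phi = 0)
    } else {
      rois <- rois_for(roi_sets, task, 1L)
      fr <- rois[rois$label == "face", ][1, ]
      corr <- offset_correction(cfg$cal_error_scale[[grp]],
                                scr$px_per_degree,
                                fr$x1 - fr$x0, fr$y1 - fr$y0,
                                scr$width_px, scr$height_px)
    }
    cal <- calibrate_logit(out$mean_pct[i], out$sd_pct[i],
                           rho = corr$rho, kappa = corr$kappa,
                           phi = corr$phi,
                           trial_noise_sd = cfg$trial_noise_sd)
    out$mu[i] <- cal$mu; out$sigma[i] <- cal$sigma
  }
  out
}
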