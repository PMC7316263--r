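#' Platform trajectory configuration
#'
#' Parameters of the pre-programmed platform motion protocols: the
#' continuous-perturbation sinusoid (amplitude `A` = 2.5 deg at `f` =
#' 0.2 Hz, anteroposterior lagging mediolateral by a quarter period), the
#' random-perturbation pulse train (Gaussian-profile tilts peaking at 6 deg
#' 330 ms after onset, three repetitions per direction in random order,
#' onset gaps drawn around 4.7 +- 0.6 s with a 4 s floor), and the
#' unstable-platform tilt bound (10 deg per direction).
#'
#' @param exercise_id Optional exercise the config is meant for.
#' @param A Sinusoid amplitude, deg.
#' @param f Sinusoid frequency, Hz.
#' @param perturbation_peak Pulse peak tilt, deg.
#' @param time_to_peak Pulse onset-to-peak time, s.
#' @param pulse_sigma Gaussian pulse width, s; default `time_to_peak / 3`
#'   so the onset sits about three sigma before the peak.
#' @param interval_mean,interval_sd,interval_min Onset-gap distribution:
#'   normal mean/SD with a hard lower truncation, s.
#' @param reps_per_direction Pulses per direction (default 3).
#' @param max_unstable_tilt Tilt bound of the unstable platform, deg.
#' @param lead_in_s Quiet time before the first pulse, s.
#' @return List of class `trajectory_config`.
#' @export
trajectory_config <- function(exercise_id = NA_integer_, A = 2.5, f = 0.2,
                              perturbation_peak = 6, time_to_peak = 0.33,
                              pulse_sigma = time_to_peak / 3,
                              interval_mean = 4.7, interval_sd = 0.6,
                              interval_min = 4.0, reps_per_direction = 3,
                              max_unstable_tilt = 10, lead_in_s = 3) {
  vals <- c(A = A, f = f, perturbation_peak = perturbation_peak,
            time_to_peak = time_to_peak, pulse_sigma = pulse_sigma,
            interval_mean = interval_mean, interval_sd = interval_sd,
            interval_min = interval_min, reps_per_direction = reps_per_direction,
            max_unstable_tilt = max_unstable_tilt, lead_in_s = lead_in_s)
  if (any(vals <= 0)) {
    abort("all trajectory parameters must be positive",
          class = "fallrisk_error_validation")
  }
  if (interval_min > interval_mean) {
    abort("`interval_min` must not exceed `interval_mean`",
          class = "fallrisk_error_validation")
  }
  structure(as.list(c(list(exercise_id = exercise_id), as.list(vals))),
            class = "trajectory_config")
}

#' Latent subject profile for session simulation
#'
#' @param instability Positive scalar scaling CoP/trunk noise amplitudes;
#'   1 is an average subject, larger is shakier.
#' @param response_gain Peak trunk response to a platform pulse, deg.
#' @param settling_tau Time constant of the trunk response, s.
#' @param ftss_stand_s,ftss_sit_s Nominal stand-up and sit-down phase
#'   durations, s.
#' @param los_reach Named reaches (cm) for forward/backward/left/right.
#' @param weight_n Body weight on the platform, N.
#' @return List of class `subject_profile`.
#' @export
subject_profile <- function(instability = 1, response_gain = 3,
                            settling_tau = 0.18,
                            ftss_stand_s = 1.2, ftss_sit_s = 1.4,
                            los_reach = c(forward = 8, backward = 5,
                                          left = 6, right = 6),
                            weight_n = 700) {
  if (any(c(instability, response_gain, settling_tau, ftss_stand_s,
            ftss_sit_s, los_reach, weight_n) <= 0)) {
    abort("all profile parameters must be positive",
          class = "fallrisk_error_validation")
  }
  structure(list(instability = instability, response_gain = response_gain,
                 settling_tau = settling_tau, ftss_stand_s = ftss_stand_s,
                 ftss_sit_s = ftss_sit_s, los_reach = los_reach,
                 weight_n = weight_n),
            class = "subject_profile")
}

rtruncnorm_min <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lower
  }
  out
}

#' Random-perturbation pulse schedule
#'
#' Draws the pulse order (each direction `reps_per_direction` times,
#' shuffled) and the onset times: the first onset after the lead-in, then
#' gaps from a normal(interval_mean, interval_sd) truncated below at
#' interval_min.
#'
#' @param config A [trajectory_config()].
#' @param seed Optional integer seed.
#' @return Tibble: `onset_time` (s), `direction`.
#' @export
generate_perturbation_schedule <- function(config = trajectory_config(),
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dirs <- sample(rep(c("forward", "left", "right"), config$reps_per_direction))
  gaps <- rtruncnorm_min(length(dirs) - 1, config$interval_mean,
                         config$interval_sd, config$interval_min)
  tibble(onset_time = config$lead_in_s + cumsum(c(0, gaps)),
         direction = dirs)
}

gaussian_pulse <- function(t, onset, peak, time_to_peak, sigma) {
  peak * exp(-((t - onset - time_to_peak)^2) / (2 * sigma^2)) *
    as.numeric(t >= onset)   # pulse starts at the scheduled onset
}

#' Pre-programmed platform angle trajectory
#'
#' Generates the commanded platform tilt for the three motorized protocols:
#' the Exercise-5 circular sinusoid, the Exercise-6 Gaussian pulse train
#' (with its ground-truth schedule), and the Exercise-4 bounded random walk
#' that emulates the subject-driven unstable platform.
#'
#' @param config A [trajectory_config()].
#' @param exercise_id 4, 5 or 6.
#' @param duration_s Trajectory length, s. For Exercise 6, `NULL` (default)
#'   sizes the trajectory to fit the full schedule plus a 2.5 s tail; an
#'   explicit duration too short for the schedule is an error.
#' @param fs Sampling rate, Hz (default 30).
#' @param seed Optional integer seed.
#' @param walk_step_deg Exercise-4 random-walk step SD, deg (default 0.4).
#' @return List: `trajectory` (tibble `t`, `theta_ml`, `theta_ap`) and
#'   `schedule` (Exercise 6 only, else `NULL`).
#' @export
generate_platform_trajectory <- function(config = trajectory_config(),
                                         exercise_id, duration_s = NULL,
                                         fs = 30, seed = NULL,
                                         walk_step_deg = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  if (exercise_id == 5) {
    duration_s <- duration_s %||% 31
    t <- seq(0, duration_s, by = 1 / fs)
    traj <- tibble(t = t,
                   theta_ml = config$A * sin(2 * pi * config$f * t),
                   theta_ap = config$A * sin(2 * pi * config$f * t - pi / 2))
    return(list(trajectory = traj, schedule = NULL))
  }
  if (exercise_id == 4) {
    duration_s <- duration_s %||% 31
    t <- seq(0, duration_s, by = 1 / fs)
    walk <- function() {
      x <- numeric(length(t))
      for (i in 2:length(t)) {
        x[i] <- max(-config$max_unstable_tilt,
                    min(config$max_unstable_tilt,
                        x[i - 1] + rnorm(1, 0, walk_step_deg)))
      }
      x
    }
    traj <- tibble(t = t, theta_ml = walk(), theta_ap = walk())
    return(list(trajectory = traj, schedule = NULL))
  }
  if (exercise_id == 6) {
    schedule <- generate_perturbation_schedule(config)
    needed <- max(schedule$onset_time) + 2.5
    duration_s <- duration_s %||% needed
    if (duration_s < needed) {
      abort(sprintf("duration %.1f s too short for the pulse schedule (needs %.1f s)",
                    duration_s, needed),
            class = "fallrisk_error_validation")
    }
    t <- seq(0, duration_s, by = 1 / fs)
    theta_ml <- numeric(length(t))
    theta_ap <- numeric(length(t))
    for (i in seq_len(nrow(schedule))) {
      pulse <- gaussian_pulse(t, schedule$onset_time[i], config$perturbation_peak,
                              config$time_to_peak, config$pulse_sigma)
      # forward = toes down (negative AP); right/left from the ML sign
      switch(schedule$direction[i],
             forward = { theta_ap <- theta_ap - pulse },
             right = { theta_ml <- theta_ml + pulse },
             left = { theta_ml <- theta_ml - pulse })
    }
    return(list(trajectory = tibble(t = t, theta_ml = theta_ml, theta_ap = theta_ap),
                schedule = schedule))
  }
  abort("`exercise_id` must be 4, 5 or 6 for a platform trajectory",
        class = "fallrisk_error_dispatch")
}

# stationary AR(1) with unit-time mean reversion; sd is the stationary SD
ar1_series <- function(n, dt, sd, tau = 1) {
  phi <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1, 0, innov_sd)
  x
}

ftss_cycle_keyframes <- function(t0, lean, rise, hold, sitlean, descend, rest,
                                 pitch_peak = 25, pitch_stand = 5) {
  # continuous-time boundary truths implied by the segmentation definitions
  list(times = c(t0, t0 + lean, t0 + lean + rise, t0 + lean + rise + hold,
                 t0 + lean + rise + hold + sitlean,
                 t0 + lean + rise + hold + sitlean + descend,
                 t0 + lean + rise + hold + sitlean + descend + rest),
       truth = tibble(
         stand_start = t0 + lean * 15 / pitch_peak,
         stand_end = t0 + lean + rise * max((0.95 - 0.3) / 0.7,
                                            (pitch_peak - 15) / (pitch_peak - pitch_stand)),
         sit_start = t0 + lean + rise + hold +
           sitlean * (15 - pitch_stand) / (pitch_peak - pitch_stand),
         sit_end = t0 + lean + rise + hold + sitlean + descend * 0.9))
}

#' Simulate one session recording
#'
#' Generates a protocol-compliant recording for any of the seven exercises,
#' together with the ground truth needed by oracle tests. The CoP is a
#' seeded stationary mean-reverting (first-order autoregressive) planar
#' process whose standard deviation scales with the subject's instability;
#' the torque channels are back-computed from the target CoP and the noisy
#' vertical force so that [compute_cop()] recovers the generated CoP
#' exactly. Trunk angles follow a scaled copy of the CoP plus independent
#' noise; trunk acceleration is white noise scaled by instability. The
#' exercise-specific structure is added on top: limits-of-stability reach
#' ramps (Exercise 1), platform motion (Exercises 4-6), per-pulse damped
#' trunk responses of the form g (s/tau) exp(1 - s/tau) (Exercise 6), and
#' trunk-pitch / load-transfer trapezoids for the five sit-to-stand cycles
#' (Exercise 7).
#'
#' @param profile A [subject_profile()].
#' @param exercise_id 1-7.
#' @param config A [trajectory_config()].
#' @param seed Optional integer seed.
#' @param fs Sampling rate, Hz (default 30).
#' @param subject_id Carried into the recording metadata.
#' @return List: `recording` (a [new_recording()]) and `truth`, whose
#'   content depends on the exercise: the true CoP (`cop`); `los_reach`;
#'   the pulse `schedule` plus analytic `settling_time` (Exercise 6); the
#'   continuous-time `phase_truth` boundaries (Exercise 7).
#' @export
generate_session <- function(profile = subject_profile(), exercise_id,
                             config = trajectory_config(), seed = NULL,
                             fs = 30, subject_id = "S01") {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs
  ins <- profile$instability

  duration_s <- switch(as.character(exercise_id),
                       "1" = 82, "2" = 31, "3" = 31, "4" = 31, "5" = 31,
                       "6" = NA, "7" = NA)
  platform <- NULL
  schedule <- NULL
  if (exercise_id %in% 4:6) {
    platform <- generate_platform_trajectory(config, exercise_id,
                                             duration_s = if (is.na(duration_s)) NULL else duration_s,
                                             fs = fs)
    schedule <- platform$schedule
    t <- platform$trajectory$t
  } else if (exercise_id == 7) {
    # build the five-cycle schedule first, then the time base
    lean <- 0.5; rise <- 0.6 * profile$ftss_stand_s
    hold <- 1.0; sitlean <- 0.5; descend <- 0.7 * profile$ftss_sit_s
    rest <- 0.8
    t0 <- 2
    cyc <- list()
    for (r in 1:5) {
      jit <- function(x) x * runif(1, 0.9, 1.1)
      kf <- ftss_cycle_keyframes(t0, jit(lean), jit(rise), jit(hold),
                                 jit(sitlean), jit(descend), jit(rest))
      cyc[[r]] <- kf
      t0 <- kf$times[7]
    }
    duration_s <- t0 + 1
    t <- seq(0, ceiling(duration_s * fs) / fs, by = dt)
  } else {
    t <- seq(0, duration_s, by = dt)
  }
  n <- length(t)

  # latent CoP (cm): AR(1) sway plus exercise-specific structure
  cop_x <- ar1_series(n, dt, sd = 0.30 * ins)
  cop_y <- ar1_series(n, dt, sd = 0.40 * ins)
  truth <- list()
  if (exercise_id == 1) {
    # reach ramps: quiet 3 s, then forward / backward / left / right
    reach <- profile$los_reach
    seg <- function(start, dx, dy, rise = 4, hold = 8, back = 4) {
      shape <- stats::approx(x = c(start, start + rise, start + rise + hold,
                                   start + rise + hold + back),
                             y = c(0, 1, 1, 0), xout = t, yleft = 0, yright = 0)$y
      cbind(dx * shape, dy * shape)
    }
    moves <- seg(3, 0, reach["forward"]) + seg(22, 0, -reach["backward"]) +
      seg(41, -reach["left"], 0) + seg(60, reach["right"], 0)
    cop_x <- 0.1 * cop_x + moves[, 1]
    cop_y <- 0.1 * cop_y + moves[, 2]
    truth$los_reach <- reach
  }
  if (exercise_id %in% 4:6) {
    truth$platform <- platform$trajectory
  }

  # weaker trunk-sway coupling in the pulse exercise so the reactive trunk
  # response dominates the background sway
  coupling <- if (exercise_id == 6) 0.3 else 1.5
  trunk_noise <- if (exercise_id == 6) 0.08 else 0.15
  trunk_roll <- coupling * cop_x + rnorm(n, 0, trunk_noise * ins)
  trunk_pitch <- coupling * cop_y + rnorm(n, 0, trunk_noise * ins)

  if (exercise_id == 6) {
    u_settle <- stats::uniroot(function(u) u * exp(1 - u) - 0.2, c(1, 20))$root
    truth$settling_time <- u_settle * profile$settling_tau
    for (i in seq_len(nrow(schedule))) {
      s <- t - schedule$onset_time[i]
      resp <- profile$response_gain * (s / profile$settling_tau) *
        exp(1 - s / profile$settling_tau)
      resp[s < 0] <- 0
      switch(schedule$direction[i],
             forward = { trunk_pitch <- trunk_pitch + resp },
             right = { trunk_roll <- trunk_roll + resp },
             left = { trunk_roll <- trunk_roll - resp })
    }
    truth$schedule <- schedule
  }

  fz <- profile$weight_n + rnorm(n, 0, 3)
  seat_load <- rep(0, n)

  if (exercise_id == 7) {
    W <- profile$weight_n
    pitch <- numeric(n); seatf <- numeric(n); basef <- numeric(n)
    # piecewise-linear profiles from the keyframes of each cycle
    pitch_t <- c(0); pitch_v <- c(0)
    seat_t <- c(0); seat_v <- c(0.7)
    for (kf in cyc) {
      tt <- kf$times
      pitch_t <- c(pitch_t, tt[1], tt[2], tt[3], tt[4], tt[5], tt[6])
      pitch_v <- c(pitch_v, 0, 25, 5, 5, 25, 0)
      seat_t <- c(seat_t, tt[2], tt[3], tt[5], tt[6])
      seat_v <- c(seat_v, 0.7, 0, 0, 0.7)
    }
    pitch <- stats::approx(pitch_t, pitch_v, xout = t, yleft = 0, yright = 0,
                           rule = 2)$y
    seat_frac <- stats::approx(seat_t, seat_v, xout = t, rule = 2)$y
    seatf <- W * seat_frac
    basef <- W - seatf   # total vertical load conserved across the transfer
    trunk_pitch <- pitch
    trunk_roll <- rnorm(n, 0, 0.1 * ins)
    fz <- basef
    seat_load <- seatf
    cop_x <- 0.05 * cop_x
    cop_y <- 0.05 * cop_y
    truth$phase_truth <- bind_rows(purrr::map(cyc, "truth"))
  }

  rec <- new_recording(
    tibble(t = t,
           fz = fz,
           mx = cop_x / 100 * fz,
           my = cop_y / 100 * fz,
           theta_ml = if (exercise_id %in% 4:6) platform$trajectory$theta_ml else rep(0, n),
           theta_ap = if (exercise_id %in% 4:6) platform$trajectory$theta_ap else rep(0, n),
           trunk_roll = trunk_roll,
           trunk_pitch = trunk_pitch,
           acc_x = rnorm(n, 0, 0.08 * ins),
           acc_y = rnorm(n, 0, 0.08 * ins),
           acc_z = rnorm(n, 0, 0.08 * ins),
           seat_load = seat_load),
    exercise_id = exercise_id, sampling_rate = fs, subject_id = subject_id)
  truth$cop <- new_cop_trace(t, cop_x, cop_y)
  list(recording = rec, truth = truth)
}

#' Extract the canonical robotic feature row from a subject's sessions
#'
#' Runs the full extraction pipeline on a list of session recordings (one
#' per exercise) and returns the per-subject feature row under the
#' canonical `ex{N}_{source}_{metric}` naming of
#' [robotic_feature_catalogue()]. Missing exercises yield `NA` features.
#'
#' @param sessions Named or unnamed list of [new_recording()] objects.
#' @param subject_id Optional; defaults to the first recording's metadata.
#' @param lever_arm_m,load_floor Passed to the stabilometric indicators.
#' @return One-row tibble: `subject_id` plus the 46 canonical features.
#' @export
extract_features <- function(sessions, subject_id = NULL, lever_arm_m = 0.5,
                             load_floor = 10) {
  by_ex <- setNames(vector("list", 7), as.character(1:7))
  for (s in sessions) by_ex[[as.character(exercise_id(s))]] <- s
  subject_id <- subject_id %||% attr(sessions[[1]], "subject_id")
  out <- tibble(subject_id = subject_id)
  nacol <- function(names) {
    for (nm in names) out[[nm]] <<- NA_real_
  }
  # exercise 1: limits of stability
  if (!is.null(by_ex[["1"]])) {
    los <- los_max_displacement(compute_cop(by_ex[["1"]], load_floor))
    out$ex1_los_forward <- los$forward; out$ex1_los_backward <- los$backward
    out$ex1_los_left <- los$left; out$ex1_los_right <- los$right
  } else nacol(paste0("ex1_los_", c("forward", "backward", "left", "right")))
  # exercises 2-5: sway metrics
  for (ex in 2:5) {
    src <- if (ex == 4) "proj" else "cop"
    cols <- paste0("ex", ex, "_", c(paste0(src, c("_sa", "_sp", "_apo", "_mlo")),
                                    "trunk_apo", "trunk_mlo", "trunk_va"))
    rec <- by_ex[[as.character(ex)]]
    if (!is.null(rec)) {
      m <- balance_metrics(rec, lever_arm_m = lever_arm_m, load_floor = load_floor)
      vals <- c(m$sway_area, m$sway_path, m$apo, m$mlo,
                m$trunk_apo, m$trunk_mlo, m$trunk_variability)
      for (i in seq_along(cols)) out[[cols[i]]] <- vals[i]
    } else nacol(cols)
  }
  # exercise 6: perturbation responses
  ex6_cols <- paste0("ex6_", c("osc_time_forward", "osc_time_left", "osc_time_right",
                               "max_tilt_ap", "max_tilt_ml",
                               "apo_forward", "apo_left", "apo_right",
                               "mlo_forward", "mlo_left", "mlo_right"))
  if (!is.null(by_ex[["6"]])) {
    rec <- by_ex[["6"]]
    events <- detect_perturbations(rec)
    valid <- events[!events$truncated, , drop = FALSE]
    responses <- purrr::map_dfr(seq_len(nrow(valid)),
                                ~ perturbation_response(rec, valid[.x, ]))
    out <- bind_cols(out, aggregate_perturbation_features(responses))
  } else nacol(ex6_cols)
  # exercise 7: sit-to-stand durations
  if (!is.null(by_ex[["7"]])) {
    out <- bind_cols(out, ftss_durations(segment_ftss(by_ex[["7"]])))
  } else nacol(paste0("ex7_", c("total_duration", "mean_stand", "mean_sit")))
  out[, c("subject_id", robotic_feature_catalogue())]
}

#' Cohort simulation configuration
#'
#' Defines a synthetic study cohort: sample size and faller prevalence
#' matching the study structure (about a third of subjects fall within the
#' follow-up year), group-specific clinical variable distributions
#' parameterized from the published baseline table, and a correlated
#' Gaussian block of standardized robotic features whose faller/non-faller
#' mean shifts carry the discriminative signal.
#'
#' @param n Cohort size (default 96).
#' @param prevalence Faller proportion (default 1/3).
#' @param effect_sizes Named standardized mean differences
#'   (faller - non-faller) for robotic features; defaults to
#'   [default_effect_sizes()].
#' @param feature_correlation Exchangeable correlation among robotic
#'   features (default 0.2).
#' @param clinical_signal Keep the published faller/non-faller differences
#'   in the clinical variables (default TRUE); `FALSE` equalizes the two
#'   groups so all signal sits in the robotic block.
#' @param seed Integer seed.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 96, prevalence = 1 / 3,
                              effect_sizes = default_effect_sizes(),
                              feature_correlation = 0.2,
                              clinical_signal = TRUE, seed = 1) {
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1)", class = "fallrisk_error_validation")
  }
  if (abs(feature_correlation) >= 1) {
    abort("|feature_correlation| must be < 1", class = "fallrisk_error_validation")
  }
  structure(list(n = n, prevalence = prevalence, effect_sizes = effect_sizes,
                 feature_correlation = feature_correlation,
                 clinical_signal = clinical_signal, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Default robotic effect sizes for cohort simulation
#'
#' Standardized faller minus non-faller mean shifts following the observed
#' direction of group differences: positive shifts on the
#' unstable-platform and continuous-perturbation oscillation ranges and
#' variabilities and on the mediolateral perturbation tilt, and a negative
#' shift on the forward limits-of-stability reach. All other features
#' carry no signal.
#'
#' @param magnitude Common |shift| in SD units (default 0.5, a moderate
#'   group difference typical of posturographic faller contrasts).
#' @return Named numeric vector over [robotic_feature_catalogue()].
#' @export
default_effect_sizes <- function(magnitude = 0.5) {
  es <- setNames(rep(0, length(robotic_feature_catalogue())),
                 robotic_feature_catalogue())
  up <- c("ex4_trunk_apo", "ex4_proj_apo", "ex4_trunk_va",
          "ex5_cop_apo", "ex5_cop_mlo", "ex5_trunk_va", "ex6_max_tilt_ml")
  es[up] <- magnitude
  es["ex1_los_forward"] <- -magnitude
  es
}

#' Scale robotic effect sizes to a target theoretical AUC
#'
#' Under the class-conditional Gaussian model with common exchangeable
#' covariance, the optimal discriminant achieves
#' AUC = Phi(sqrt(delta' Sigma^-1 delta / 2)); this rescales a shift
#' pattern so that theoretical AUC equals `target_auc`.
#'
#' @param effect_sizes Named shift vector (the pattern).
#' @param rho Exchangeable correlation.
#' @param target_auc Desired theoretical AUC.
#' @return Rescaled effect-size vector.
#' @export
scale_effects_to_auc <- function(effect_sizes, rho, target_auc) {
  delta_target <- sqrt(2) * qnorm(target_auc)
  current <- mahalanobis_shift(effect_sizes, rho)
  if (current == 0) {
    abort("effect pattern is all zero; cannot scale",
          class = "fallrisk_error_validation")
  }
  effect_sizes * delta_target / current
}

mahalanobis_shift <- function(delta, rho) {
  p <- length(delta)
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  sqrt(drop(t(delta) %*% solve(sigma, delta)))
}

# group-specific clinical sampling parameters (faller; non-faller)
clinical_param_defaults <- function(signal = TRUE) {
  p <- list(
    age = list(f = c(79.1, 6.6), n = c(76.2, 6.3)),
    gait_speed = list(f = c(0.95, 0.22), n = c(1.08, 0.28)),
    history = list(f = 0.875, n = 0.625),
    n_drugs = list(f = c(3.88, 2.17), n = c(3.73, 2.61)),
    female = list(f = 0.688, n = 0.625),
    tug = list(f = c(9.84, 2.57), n = c(9.63, 3.53)),
    poma = list(f = c(27.06, 1.93), n = c(26.35, 2.78)),
    sppb = list(f = c(7.58, 2.55), n = c(8.68, 2.37)))
  if (!signal) {
    p <- purrr::map(p, function(v) {
      pooled <- if (length(v$f) == 2) (v$f + v$n) / 2 else (v$f + v$n) / 2
      list(f = pooled, n = pooled)
    })
  }
  p
}

#' Simulate a feature-level cohort
#'
#' Draws outcomes Bernoulli(prevalence), clinical variables from
#' group-specific distributions parameterized by the published baseline
#' characteristics (ages and gait speeds normal, gait speed truncated above
#' 0.2 m/s, drug counts rounded and clipped at 0, fall history and sex
#' Bernoulli, mobility scores clipped to instrument ranges), and a
#' standardized robotic feature block from a multivariate normal with
#' exchangeable correlation and faller mean shifts given by the effect
#' sizes. The generative truth (shift vector, optimal linear discriminant,
#' and the theoretical AUC of the robotic block) is attached.
#'
#' @param config A [cohort_sim_config()].
#' @return A `cohort_table` tibble with attribute `generative_truth`
#'   (list: `effect_sizes`, `rho`, `discriminant`, `theoretical_auc`).
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  set.seed(config$seed)
  n <- config$n
  faller <- rbinom(n, 1, config$prevalence)
  if (sum(faller) < 2 || sum(1 - faller) < 2) {
    abort("degenerate cohort draw: fewer than 2 subjects in a group; increase n",
          class = "fallrisk_error_validation")
  }
  cp <- clinical_param_defaults(config$clinical_signal)
  draw2 <- function(par, trunc_min = -Inf, round_it = FALSE,
                    clip = c(-Inf, Inf)) {
    m <- ifelse(faller == 1, par$f[1], par$n[1])
    s <- ifelse(faller == 1, par$f[2], par$n[2])
    x <- rnorm(n, m, s)
    bad <- x < trunc_min
    while (any(bad)) {
      x[bad] <- rnorm(sum(bad), m[bad], s[bad])
      bad <- x < trunc_min
    }
    if (round_it) x <- round(x)
    pmin(pmax(x, clip[1]), clip[2])
  }
  drawb <- function(par) rbinom(n, 1, ifelse(faller == 1, par$f, par$n))
  clinical <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = pmax(draw2(cp$age), 65),
    sex = drawb(cp$female),
    history_of_falling = drawb(cp$history),
    n_drugs = draw2(cp$n_drugs, round_it = TRUE, clip = c(0, Inf)),
    tug = draw2(cp$tug, trunc_min = 2),
    poma = draw2(cp$poma, round_it = TRUE, clip = c(0, 28)),
    sppb = draw2(cp$sppb, round_it = TRUE, clip = c(0, 12)),
    gait_speed = draw2(cp$gait_speed, trunc_min = 0.2))

  feats <- robotic_feature_catalogue()
  p <- length(feats)
  delta <- setNames(rep(0, p), feats)
  delta[names(config$effect_sizes)] <- config$effect_sizes
  rho <- config$feature_correlation
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  x <- z + tcrossprod(faller, delta)
  colnames(x) <- feats
  robotic <- bind_cols(tibble(subject_id = clinical$subject_id), as_tibble(x))

  table <- assemble_cohort(clinical, robotic,
                           tibble(subject_id = clinical$subject_id,
                                  faller = faller))
  w <- solve(sigma, delta)
  attr(table, "generative_truth") <- list(
    effect_sizes = delta, rho = rho, discriminant = w,
    theoretical_auc = pnorm(mahalanobis_shift(delta, rho) / sqrt(2)))
  table
}

#' Synthetic sit-to-stand session with exact linear pitch ramps
#'
#' Builds a noise-free five-cycle sit-to-stand recording in which every
#' trunk-pitch transition moves by exactly `ramp_per_sample` degrees per
#' sample and the load channels switch consistently with the phase
#' definitions (full base load during standing, seat load back at its
#' seated baseline after each descent). Because the pitch grid is exact,
#' the trunk pitch at the detected stand onset must equal the first grid
#' value above the 15 degree threshold; useful for validating the
#' threshold semantics of [segment_ftss()].
#'
#' @param ramp_per_sample Pitch increment per sample, deg (default 0.1).
#' @param fs Sampling rate, Hz (default 30).
#' @param weight_n Body weight, N; seated split 70/30 seat/base.
#' @return List: `recording` and `truth` (tibble of cycle boundary times).
#' @export
ftss_ramp_session <- function(ramp_per_sample = 0.1, fs = 30, weight_n = 700) {
  S <- 0.7 * weight_n; B <- weight_n - S
  up1 <- seq(ramp_per_sample, 25, by = ramp_per_sample)
  down1 <- seq(25 - ramp_per_sample, 5, by = -ramp_per_sample)
  up2 <- seq(5 + ramp_per_sample, 25, by = ramp_per_sample)
  down2 <- seq(25 - ramp_per_sample, 0, by = -ramp_per_sample)
  hold <- 30
  pitch <- c(); seat <- c(); base <- c()
  add <- function(p, s, b) {
    pitch <<- c(pitch, p); seat <<- c(seat, rep(s, length(p)))
    base <<- c(base, rep(b, length(p)))
  }
  add(rep(0, 2 * fs), S, B)                     # seated baseline window
  truth <- list()
  for (r in 1:5) {
    i0 <- length(pitch)
    add(up1, S, B)                              # forward lean, still seated
    stand_end_i <- length(pitch) + which(down1 < 15)[1]
    add(down1, 0, weight_n)                     # rising: load on the base
    add(rep(5, hold), 0, weight_n)              # standing hold
    sit_start_i <- length(pitch) + which(up2 > 15)[1]
    add(up2, 0, weight_n)                       # lean to sit
    sit_end_i <- length(pitch) + which(down2 < 15)[1]
    add(down2, S, B)                            # descending: seat reloaded
    add(rep(0, hold), S, B)                     # seated rest
    truth[[r]] <- tibble(stand_start = (i0 + which(up1 > 15)[1] - 1) / fs,
                         stand_end = (stand_end_i - 1) / fs,
                         sit_start = (sit_start_i - 1) / fs,
                         sit_end = (sit_end_i - 1) / fs)
  }
  n <- length(pitch)
  rec <- new_recording(
    tibble(t = (seq_len(n) - 1) / fs, fz = base, mx = 0, my = 0,
           theta_ml = 0, theta_ap = 0, trunk_roll = 0, trunk_pitch = pitch,
           acc_x = 0, acc_y = 0, acc_z = 0, seat_load = seat),
    exercise_id = 7, sampling_rate = fs)
  list(recording = rec, truth = bind_rows(truth))
}
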