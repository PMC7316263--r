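test_that("perturbation detection recovers the simulated pulse schedule", {
  s <- generate_session(subject_profile(), 6, seed = 101)
  ev <- detect_perturbations(s$recording)
  truth <- dplyr::arrange(s$truth$schedule, onset_time)
  expect_equal(nrow(ev), 9)
  expect_equal(as.integer(table(ev$direction)[c("forward", "left", "right")]),
               rep(3L, 3))
  expect_equal(ev$direction, truth$direction)
  # back-tracked onsets sit within 3 samples (100 ms) of the scheduled onset
  expect_lt(max(abs(ev$onset_time - truth$onset_time)), 3.5 / 30)
  expect_false(any(ev$truncated))
})

test_that("a flat platform yields no events and a late pulse is flagged truncated", {
  flat <- make_recording(n = 300, exercise_id = 6)
  expect_equal(nrow(detect_perturbations(flat)), 0)

  # single pulse starting 0.5 s before the end of the recording
  n <- 300; t <- (seq_len(n) - 1) / 30
  onset <- t[n] - 0.5
  ap <- -6 * exp(-((t - onset - 0.33)^2) / (2 * 0.11^2)) * (t >= onset)
  late <- make_recording(n = n, exercise_id = 6, theta_ap = ap)
  ev <- detect_perturbations(late)
  expect_equal(nrow(ev), 1)
  expect_true(ev$truncated)
  expect_error(perturbation_response(late, ev[1, ]),
               class = "fallrisk_error_truncated")
})

test_that("onsets are robust to platform noise below half the threshold", {
  s <- generate_session(subject_profile(), 6, seed = 77)
  ev0 <- detect_perturbations(s$recording)
  noisy <- s$recording
  set.seed(5)
  noisy$theta_ml <- noisy$theta_ml + runif(nrow(noisy), -0.2, 0.2)
  noisy$theta_ap <- noisy$theta_ap + runif(nrow(noisy), -0.2, 0.2)
  ev1 <- detect_perturbations(noisy)
  expect_equal(nrow(ev1), nrow(ev0))
  expect_equal(ev1$direction, ev0$direction)
  expect_lt(max(abs(ev1$onset_time - ev0$onset_time)), 2.5 / 30)
})

test_that("every epoch lies inside the recording unless flagged truncated", {
  for (seed in c(11, 12, 13)) {
    s <- generate_session(subject_profile(), 6, seed = seed)
    ev <- detect_perturbations(s$recording)
    ok <- ev$epoch_start >= s$recording$t[1] - 1e-9 &
      ev$epoch_end <= max(s$recording$t) + 1e-9
    expect_true(all(ok | ev$truncated))
  }
})

test_that("oscillation time follows the band-and-hold rule with its cap", {
  fs <- 30; t <- (0:89) / fs
  # one-sample spike then immediate return: settles one sample after the spike
  ang <- numeric(90); ang[31] <- 5
  expect_equal(oscillation_time(t, ang, onset_time = t[28], baseline = 0),
               t[32] - t[28])
  # never re-enters the band: capped at the epoch length
  ramp <- pmin((t - 0.5) * 10, 8); ramp[t < 0.5] <- 0
  expect_equal(oscillation_time(t, ramp, onset_time = 0.5, baseline = 0), 1.5)
  # zero deviation returns 0
  expect_equal(oscillation_time(t, numeric(90), onset_time = 0.5, baseline = 0), 0)
})

test_that("oscillation time matches the analytic band crossing of a damped response", {
  fs <- 1000; t <- seq(0, 2, by = 1 / fs)
  tau <- 0.18; g <- 4
  resp <- g * (t / tau) * exp(1 - t / tau)
  # closed form: u e^(1-u) = band_frac at the post-peak branch
  u <- uniroot(function(u) u * exp(1 - u) - 0.2, c(1, 30))$root
  expect_equal(oscillation_time(t, resp, onset_time = 0, baseline = 0),
               u * tau, tolerance = 1.5 / fs)

  # monotone in the damping time constant
  taus <- c(0.08, 0.12, 0.16, 0.20, 0.24)
  times <- sapply(taus, function(tau) {
    oscillation_time(t, g * (t / tau) * exp(1 - t / tau), 0, 0)
  })
  expect_true(all(diff(times) >= 0))
})

test_that("perturbation responses recover simulated trunk kinematics", {
  s <- generate_session(subject_profile(response_gain = 4, settling_tau = 0.18),
                        6, seed = 55)
  ev <- detect_perturbations(s$recording)
  valid <- ev[!ev$truncated, , drop = FALSE]
  rs <- purrr::map_dfr(seq_len(nrow(valid)),
                       ~ perturbation_response(s$recording, valid[.x, ]))
  # forward pulses load the pitch axis, lateral pulses the roll axis
  fwd <- rs[rs$direction == "forward", ]
  lat <- rs[rs$direction != "forward", ]
  expect_true(all(fwd$max_tilt_ap > fwd$max_tilt_ml))
  expect_true(all(lat$max_tilt_ml > lat$max_tilt_ap))
  expect_equal(mean(fwd$max_tilt_ap), 4, tolerance = 0.2)
  # measured settling times track the generator's analytic settling time
  expect_equal(mean(rs$oscillation_time), s$truth$settling_time, tolerance = 0.25)
})

test_that("single clean pulse response has exact peak features", {
  n <- 300; fs <- 30; t <- (seq_len(n) - 1) / fs
  onset <- 3
  ap_platform <- -6 * exp(-((t - onset - 0.33)^2) / (2 * 0.11^2)) * (t >= onset)
  # trunk reacts 0.15 s after the platform, so the pre-onset baseline window
  # (which ends at the back-tracked onset) stays clean
  lag <- onset + 0.15
  pitch <- 4 * ((t - lag) / 0.2) * exp(1 - (t - lag) / 0.2) * (t >= lag)
  rec <- make_recording(n = n, exercise_id = 6, theta_ap = ap_platform,
                        trunk_pitch = pitch)
  ev <- detect_perturbations(rec)
  r <- perturbation_response(rec, ev[1, ])
  expect_equal(r$direction, "forward")
  expect_equal(r$max_tilt_ml, 0)
  expect_equal(r$max_tilt_ap, max(pitch), tolerance = 1e-9)

  # zero trunk response: all response features zero
  rec0 <- make_recording(n = n, exercise_id = 6, theta_ap = ap_platform)
  r0 <- perturbation_response(rec0, detect_perturbations(rec0)[1, ])
  expect_true(all(unlist(r0[, c("apo_post", "mlo_post", "oscillation_time",
                                "max_tilt_ap", "max_tilt_ml")]) == 0))
})

test_that("aggregation averages per direction and marks empty directions missing", {
  rs <- tibble::tibble(
    direction = c("forward", "forward", "forward", "left"),
    apo_post = c(1, 2, 3, 4), mlo_post = c(2, 2, 2, 5),
    oscillation_time = c(0.4, 0.5, 0.6, 0.3),
    max_tilt_ap = c(1, 1, 1, 2), max_tilt_ml = c(0.5, 0.5, 0.5, 3))
  agg <- aggregate_perturbation_features(rs)
  expect_equal(agg$ex6_osc_time_forward, 0.5)
  expect_equal(agg$ex6_apo_forward, 2)
  expect_true(is.na(agg$ex6_osc_time_right))     # no valid right responses
  expect_equal(agg$ex6_max_tilt_ap, mean(rs$max_tilt_ap))
  expect_equal(agg$ex6_max_tilt_ml, mean(rs$max_tilt_ml))
})

test_that("FTSS segmentation recovers the simulated phase boundaries", {
  s <- generate_session(subject_profile(), 7, seed = 202)
  ph <- segment_ftss(s$recording)
  truth <- s$truth$phase_truth
  expect_equal(nrow(ph$cycles), 5)
  for (col in c("stand_start", "stand_end", "sit_start", "sit_end")) {
    expect_lt(max(abs(ph$cycles[[col]] - truth[[col]])), 1.5 / 30)
  }
  # durations from phase boundaries
  d <- ftss_durations(ph)
  expect_equal(d$ex7_total_duration, ph$cycles$sit_end[5] - ph$cycles$stand_start[1])
  expect_equal(d$ex7_mean_stand, mean(ph$cycles$stand_end - ph$cycles$stand_start))
  expect_equal(d$ex7_mean_sit, mean(ph$cycles$sit_end - ph$cycles$sit_start))
})

test_that("FTSS segmentation rejects invalid and degenerate trials", {
  s <- generate_session(subject_profile(), 7, seed = 203)
  rec <- s$recording
  # truncate after the 4th cycle: invalid trial
  cut <- s$truth$phase_truth$sit_end[4] + 0.5
  short <- new_recording(rec[rec$t <= cut, ], exercise_id = 7)
  expect_error(segment_ftss(short), class = "fallrisk_error_invalid_trial")

  # pitch never crossing the threshold
  flat <- make_recording(n = 300, exercise_id = 7, fz = 210, seat_load = 490)
  expect_error(segment_ftss(flat), class = "fallrisk_error_zero_cycles")

  # segmentation is order-dependent: a time-reversed recording does not
  # reproduce the forward phase structure (rise and descent swap roles)
  rev <- rec
  rev$fz <- base::rev(rec$fz); rev$seat_load <- base::rev(rec$seat_load)
  rev$trunk_pitch <- base::rev(rec$trunk_pitch)
  fwd_ph <- segment_ftss(rec)
  rev_ph <- tryCatch(segment_ftss(rev), error = function(e) NULL)
  if (!is.null(rev_ph)) {
    expect_gt(abs(rev_ph$mean_stand - fwd_ph$mean_stand), 0.05)
  } else {
    succeed("time-reversed recording has no valid phase sequence")
  }
})

test_that("a slow pitch ramp puts the stand onset at the threshold crossing", {
  n <- 400
  pitch <- 0.1 * (seq_len(n) - 1)          # 0.1 deg per sample from 0
  # hold loads seated so only the first crossing matters; then complete a
  # single stand so the detector has something to chew on
  rec <- make_recording(n = n, exercise_id = 7, fz = 210, seat_load = 490,
                        trunk_pitch = pitch)
  expect_error(segment_ftss(rec), class = "fallrisk_error_invalid_trial")
  # relax the cycle requirement through n_cycles = 0 is not allowed; instead
  # check the onset through a full synthetic cycle built on the same ramp
  s <- ftss_ramp_session(ramp_per_sample = 0.1)
  ph <- segment_ftss(s$recording)
  expect_equal(s$recording$trunk_pitch[which(s$recording$t == ph$cycles$stand_start[1])],
               15.1, tolerance = 1e-9)
})
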