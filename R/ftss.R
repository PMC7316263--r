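#' Segment the five-times-sit-to-stand test into movement phases
#'
#' Phase boundaries are read jointly from the trunk pitch (IMU) and the
#' vertical loads on the base and seat platforms. A sit-to-stand phase
#' starts when the forward trunk inclination first exceeds the pitch
#' threshold while seated, and ends at the first subsequent sample at which
#' the load is completely on the base platform (base load at least 95% of
#' the total measured vertical load) with the trunk back under the
#' threshold. A stand-to-sit phase starts at the next supra-threshold
#' forward inclination and ends when the seat load has returned to its
#' seated baseline (within 10%) with the trunk under the threshold. The
#' seated baseline is the mean seat load over the first second of the
#' recording. A valid trial contains exactly five complete cycles.
#'
#' @param recording A recording with `exercise_id = 7` and a `seat_load`
#'   channel.
#' @param pitch_threshold_deg Trunk pitch threshold in deg (default 15).
#' @param base_frac Fraction of total load that must be on the base platform
#'   for full standing (default 0.95).
#' @param seat_tol Relative tolerance for the seat load returning to
#'   baseline (default 0.10).
#' @param n_cycles Number of cycles a valid trial must contain (default 5).
#' @return List of class `ftss_phases`: `cycles` (tibble with
#'   `stand_start`, `stand_end`, `sit_start`, `sit_end` times in s),
#'   `total_duration`, `stand_durations`, `sit_durations`, `mean_stand`,
#'   `mean_sit`.
#' @export
segment_ftss <- function(recording, pitch_threshold_deg = 15,
                         base_frac = 0.95, seat_tol = 0.10, n_cycles = 5) {
  stopifnot_recording(recording, exercise = 7)
  if (!"seat_load" %in% names(recording) || all(is.na(recording$seat_load))) {
    abort("FTSS segmentation needs the `seat_load` channel",
          class = "fallrisk_error_channels")
  }
  t <- recording$t
  pitch <- recording$trunk_pitch
  seat <- recording$seat_load
  base <- recording$fz
  total <- seat + base
  seat_baseline <- mean(seat[t <= t[1] + 1])
  if (!any(pitch > pitch_threshold_deg)) {
    abort("trunk pitch never crosses the threshold: no sit-to-stand cycles found",
          class = "fallrisk_error_zero_cycles")
  }

  n <- length(t)
  first_from <- function(i, cond) {
    idx <- which(cond[i:n])
    if (length(idx) == 0) NA_integer_ else i + idx[1] - 1L
  }

  cycles <- list()
  i <- 1L
  repeat {
    stand_start <- first_from(i, pitch > pitch_threshold_deg)
    if (is.na(stand_start)) break
    stand_end <- first_from(stand_start,
                            base >= base_frac * total & pitch < pitch_threshold_deg)
    if (is.na(stand_end)) break
    sit_start <- first_from(stand_end, pitch > pitch_threshold_deg)
    if (is.na(sit_start)) break
    sit_end <- first_from(sit_start,
                          abs(seat - seat_baseline) <= seat_tol * seat_baseline &
                            pitch < pitch_threshold_deg)
    if (is.na(sit_end)) break
    cycles[[length(cycles) + 1]] <-
      tibble(stand_start = t[stand_start], stand_end = t[stand_end],
             sit_start = t[sit_start], sit_end = t[sit_end])
    i <- sit_end + 1L
    if (i > n) break
  }

  if (length(cycles) < n_cycles) {
    abort(sprintf("invalid trial: found %d complete cycle(s), a valid test has %d",
                  length(cycles), n_cycles),
          class = "fallrisk_error_invalid_trial")
  }
  cycles <- bind_rows(cycles[seq_len(n_cycles)])
  phases <- list(
    cycles = cycles,
    total_duration = cycles$sit_end[n_cycles] - cycles$stand_start[1],
    stand_durations = cycles$stand_end - cycles$stand_start,
    sit_durations = cycles$sit_end - cycles$sit_start,
    mean_stand = mean(cycles$stand_end - cycles$stand_start),
    mean_sit = mean(cycles$sit_end - cycles$sit_start))
  class(phases) <- "ftss_phases"
  phases
}

#' @export
print.ftss_phases <- function(x, ...) {
  cat(sprintf("<ftss_phases> %d cycles, total %.2f s (mean stand %.2f s, mean sit %.2f s)\n",
              nrow(x$cycles), x$total_duration, x$mean_stand, x$mean_sit))
  print(x$cycles)
  invisible(x)
}

#' Duration features of a segmented sit-to-stand trial
#'
#' Total test duration (first stand onset to last seat return), the
#' per-repetition stand-up and sit-down times, and their means.
#'
#' @param phases An [segment_ftss()] result.
#' @return One-row tibble with `ex7_`-prefixed canonical feature names:
#'   `ex7_total_duration`, `ex7_mean_stand`, `ex7_mean_sit` (s).
#' @export
ftss_durations <- function(phases) {
  if (!inherits(phases, "ftss_phases")) {
    abort("expected an `ftss_phases` object", class = "fallrisk_error_validation")
  }
  tibble(ex7_total_duration = phases$total_duration,
         ex7_mean_stand = phases$mean_stand,
         ex7_mean_sit = phases$mean_sit)
}
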