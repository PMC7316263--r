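#' Detect platform perturbation epochs (random-perturbation exercise)
#'
#' Perturbation onsets are found on the platform's angular displacement
#' signal: the total tilt magnitude relative to the pre-task baseline is
#' thresholded, and each supra-threshold excursion is dated back to the last
#' sub-threshold sample before it. Each event carries the analysis epoch
#' from 0.25 s before the onset to 1.5 s after it; the feature window runs
#' from the onset to 1 s after it. The perturbation direction (forward =
#' toes-down anteroposterior tilt; left/right from the sign of the
#' mediolateral tilt) is read off the dominant axis at the excursion peak.
#'
#' @param recording A recording with `exercise_id = 6`.
#' @param threshold_deg Onset detection threshold on the tilt magnitude
#'   (default 0.5 deg).
#' @param baseline_s Initial window whose mean tilt defines the neutral
#'   platform attitude (default 1 s).
#' @param merge_gap_s Supra-threshold runs closer than this are treated as
#'   one event (default 2 s; the protocol spaces pulses by >= 4 s).
#' @param pre_s,post_s Epoch extent around the onset (defaults 0.25 / 1.5 s).
#' @return Tibble of class `perturbation_events`: `onset_time`,
#'   `onset_index`, `direction`, `peak_tilt`, `epoch_start`, `epoch_end`,
#'   `truncated`. Events whose epoch leaves the recording are flagged
#'   `truncated` and are excluded from feature aggregation downstream.
#'   No events at all gives a zero-row tibble.
#' @export
detect_perturbations <- function(recording, threshold_deg = 0.5,
                                 baseline_s = 1, merge_gap_s = 2,
                                 pre_s = 0.25, post_s = 1.5) {
  stopifnot_recording(recording, exercise = 6)
  t <- recording$t
  base_idx <- t <= t[1] + baseline_s
  ml <- recording$theta_ml - mean(recording$theta_ml[base_idx])
  ap <- recording$theta_ap - mean(recording$theta_ap[base_idx])
  mag <- sqrt(ml^2 + ap^2)
  above <- mag > threshold_deg
  empty <- tibble(onset_time = numeric(), onset_index = integer(),
                  direction = character(), peak_tilt = numeric(),
                  epoch_start = numeric(), epoch_end = numeric(),
                  truncated = logical())
  class(empty) <- c("perturbation_events", class(empty))
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by less than merge_gap_s (noise can split a pulse)
  fs <- sampling_rate(recording)
  gap_n <- merge_gap_s * fs
  keep_start <- runs$start
  keep_end <- runs$end
  merged <- list()
  cs <- keep_start[1]; ce <- keep_end[1]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (keep_start[i] - ce < gap_n) {
        ce <- keep_end[i]
      } else {
        merged[[length(merged) + 1]] <- c(cs, ce)
        cs <- keep_start[i]; ce <- keep_end[i]
      }
    }
  }
  merged[[length(merged) + 1]] <- c(cs, ce)

  events <- purrr::map_dfr(merged, function(run) {
    onset_index <- max(run[1] - 1L, 1L)  # last sub-threshold sample before
    seg <- run[1]:run[2]
    pk <- seg[which.max(mag[seg])]
    direction <- if (abs(ap[pk]) >= abs(ml[pk])) {
      "forward"                     # toes-down AP pulse
    } else if (ml[pk] < 0) "left" else "right"
    tibble(onset_time = t[onset_index],
           onset_index = as.integer(onset_index),
           direction = direction,
           peak_tilt = mag[pk],
           epoch_start = t[onset_index] - pre_s,
           epoch_end = t[onset_index] + post_s,
           truncated = (t[onset_index] - pre_s < t[1] - 1e-9) ||
                       (t[onset_index] + post_s > t[length(t)] + 1e-9))
  })
  events <- arrange(events, .data$onset_time)
  class(events) <- c("perturbation_events", class(tibble()))
  events
}

#' Trunk stabilization time after a perturbation
#'
#' Time from the perturbation onset to the first instant after the peak
#' trunk deviation at which the baseline-referenced angle stays inside a
#' band of `band_frac` times the peak deviation for `hold_s` continuously.
#' If the trunk never stabilizes inside the epoch the value is capped at
#' the epoch length.
#'
#' @param t,angle Time (s) and trunk angle (deg) samples covering the epoch.
#' @param onset_time Perturbation onset (s).
#' @param baseline Reference angle (deg), normally the pre-onset mean.
#' @param band_frac Stabilization band as a fraction of the peak deviation
#'   (default 0.2).
#' @param hold_s Time the signal must remain inside the band (default 0.25 s).
#' @param cap_s Epoch length after onset; also the returned cap (default 1.5 s).
#' @return Stabilization time in s, in `[0, cap_s]`. A zero peak deviation
#'   returns 0.
#' @export
oscillation_time <- function(t, angle, onset_time, baseline,
                             band_frac = 0.2, hold_s = 0.25, cap_s = 1.5) {
  keep <- t >= onset_time - 1e-9 & t <= onset_time + cap_s + 1e-9
  t <- t[keep]; dev <- abs(angle[keep] - baseline)
  if (length(t) == 0 || max(dev) <= 0) return(0)
  pk <- which.max(dev)
  band <- band_frac * dev[pk]
  inside <- dev < band
  inside[seq_len(pk)] <- FALSE   # only instants after the peak count
  if (!any(inside)) return(cap_s)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    if (t[ends[j]] - t[starts[j]] + 1e-9 >= hold_s) {
      return(t[starts[j]] - onset_time)
    }
  }
  cap_s
}

#' Trunk response features for one perturbation epoch
#'
#' Trunk pitch and roll are referenced to their pre-onset baseline (mean
#' over the 0.25 s before the onset). Over the 1 s analysis window the
#' AP/ML post-perturbation oscillation ranges and the maximum absolute
#' trunk excursions are computed; the stabilization time is evaluated on
#' the axis with the larger peak deviation over the full 1.5 s epoch.
#'
#' @param recording The Exercise-6 recording the event came from.
#' @param event One row of [detect_perturbations()] output.
#' @param analysis_s Feature window length after the onset (default 1 s).
#' @param ... Passed to [oscillation_time()].
#' @return One-row tibble: `direction`, `apo_post`, `mlo_post` (deg),
#'   `oscillation_time` (s), `max_tilt_ap`, `max_tilt_ml` (deg).
#' @export
perturbation_response <- function(recording, event, analysis_s = 1, ...) {
  stopifnot_recording(recording, exercise = 6)
  if (isTRUE(event$truncated)) {
    abort("cannot compute features for a truncated perturbation epoch",
          class = "fallrisk_error_truncated")
  }
  t <- recording$t
  onset <- event$onset_time
  pre <- t >= onset - 0.25 - 1e-9 & t <= onset + 1e-9
  win <- t >= onset - 1e-9 & t <= onset + analysis_s + 1e-9
  base_pitch <- mean(recording$trunk_pitch[pre])
  base_roll <- mean(recording$trunk_roll[pre])
  pitch_dev <- recording$trunk_pitch[win] - base_pitch
  roll_dev <- recording$trunk_roll[win] - base_roll
  max_ap <- max(abs(pitch_dev))
  max_ml <- max(abs(roll_dev))
  osc_axis <- if (max_ap >= max_ml) recording$trunk_pitch else recording$trunk_roll
  osc_base <- if (max_ap >= max_ml) base_pitch else base_roll
  tibble(direction = event$direction,
         apo_post = oscillation_range(pitch_dev),
         mlo_post = oscillation_range(roll_dev),
         oscillation_time = oscillation_time(t, osc_axis, onset, osc_base, ...),
         max_tilt_ap = max_ap,
         max_tilt_ml = max_ml)
}

#' Aggregate per-epoch perturbation responses into subject features
#'
#' Per-direction means of the stabilization time and of the
#' post-perturbation AP/ML ranges (forward, left, right), plus the maximum
#' trunk tilt per axis averaged across all directions (only the
#' between-direction means are kept for the tilt features). A direction
#' with no valid (non-truncated) response yields `NA` for its features.
#'
#' @param responses Tibble of [perturbation_response()] rows.
#' @return One-row tibble with `ex6_`-prefixed canonical feature names.
#' @export
aggregate_perturbation_features <- function(responses) {
  dirs <- c("forward", "left", "right")
  mean_of <- function(d, col) {
    v <- responses[[col]][responses$direction == d]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- tibble(.rows = 1)
  for (d in dirs) out[[paste0("ex6_osc_time_", d)]] <- mean_of(d, "oscillation_time")
  out$ex6_max_tilt_ap <- if (nrow(responses) == 0) NA_real_ else mean(responses$max_tilt_ap)
  out$ex6_max_tilt_ml <- if (nrow(responses) == 0) NA_real_ else mean(responses$max_tilt_ml)
  for (d in dirs) out[[paste0("ex6_apo_", d)]] <- mean_of(d, "apo_post")
  for (d in dirs) out[[paste0("ex6_mlo_", d)]] <- mean_of(d, "mlo_post")
  out
}
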