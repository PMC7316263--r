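#' Construct a balance-session recording
#'
#' A recording is one session of multichannel time series sampled at a fixed
#' rate (30 Hz on the device) during one of the seven assessment exercises:
#' vertical force and the two torque components under the foot platform, the
#' platform tilt angles, trunk roll/pitch from the torso IMU, 3-axis trunk
#' acceleration, and (for the sit-to-stand test) the vertical force under the
#' seat. It is stored as a tibble with one row per sample and session
#' metadata in attributes.
#'
#' @param data Data frame with columns `t` (s), `fz` (N), `mx`, `my` (N m),
#'   `theta_ml`, `theta_ap` (deg), `trunk_roll`, `trunk_pitch` (deg),
#'   `acc_x`, `acc_y`, `acc_z` (m/s^2) and optionally `seat_load` (N).
#' @param exercise_id Integer 1-7 identifying the exercise protocol.
#' @param sampling_rate Sampling frequency in Hz (default 30).
#' @param subject_id Optional subject identifier.
#' @param eyes `"open"` or `"closed"` (eyes-closed applies to Exercise 3).
#'
#' @details Coordinate conventions: x is mediolateral (positive right), y is
#'   anteroposterior (positive forward); trunk pitch is positive in forward
#'   flexion; a toes-down platform pitch is negative `theta_ap`.
#'
#' @return A tibble of class `balance_recording`.
#' @export
new_recording <- function(data, exercise_id, sampling_rate = 30,
                          subject_id = NA_character_, eyes = c("open", "closed")) {
  eyes <- match.arg(eyes)
  data <- as_tibble(data)
  required <- c("t", "fz", "mx", "my", "theta_ml", "theta_ap",
                "trunk_roll", "trunk_pitch", "acc_x", "acc_y", "acc_z")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("recording is missing channel(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fallrisk_error_channels")
  }
  if (!is.numeric(exercise_id) || length(exercise_id) != 1 ||
      !exercise_id %in% 1:7) {
    abort("`exercise_id` must be a single integer in 1..7",
          class = "fallrisk_error_validation")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be positive", class = "fallrisk_error_validation")
  }
  if (nrow(data) < 2) {
    abort("a recording needs at least 2 samples",
          class = "fallrisk_error_insufficient_data")
  }
  dt <- diff(data$t)
  if (any(dt <= 0)) {
    abort("`t` must be strictly increasing", class = "fallrisk_error_validation")
  }
  if (max(abs(dt - 1 / sampling_rate)) > 1e-9) {
    abort("`t` spacing must equal 1/sampling_rate (within 1e-9 s)",
          class = "fallrisk_error_validation")
  }
  structure(data,
            class = c("balance_recording", class(data)),
            exercise_id = as.integer(exercise_id),
            sampling_rate = sampling_rate,
            subject_id = subject_id,
            eyes = eyes)
}

#' Recording metadata accessors
#'
#' @param recording A `balance_recording`.
#' @return `exercise_id()` the integer exercise id; `sampling_rate()` the
#'   sampling frequency in Hz.
#' @export
exercise_id <- function(recording) attr(recording, "exercise_id")

#' @rdname exercise_id
#' @export
sampling_rate <- function(recording) attr(recording, "sampling_rate")

#' @export
print.balance_recording <- function(x, ...) {
  cat(sprintf("<balance_recording> exercise %d, %d samples @ %g Hz, subject %s, eyes %s\n",
              exercise_id(x), nrow(x), sampling_rate(x),
              attr(x, "subject_id"), attr(x, "eyes")))
  NextMethod()
}

stopifnot_recording <- function(recording, exercise = NULL) {
  if (!inherits(recording, "balance_recording")) {
    abort("expected a `balance_recording` (see `new_recording()`)",
          class = "fallrisk_error_validation")
  }
  if (!is.null(exercise) && !exercise_id(recording) %in% exercise) {
    abort(sprintf("this analysis applies to exercise(s) %s, got exercise %d",
                  paste(exercise, collapse = ", "), exercise_id(recording)),
          class = "fallrisk_error_dispatch")
  }
  invisible(recording)
}

#' Read / write a session recording
#'
#' The on-disk form is a plain CSV (UTF-8, comma separated, `.` decimal, NA
#' as empty field) with one row per sample and the canonical channel header,
#' plus a JSON sidecar `<path>.json` carrying
#' `{subject_id, exercise_id, sampling_rate, eyes}`.
#'
#' @param recording A `balance_recording`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `read_recording()` returns a `balance_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot_recording(recording)
  utils::write.csv(as.data.frame(recording), path, row.names = FALSE, na = "")
  meta <- list(subject_id = attr(recording, "subject_id"),
               exercise_id = exercise_id(recording),
               sampling_rate = sampling_rate(recording),
               eyes = attr(recording, "eyes"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    abort(paste0("recording CSV or JSON sidecar not found for: ", path),
          class = "fallrisk_error_io")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  data <- utils::read.csv(path, na.strings = "")
  new_recording(data,
                exercise_id = meta$exercise_id,
                sampling_rate = meta$sampling_rate,
                subject_id = meta$subject_id,
                eyes = meta$eyes)
}
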