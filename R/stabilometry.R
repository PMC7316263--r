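#' Center of pressure from platform force/torque channels
#'
#' The planar center of pressure (CoP) under the foot platform is the ratio
#' of the horizontal torque components to the vertical force measured by the
#' 6-axis force-torque sensor: x = mx / fz (mediolateral), y = my / fz
#' (anteroposterior). The ratio is in metres and is converted to cm, the
#' conventional stabilometric unit.
#'
#' @param recording A [new_recording()] object with `fz`, `mx`, `my`.
#' @param load_floor Minimum admissible vertical force in N (default 10);
#'   any sample at or below it means the platform is unloaded and no CoP
#'   exists there.
#' @return A tibble of class `cop_trace` with columns `t`, `x`, `y` (cm).
#' @export
compute_cop <- function(recording, load_floor = 10) {
  stopifnot_recording(recording)
  bad <- which(recording$fz <= load_floor)
  if (length(bad) > 0) {
    abort(sprintf(
      "unloaded platform: fz <= %g N first at sample %d (t = %.3f s)",
      load_floor, bad[1], recording$t[bad[1]]),
      class = "fallrisk_error_unloaded")
  }
  new_cop_trace(t = recording$t,
                x = 100 * recording$mx / recording$fz,
                y = 100 * recording$my / recording$fz)
}

new_cop_trace <- function(t, x, y) {
  stopifnot(length(x) == length(y))
  structure(tibble(t = t, x = x, y = y),
            class = c("cop_trace", class(tibble())))
}

#' Planar projection of the platform tilt angles
#'
#' For the unstable-platform condition the statokinesigram is taken from the
#' platform's angular displacement rather than the CoP. The tilt angles are
#' projected to a planar trace by the small-angle arc length d = R * theta,
#' so sway metrics keep cm / cm^2 units. The lever arm R is a scale
#' convention, not a physiological quantity.
#'
#' @param recording A recording with `theta_ml`, `theta_ap` in deg.
#' @param lever_arm_m Projection radius in m (default 0.5).
#' @return A `cop_trace` tibble (`t`, `x`, `y` in cm).
#' @export
platform_projection <- function(recording, lever_arm_m = 0.5) {
  stopifnot_recording(recording)
  k <- 100 * lever_arm_m * pi / 180  # deg -> cm at radius R
  new_cop_trace(t = recording$t,
                x = k * recording$theta_ml,
                y = k * recording$theta_ap)
}

trace_xy <- function(trace) {
  if (inherits(trace, "cop_trace") || (is.data.frame(trace) &&
      all(c("x", "y") %in% names(trace)))) {
    cbind(trace$x, trace$y)
  } else if (is.matrix(trace) && ncol(trace) == 2) {
    trace
  } else {
    abort("expected a planar trace: a `cop_trace`, a data frame with x/y, or a 2-column matrix",
          class = "fallrisk_error_validation")
  }
}

#' Sway path: cumulative length of a planar trajectory
#'
#' Sum of Euclidean distances between consecutive samples of the
#' statokinesigram, in the units of the trace (cm for CoP, or deg if applied
#' to raw angles).
#'
#' @param trace Planar trace (`cop_trace`, data frame with `x`/`y`, or
#'   2-column matrix).
#' @return Path length (scalar, >= 0).
#' @export
sway_path <- function(trace) {
  xy <- trace_xy(trace)
  if (nrow(xy) < 2) {
    abort("sway_path needs at least 2 samples",
          class = "fallrisk_error_insufficient_data")
  }
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Sway area: 95% prediction ellipse of the statokinesigram
#'
#' Area of the ellipse that contains an individual point of the trace with
#' 95% probability under a bivariate normal model:
#' pi * q * sqrt(det(Sigma-hat)), where Sigma-hat is the 2x2 sample
#' covariance (divisor n - 1) and q is the 0.95 chi-square quantile with
#' 2 df (about 5.9915). Units are squared trace units.
#'
#' @inheritParams sway_path
#' @param conf Coverage probability of the ellipse (default 0.95).
#' @return Ellipse area (scalar, >= 0). A numerically negative covariance
#'   determinant is clamped to 0.
#' @export
sway_area <- function(trace, conf = 0.95) {
  xy <- trace_xy(trace)
  if (nrow(xy) < 3) {
    abort("sway_area needs at least 3 samples",
          class = "fallrisk_error_insufficient_data")
  }
  d <- det(cov(xy))
  pi * qchisq(conf, df = 2) * sqrt(max(d, 0))
}

#' Oscillation range of a 1-D signal
#'
#' max - min of the series; applied to CoP x/y for the mediolateral (MLO)
#' and anteroposterior (APO) ranges, to the platform-projection coordinates
#' in the unstable condition, and to trunk roll/pitch for the trunk ranges.
#'
#' @param series Numeric vector with at least one finite sample.
#' @return Range (scalar, >= 0).
#' @export
oscillation_range <- function(series) {
  if (length(series) < 1 || all(!is.finite(series))) {
    abort("oscillation_range needs at least one finite sample",
          class = "fallrisk_error_insufficient_data")
  }
  max(series, na.rm = TRUE) - min(series, na.rm = TRUE)
}

#' Trunk variability from 3-axis trunk acceleration
#'
#' Standard deviation (divisor n - 1) of the Euclidean norm of the
#' per-sample mean-centered acceleration vector: a single scalar summary of
#' how much the trunk moved during the task. Per-axis standard deviations
#' are returned alongside as auxiliary outputs.
#'
#' @param acc n x 3 matrix or data frame of trunk acceleration (m/s^2).
#' @return Named list: `va` (the scalar indicator, m/s^2) and
#'   `per_axis` (named 3-vector of per-axis SDs).
#' @export
trunk_variability <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2) {
    abort("trunk_variability needs at least 2 samples",
          class = "fallrisk_error_insufficient_data")
  }
  if (ncol(acc) != 3) {
    abort("trunk acceleration must have 3 axes", class = "fallrisk_error_validation")
  }
  centered <- sweep(acc, 2, colMeans(acc))
  norms <- sqrt(rowSums(centered^2))
  list(va = sd(norms),
       per_axis = c(x = sd(acc[, 1]), y = sd(acc[, 2]), z = sd(acc[, 3])))
}

#' Limits-of-stability maximal CoP displacements
#'
#' Maximum CoP excursion in each of the four directions over the whole task,
#' after re-zeroing the trace to the mean of an initial quiet-standing
#' window: forward = max(y - y0), backward = -min(y - y0), right =
#' max(x - x0), left = -min(x - x0), each clamped at 0.
#'
#' @param trace A `cop_trace`.
#' @param quiet_window_s Length of the initial window whose mean defines the
#'   neutral stance (default 2 s).
#' @return One-row tibble with `forward`, `backward`, `left`, `right` (cm).
#' @export
los_max_displacement <- function(trace, quiet_window_s = 2) {
  xy <- trace_xy(trace)
  if (nrow(xy) < 1) {
    abort("empty trace", class = "fallrisk_error_insufficient_data")
  }
  quiet <- if (!is.null(trace$t)) trace$t <= trace$t[1] + quiet_window_s else
    seq_len(nrow(xy)) == 1
  if (!any(quiet)) quiet[1] <- TRUE
  x <- xy[, 1] - mean(xy[quiet, 1])
  y <- xy[, 2] - mean(xy[quiet, 2])
  tibble(forward  = max(max(y), 0),
         backward = max(-min(y), 0),
         left     = max(-min(x), 0),
         right    = max(max(x), 0))
}

#' Stabilometric indicator suite for the standing balance exercises
#'
#' Computes the full sway-metric set for Exercises 2-5: sway area, sway
#' path and the AP/ML oscillation ranges of the source statokinesigram (the
#' CoP for Exercises 2, 3 and 5; the planar platform-angle projection for
#' Exercise 4), the trunk AP/ML oscillation ranges from the IMU roll/pitch
#' angles, and the trunk acceleration variability.
#'
#' @param recording A recording with `exercise_id` in 2..5.
#' @param duration_s Analysis duration in s; defaults to the protocol's 30 s
#'   for Exercises 2-5. The recording must cover it.
#' @param lever_arm_m Lever arm for the Exercise-4 projection (m).
#' @param load_floor Passed to [compute_cop()].
#' @return One-row tibble: `sway_area` (cm^2), `sway_path` (cm), `apo`,
#'   `mlo` (cm), `trunk_apo`, `trunk_mlo` (deg), `trunk_variability`
#'   (m/s^2), and `source` (`"cop"` or `"platform_projection"`).
#' @export
balance_metrics <- function(recording, duration_s = 30, lever_arm_m = 0.5,
                            load_floor = 10) {
  stopifnot_recording(recording, exercise = 2:5)
  span <- recording$t[nrow(recording)] - recording$t[1]
  if (span + 1e-9 < duration_s) {
    abort(sprintf("recording covers %.2f s but the analysis needs %.2f s",
                  span, duration_s),
          class = "fallrisk_error_insufficient_duration")
  }
  rec <- recording[recording$t <= recording$t[1] + duration_s, , drop = FALSE]
  source <- if (exercise_id(recording) == 4) "platform_projection" else "cop"
  trace <- if (source == "cop") {
    compute_cop(new_recording(rec, exercise_id(recording), sampling_rate(recording)),
                load_floor = load_floor)
  } else {
    platform_projection(rec, lever_arm_m = lever_arm_m)
  }
  va <- trunk_variability(cbind(rec$acc_x, rec$acc_y, rec$acc_z))
  tibble(sway_area = sway_area(trace),
         sway_path = sway_path(trace),
         apo = oscillation_range(trace$y),
         mlo = oscillation_range(trace$x),
         trunk_apo = oscillation_range(rec$trunk_pitch),
         trunk_mlo = oscillation_range(rec$trunk_roll),
         trunk_variability = va$va,
         source = source)
}

#' Statokinesigram plot with the 95% prediction ellipse
#'
#' @param object A `cop_trace`.
#' @param conf Ellipse coverage (default 0.95).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cop_trace
#' @export
autoplot.cop_trace <- function(object, conf = 0.95, ...) {
  xy <- trace_xy(object)
  mu <- colMeans(xy)
  S <- cov(xy)
  d <- det(S)
  ell <- NULL
  if (is.finite(d) && d > 0) {
    r <- sqrt(qchisq(conf, 2))
    ang <- seq(0, 2 * pi, length.out = 181)
    circ <- rbind(cos(ang), sin(ang)) * r
    pts <- t(chol(S)) %*% circ + mu
    ell <- tibble(x = pts[1, ], y = pts[2, ])
  }
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mediolateral (cm)", y = "anteroposterior (cm)",
                  title = "Statokinesigram")
  if (!is.null(ell)) {
    p <- p + ggplot2::geom_path(data = ell, colour = "firebrick")
  }
  p
}
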