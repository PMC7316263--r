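test_that("CoP is the torque-to-force ratio in cm and errors when unloaded", {
  rec <- make_recording(n = 30, fz = 700, mx = 3.5, my = -7.0)
  cop <- compute_cop(rec)
  expect_equal(cop$x, rep(0.5, 30))
  expect_equal(cop$y, rep(-1.0, 30))

  zero <- compute_cop(make_recording(n = 30, fz = 700, mx = 0, my = 0))
  expect_true(all(zero$x == 0) && all(zero$y == 0))

  fz <- rep(700, 30); fz[12] <- 0
  expect_error(compute_cop(make_recording(n = 30, fz = fz)),
               class = "fallrisk_error_unloaded")
  expect_error(compute_cop(make_recording(n = 30, fz = fz)), "sample 12")

  # the ratio is scale invariant in the applied load
  rec2 <- make_recording(n = 30, fz = 1400, mx = 7.0, my = -14.0)
  expect_equal(compute_cop(rec2)$x, cop$x)
  expect_equal(compute_cop(rec2)$y, cop$y)
})

test_that("sway path matches closed forms for segments and circles", {
  expect_equal(sway_path(cbind(rep(1, 10), rep(2, 10))), 0)

  # straight segment, irregular sampling: collinear additivity
  s <- c(0, 0.11, 0.5, 0.53, 1)
  expect_equal(sway_path(cbind(3 * s, 4 * s)), 5)

  # unit circle at 360 equal angles: chord sum 360 * 2 * sin(pi/360)
  ang <- 2 * pi * (0:360) / 360
  expect_equal(sway_path(cbind(cos(ang), sin(ang))), 360 * 2 * sin(pi / 360),
               tolerance = 1e-12)

  expect_error(sway_path(cbind(1, 1)), class = "fallrisk_error_insufficient_data")
})

test_that("sway path is rigid-motion invariant, scales linearly, grows under refinement", {
  set.seed(42)
  xy <- cbind(cumsum(rnorm(50)), cumsum(rnorm(50)))
  p0 <- sway_path(xy)
  th <- 0.7
  rot <- xy %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(sway_path(rot), p0)
  expect_equal(sway_path(sweep(xy, 2, c(3, -9), "+")), p0)
  expect_equal(sway_path(2.5 * xy), 2.5 * p0)

  # refining a sampled smooth curve never decreases the chord sum
  t1 <- seq(0, 2 * pi, length.out = 51)
  t2 <- seq(0, 2 * pi, length.out = 101)
  curve <- function(t) cbind(cos(t), sin(2 * t))
  expect_gte(sway_path(curve(t2)), sway_path(curve(t1)))
  # and converges to arc length for a polyline-limit curve (circle)
  tfine <- seq(0, 2 * pi, length.out = 20001)
  expect_equal(sway_path(cbind(cos(tfine), sin(tfine))), 2 * pi, tolerance = 1e-6)
})

test_that("sway area matches the analytic 95% ellipse and degenerates to zero", {
  expect_equal(sway_area(cbind(rep(1, 5), rep(2, 5))), 0)
  expect_equal(sway_area(cbind(1:5, 2 * (1:5) + 3)), 0)  # collinear

  set.seed(7)
  z <- matrix(rnorm(2e5), ncol = 2)
  expect_equal(sway_area(z), pi * qchisq(0.95, 2), tolerance = 0.05)

  # area pi * q * sqrt(det Sigma) for a general covariance
  sig <- matrix(c(2, 0.8, 0.8, 1), 2)
  z2 <- z %*% chol(sig)
  expect_equal(sway_area(z2), pi * qchisq(0.95, 2) * sqrt(det(sig)),
               tolerance = 0.05)

  # rigid motions leave the area unchanged; scaling goes as k^2
  th <- 1.1
  rot <- z[1:5000, ] %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(sway_area(rot), sway_area(z[1:5000, ]), tolerance = 1e-9)
  expect_equal(sway_area(3 * z[1:5000, ]), 9 * sway_area(z[1:5000, ]),
               tolerance = 1e-9)

  expect_error(sway_area(cbind(1:2, 1:2)), class = "fallrisk_error_insufficient_data")
})

test_that("oscillation range is the peak-to-peak excursion", {
  expect_equal(oscillation_range(rep(3.3, 10)), 0)
  expect_equal(oscillation_range(c(-2, 0, 5)), 7)
  t <- seq(0, 1, by = 1 / 600)
  expect_equal(oscillation_range(1.5 * sin(2 * pi * 5 * t)), 3.0, tolerance = 1e-3)
  expect_error(oscillation_range(numeric(0)),
               class = "fallrisk_error_insufficient_data")
})

test_that("trunk variability is the SD of the centered-norm and reports per-axis SDs", {
  expect_equal(trunk_variability(matrix(5, 10, 3))$va, 0)

  # single-axis square wave: centered norms are all 1, so the norm SD is 0,
  # while the per-axis rule gives sqrt(4/3)
  acc <- cbind(c(1, 1, 3, 3), 0, 0)
  tv <- trunk_variability(acc)
  expect_equal(tv$va, 0)
  expect_equal(unname(tv$per_axis["x"]), sqrt(4 / 3))

  # white-noise closed form via brute-force simulation oracle
  set.seed(3)
  sigma <- 0.4
  acc <- matrix(rnorm(3e4 * 3, 0, sigma), ncol = 3)
  oracle <- sd(sqrt(rowSums(matrix(rnorm(3e5 * 3, 0, sigma), ncol = 3)^2)))
  expect_equal(trunk_variability(acc)$va, oracle, tolerance = 0.05)

  expect_error(trunk_variability(matrix(1, 1, 3)),
               class = "fallrisk_error_insufficient_data")
})

test_that("LOS maxima are re-zeroed directional extremes clamped at zero", {
  t <- (0:299) / 30
  x <- numeric(300); y <- numeric(300)
  x[100] <- -3; y[120] <- 4; x[200] <- 2; y[220] <- -1
  tr <- tibble::tibble(t = t, x = x, y = y)
  los <- los_max_displacement(tr)
  expect_equal(unlist(los), c(forward = 4, backward = 1, left = 3, right = 2))

  con <- los_max_displacement(tibble::tibble(t = t, x = rep(1, 300), y = rep(1, 300)))
  expect_equal(unlist(con), c(forward = 0, backward = 0, left = 0, right = 0))

  # a baseline offset in the quiet window is removed before taking extremes
  y2 <- rep(1, 300); y2[200] <- 5
  off <- los_max_displacement(tibble::tibble(t = t, x = rep(1, 300), y = y2))
  expect_equal(off$forward, 4)
})

test_that("balance metrics dispatch on exercise and fail on wrong input", {
  t <- (0:930) / 30
  my <- 700 * (1 / 100) * sin(2 * pi * 0.5 * t)  # pure AP CoP sinusoid, 1 cm
  rec <- make_recording(n = 931, exercise_id = 2, my = my)
  m <- balance_metrics(rec)
  expect_equal(m$apo, 2, tolerance = 1e-3)
  expect_equal(m$mlo, 0)
  expect_equal(m$source, "cop")

  # constant CoP and trunk: everything zero
  m0 <- balance_metrics(make_recording(n = 931, exercise_id = 3))
  expect_true(all(unlist(m0[, 1:7]) == 0))

  # exercise 4 uses the platform projection
  s4 <- generate_session(subject_profile(), 4, seed = 4)
  m4 <- balance_metrics(s4$recording)
  expect_equal(m4$source, "platform_projection")
  expect_equal(m4$sway_path,
               sway_path(platform_projection(s4$recording[s4$recording$t <= 30, ] |>
                 new_recording(exercise_id = 4))),
               tolerance = 1e-6)

  expect_error(balance_metrics(make_recording(n = 931, exercise_id = 6)),
               class = "fallrisk_error_dispatch")
  expect_error(balance_metrics(make_recording(n = 60, exercise_id = 2)),
               class = "fallrisk_error_insufficient_duration")
})
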