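# small constructors shared across test files

make_recording <- function(n = 90, fs = 30, exercise_id = 2,
                           fz = 700, mx = 0, my = 0,
                           theta_ml = 0, theta_ap = 0,
                           trunk_roll = 0, trunk_pitch = 0,
                           acc = NULL, seat_load = 0) {
  rep_n <- function(v) if (length(v) == 1) rep(v, n) else v
  if (is.null(acc)) acc <- matrix(0, n, 3)
  new_recording(
    tibble::tibble(t = (seq_len(n) - 1) / fs,
                   fz = rep_n(fz), mx = rep_n(mx), my = rep_n(my),
                   theta_ml = rep_n(theta_ml), theta_ap = rep_n(theta_ap),
                   trunk_roll = rep_n(trunk_roll),
                   trunk_pitch = rep_n(trunk_pitch),
                   acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
                   seat_load = rep_n(seat_load)),
    exercise_id = exercise_id, sampling_rate = fs)
}

make_preds <- function(truth, prob, subject_id = NULL) {
  d <- tibble::tibble(truth = truth, prob = prob)
  if (!is.null(subject_id)) d$subject_id <- subject_id
  d
}

# independent Mann-Whitney AUC by exhaustive pair counting (oracle)
pair_count_auc <- function(truth, prob) {
  ev <- prob[truth == 1]; ne <- prob[truth == 0]
  s <- 0
  for (a in ev) for (b in ne) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(ev) * length(ne))
}
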