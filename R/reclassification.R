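align_pred_pair <- function(old, new) {
  check_preds(old); check_preds(new)
  if ("subject_id" %in% names(old) && "subject_id" %in% names(new)) {
    if (!setequal(old$subject_id, new$subject_id) ||
        anyDuplicated(old$subject_id) || anyDuplicated(new$subject_id)) {
      abort("the two prediction sets must cover the same subjects exactly once",
            class = "fallrisk_error_mismatch")
    }
    new <- new[match(old$subject_id, new$subject_id), ]
  } else if (nrow(old) != nrow(new)) {
    abort("prediction sets differ in size", class = "fallrisk_error_mismatch")
  }
  if (any(old$truth != new$truth)) {
    abort("the two prediction sets disagree on the outcome labels",
          class = "fallrisk_error_mismatch")
  }
  list(truth = old$truth, p_old = old$prob, p_new = new$prob)
}

two_sided_p <- function(est, se) {
  if (se == 0) return(if (abs(est) < 1e-15) 1 else 0)
  2 * pnorm(-abs(est / se))
}

#' Continuous net reclassification improvement
#'
#' Category-free NRI of a new risk model against an old one:
#' `[P(up | event) - P(down | event)] + [P(down | nonevent) -
#' P(up | nonevent)]`, where up / down mean a strictly higher / lower
#' predicted probability under the new model (exact ties move neither way).
#' The p-value is an asymptotic z-test with per-group variance
#' `(p_up + p_down - (p_up - p_down)^2) / n_group`.
#'
#' Categorical NRI over user-supplied risk thresholds is available via
#' `thresholds`: up / down then mean crossing into a higher / lower
#' category.
#'
#' @param old,new Prediction sets (data frames with `truth`, `prob`, and
#'   optionally `subject_id`) for the same subjects, e.g. the
#'   cross-validated out-of-fold probabilities of two [nested_cv_evaluate()]
#'   fits.
#' @param thresholds Optional increasing vector of category-defining risk
#'   cutoffs; `NULL` (default) gives the continuous NRI.
#' @return One-row tibble: `nri`, `z`, `p_value`, and the component
#'   proportions `event_up`, `event_down`, `nonevent_up`, `nonevent_down`.
#' @export
nri <- function(old, new, thresholds = NULL) {
  a <- align_pred_pair(old, new)
  cat_of <- function(p) {
    if (is.null(thresholds)) p else findInterval(p, sort(thresholds))
  }
  co <- cat_of(a$p_old); cn <- cat_of(a$p_new)
  up <- cn > co; down <- cn < co
  ev <- a$truth == 1
  n_e <- sum(ev); n_ne <- sum(!ev)
  if (n_e == 0 || n_ne == 0) {
    abort("both outcome groups must be non-empty", class = "fallrisk_error_single_class")
  }
  p_up_e <- mean(up[ev]);  p_dn_e <- mean(down[ev])
  p_up_n <- mean(up[!ev]); p_dn_n <- mean(down[!ev])
  est <- (p_up_e - p_dn_e) + (p_dn_n - p_up_n)
  v_e <- (p_up_e + p_dn_e - (p_up_e - p_dn_e)^2) / n_e
  v_n <- (p_up_n + p_dn_n - (p_up_n - p_dn_n)^2) / n_ne
  se <- sqrt(v_e + v_n)
  tibble(nri = est, z = if (se == 0) 0 else est / se,
         p_value = two_sided_p(est, se),
         event_up = p_up_e, event_down = p_dn_e,
         nonevent_up = p_up_n, nonevent_down = p_dn_n)
}

#' Integrated discrimination improvement
#'
#' The discrimination slope of a model is the mean predicted probability
#' among events minus that among nonevents; the IDI is the difference in
#' slope between the new and the old model. The p-value is a z-test on the
#' paired per-subject probability differences, with standard error
#' `sqrt(se_events^2 + se_nonevents^2)`.
#'
#' @inheritParams nri
#' @return One-row tibble: `idi`, `z`, `p_value`, `slope_old`, `slope_new`.
#' @export
idi <- function(old, new) {
  a <- align_pred_pair(old, new)
  ev <- a$truth == 1
  slope <- function(p) mean(p[ev]) - mean(p[!ev])
  d <- a$p_new - a$p_old
  se <- sqrt(var(d[ev]) / sum(ev) + var(d[!ev]) / sum(!ev))
  est <- slope(a$p_new) - slope(a$p_old)
  tibble(idi = est, z = if (se == 0) 0 else est / se,
         p_value = two_sided_p(est, se),
         slope_old = slope(a$p_old), slope_new = slope(a$p_new))
}

#' Reclassification comparison of two risk models
#'
#' Convenience wrapper bundling [nri()] and [idi()] for two fitted
#' cross-validation objects or raw prediction sets.
#'
#' @param old,new `fallrisk_cv` objects or prediction data frames.
#' @param thresholds Passed to [nri()].
#' @return One-row tibble of class `fallrisk_comparison` with the NRI and
#'   IDI estimates, p-values and components, plus model labels.
#' @export
compare_risk_models <- function(old, new, thresholds = NULL) {
  lab <- function(m, default) if (inherits(m, "fallrisk_cv")) m$spec$name else default
  as_preds <- function(m) if (inherits(m, "fallrisk_cv")) m$predictions else m
  r1 <- nri(as_preds(old), as_preds(new), thresholds = thresholds)
  r2 <- idi(as_preds(old), as_preds(new))
  out <- bind_cols(tibble(model_old = lab(old, "old"), model_new = lab(new, "new")),
                   dplyr::rename(r1, nri_z = "z", nri_p = "p_value"),
                   dplyr::rename(r2, idi_z = "z", idi_p = "p_value"))
  class(out) <- c("fallrisk_comparison", class(tibble()))
  out
}
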