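#' Feature-set specification
#'
#' Names a candidate model as the union of clinical and robotic variable
#' columns of a cohort table.
#'
#' @param name Label for the feature set.
#' @param clinical_vars,robotic_vars Character vectors of column names
#'   (either may be empty, not both).
#' @return List of class `feature_set_spec`.
#' @export
feature_set_spec <- function(name, clinical_vars = character(),
                             robotic_vars = character()) {
  vars <- c(clinical_vars, robotic_vars)
  if (length(vars) == 0) {
    abort("a feature set needs at least one variable",
          class = "fallrisk_error_validation")
  }
  if (anyDuplicated(vars)) {
    abort("duplicated variable names in feature set",
          class = "fallrisk_error_validation")
  }
  structure(list(name = name,
                 clinical_vars = clinical_vars,
                 robotic_vars = robotic_vars),
            class = "feature_set_spec")
}

#' Nested cross-validation configuration
#'
#' @param outer_folds,inner_folds Numbers of stratified folds (default 5/5).
#' @param lambda_grid L1 penalty grid; default 25 values log-spaced over
#'   `[1e-3, 1e2]` (applied to standardized features).
#' @param seed Integer seed controlling all fold assignments.
#' @param standardize Z-score non-binary features using training-partition
#'   statistics only (default TRUE); 0/1 columns pass through unscaled.
#' @param n_repeats Repeated repartitions to average over (default 1).
#' @return List of class `nested_cv_config`.
#' @export
nested_cv_config <- function(outer_folds = 5, inner_folds = 5,
                             lambda_grid = 10^seq(-3, 2, length.out = 25),
                             seed = 1, standardize = TRUE, n_repeats = 1) {
  if (outer_folds < 2 || inner_folds < 2) {
    abort("fold counts must be >= 2", class = "fallrisk_error_validation")
  }
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0)) {
    abort("`lambda_grid` must be non-empty and positive",
          class = "fallrisk_error_validation")
  }
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 seed = as.integer(seed), standardize = standardize,
                 n_repeats = n_repeats),
            class = "nested_cv_config")
}

# stratified fold labels; every fold gets both classes or we abort
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(sprintf("class %s has %d subject(s), fewer than %d folds: stratification impossible",
                    cls, length(idx), k),
            class = "fallrisk_error_stratification")
    }
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

auc_mw <- function(truth, prob) {
  r <- rank(prob)
  m <- sum(truth == 1); n <- sum(truth == 0)
  (sum(r[truth == 1]) - m * (m + 1) / 2) / (m * n)
}

# design matrix for a feature set; zero-variance columns dropped with a warning
cv_design <- function(table, spec) {
  vars <- c(spec$clinical_vars, spec$robotic_vars)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("feature set `", spec$name, "` names absent column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fallrisk_error_validation")
  }
  x <- as.matrix(as.data.frame(table)[, vars, drop = FALSE])
  if (!is.numeric(x)) {
    abort("all model features must be numeric after encoding",
          class = "fallrisk_error_validation")
  }
  bad <- vars[apply(x, 2, function(v) any(!is.finite(v)))]
  if (length(bad) > 0) {
    abort(paste0("non-finite values in feature column(s): ",
                 paste(bad, collapse = ", ")),
          class = "fallrisk_error_validation")
  }
  zv <- vars[apply(x, 2, function(v) var(v) == 0)]
  if (length(zv) > 0) {
    warn(paste0("dropping zero-variance column(s): ", paste(zv, collapse = ", ")))
    x <- x[, setdiff(colnames(x), zv), drop = FALSE]
  }
  x
}

# z-score continuous columns by training statistics; 0/1 columns untouched
fit_scaler <- function(x_train) {
  is_bin <- apply(x_train, 2, function(v) all(v %in% c(0, 1)))
  mu <- ifelse(is_bin, 0, colMeans(x_train))
  sdev <- ifelse(is_bin, 1, apply(x_train, 2, sd))
  sdev[sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, "/")
}

fit_lasso <- function(x, y, lambda_grid) {
  if (ncol(x) == 1) {          # glmnet needs >= 2 columns; pad with a null one
    x <- cbind(x, `..null` = 0)
  }
  # small inner folds legitimately hold few events; glmnet's class-size
  # caution is expected there and would otherwise flood the logs
  withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                   lambda = lambda_grid, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
predict_lasso <- function(fit, x, lambda) {
  if (ncol(x) == 1) x <- cbind(x, `..null` = 0)
  predict(fit, newx = x, s = lambda, type = "response")
}

#' Nested cross-validated lasso risk classification
#'
#' Fits an L1-penalized logistic model of faller status for one feature
#' set under two nested loops of stratified cross-validation: the inner
#' loop selects the penalty maximizing mean validation ROC AUC over the
#' grid (ties resolved toward the larger penalty, i.e. the sparser model);
#' the selected model, refit on the full outer-training partition with
#' standardization statistics from that partition only, predicts the
#' held-out outer fold. The out-of-fold probabilities pooled across outer
#' folds feed the discrimination metric suite, so every subject is scored
#' by a model that never saw it.
#'
#' @param table A [assemble_cohort()] table (must contain `faller`).
#' @param spec A [feature_set_spec()].
#' @param config A [nested_cv_config()].
#' @return Object of class `fallrisk_cv`: list with `predictions` (tibble
#'   `subject_id`, `repeat_id`, `fold`, `truth`, `prob`), `report` (the
#'   pooled [performance_report()], averaged over repeats), `per_fold_auc`,
#'   `chosen_lambda` (per outer fold), `spec`, `config`, `features`.
#' @export
nested_cv_evaluate <- function(table, spec, config = nested_cv_config()) {
  if (!inherits(spec, "feature_set_spec")) {
    abort("`spec` must be a `feature_set_spec`", class = "fallrisk_error_validation")
  }
  y <- as.integer(table$faller)
  x_all <- cv_design(table, spec)
  ids <- if ("subject_id" %in% names(table)) table$subject_id else seq_len(nrow(table))
  grid <- config$lambda_grid

  all_preds <- list()
  all_fold_auc <- list()
  all_lambda <- list()
  reports <- list()
  for (rep_i in seq_len(config$n_repeats)) {
    set.seed(config$seed + rep_i - 1L)
    outer <- stratified_folds(y, config$outer_folds)
    preds <- tibble(subject_id = ids, repeat_id = rep_i, fold = outer,
                    truth = y, prob = NA_real_)
    lam_k <- numeric(config$outer_folds)
    for (k in seq_len(config$outer_folds)) {
      tr <- outer != k
      x_tr <- x_all[tr, , drop = FALSE]
      y_tr <- y[tr]
      inner <- stratified_folds(y_tr, config$inner_folds)
      auc_mat <- matrix(NA_real_, config$inner_folds, length(grid))
      for (j in seq_len(config$inner_folds)) {
        itr <- inner != j
        scaler <- if (config$standardize) fit_scaler(x_tr[itr, , drop = FALSE])
                  else list(mu = rep(0, ncol(x_tr)), sd = rep(1, ncol(x_tr)))
        fit <- fit_lasso(apply_scaler(x_tr[itr, , drop = FALSE], scaler),
                         y_tr[itr], grid)
        p <- predict_lasso(fit, apply_scaler(x_tr[!itr, , drop = FALSE], scaler), grid)
        auc_mat[j, ] <- apply(p, 2, function(col) auc_mw(y_tr[!itr], col))
      }
      mean_auc <- colMeans(auc_mat)
      # grid is descending, so the first index at the max is the largest penalty
      lam_k[k] <- grid[which(mean_auc >= max(mean_auc) - 1e-12)[1]]
      scaler <- if (config$standardize) fit_scaler(x_tr)
                else list(mu = rep(0, ncol(x_tr)), sd = rep(1, ncol(x_tr)))
      fit <- fit_lasso(apply_scaler(x_tr, scaler), y_tr, grid)
      preds$prob[!tr] <-
        as.numeric(predict_lasso(fit, apply_scaler(x_all[!tr, , drop = FALSE], scaler),
                                 lam_k[k]))
    }
    all_preds[[rep_i]] <- preds
    all_lambda[[rep_i]] <- tibble(repeat_id = rep_i,
                                  fold = seq_len(config$outer_folds),
                                  lambda = lam_k)
    all_fold_auc[[rep_i]] <- preds %>%
      group_by(.data$fold) %>%
      summarise(auc = auc_mw(.data$truth, .data$prob), .groups = "drop") %>%
      mutate(repeat_id = rep_i)
    reports[[rep_i]] <- performance_report(select(preds, "truth", "prob"))
  }

  report <- bind_rows(reports) %>% summarise(across(dplyr::everything(), mean))
  structure(list(predictions = bind_rows(all_preds),
                 report = report,
                 per_repeat_report = bind_rows(reports, .id = "repeat_id"),
                 per_fold_auc = bind_rows(all_fold_auc),
                 chosen_lambda = bind_rows(all_lambda),
                 spec = spec, config = config,
                 features = colnames(x_all)),
            class = "fallrisk_cv")
}

#' @export
print.fallrisk_cv <- function(x, ...) {
  cat(sprintf("<fallrisk_cv> feature set '%s' (%d features), %d-fold nested CV\n",
              x$spec$name, length(x$features), x$config$outer_folds))
  cat(sprintf("  pooled ROC AUC %.3f (95%% CI %.3f-%.3f), AP %.3f, MCC %.3f\n",
              x$report$roc_auc, x$report$ci_low, x$report$ci_high,
              x$report$mean_precision, x$report$mcc))
  invisible(x)
}

#' Tidy a nested-CV fit
#'
#' @param x A `fallrisk_cv` object.
#' @param ... Unused.
#' @return `tidy()`: per outer fold, the held-out AUC and the inner-loop
#'   penalty choice. `glance()`: the one-row pooled performance report.
#' @method tidy fallrisk_cv
#' @export
tidy.fallrisk_cv <- function(x, ...) {
  left_join(x$per_fold_auc, x$chosen_lambda, by = c("repeat_id", "fold")) %>%
    select("repeat_id", "fold", "auc", "lambda")
}

#' @rdname tidy.fallrisk_cv
#' @method glance fallrisk_cv
#' @export
glance.fallrisk_cv <- function(x, ...) {
  bind_cols(tibble(feature_set = x$spec$name,
                   n_features = length(x$features),
                   n_subjects = length(unique(x$predictions$subject_id))),
            x$report)
}

#' ROC curve of the pooled out-of-fold predictions
#'
#' @param object A `fallrisk_cv` object.
#' @param ... Unused.
#' @return A ggplot of the pooled ROC curve with the chance diagonal.
#' @method autoplot fallrisk_cv
#' @export
autoplot.fallrisk_cv <- function(object, ...) {
  p <- object$predictions
  thr <- c(Inf, sort(unique(p$prob), decreasing = TRUE), -Inf)
  curve <- purrr::map_dfr(thr, function(ct) {
    tibble(fpr = mean(p$prob[p$truth == 0] >= ct),
           tpr = mean(p$prob[p$truth == 1] >= ct))
  })
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC, %s (AUC %.2f)",
                                  object$spec$name, object$report$roc_auc))
}
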