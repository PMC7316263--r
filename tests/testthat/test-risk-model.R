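test_that("AUC equals exhaustive pair counting and handles ties", {
  p <- make_preds(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(roc_auc_delong(p)$auc, 1.0)

  p2 <- make_preds(c(1, 1, 0, 0), c(0.9, 0.3, 0.1, 0.4))
  expect_equal(roc_auc_delong(p2)$auc, 0.75)
  expect_equal(roc_auc_delong(p2)$auc, pair_count_auc(p2$truth, p2$prob))

  ties <- make_preds(rep(c(1, 0), 5), rep(0.5, 10))
  expect_equal(roc_auc_delong(ties)$auc, 0.5)

  set.seed(10)
  rnd <- make_preds(rbinom(40, 1, 0.4), round(runif(40), 1))  # many ties
  expect_equal(roc_auc_delong(rnd)$auc, pair_count_auc(rnd$truth, rnd$prob))

  expect_error(roc_auc_delong(make_preds(rep(1, 5), runif(5))),
               class = "fallrisk_error_single_class")
})

test_that("DeLong interval agrees with the bootstrap and matches pROC", {
  set.seed(21)
  n <- 50
  prob <- c(rbeta(n, 4, 2), rbeta(n, 2, 4))
  truth <- rep(c(1, 0), each = n)
  d <- roc_auc_delong(make_preds(truth, prob))

  boot <- replicate(1e4, {
    i <- sample(which(truth == 1), n, replace = TRUE)
    j <- sample(which(truth == 0), n, replace = TRUE)
    fallrisk:::auc_mw(c(rep(1, n), rep(0, n)), c(prob[i], prob[j]))
  })
  expect_equal(d$ci_low, quantile(boot, 0.025, names = FALSE), tolerance = 0.02)
  expect_equal(d$ci_high, quantile(boot, 0.975, names = FALSE), tolerance = 0.02)

  # independent implementation cross-check
  pr <- pROC::ci.auc(pROC::roc(truth, prob, quiet = TRUE), method = "delong")
  expect_equal(d$ci_low, pr[1], tolerance = 1e-9)
  expect_equal(d$auc, pr[2], tolerance = 1e-9)
  expect_equal(d$ci_high, pr[3], tolerance = 1e-9)

  # the interval shrinks roughly as 1/sqrt(n)
  set.seed(22)
  w100 <- roc_auc_delong(make_preds(rep(c(1, 0), each = 50),
                                    c(rbeta(50, 4, 2), rbeta(50, 2, 4))))
  w400 <- roc_auc_delong(make_preds(rep(c(1, 0), each = 200),
                                    c(rbeta(200, 4, 2), rbeta(200, 2, 4))))
  ratio <- (w400$ci_high - w400$ci_low) / (w100$ci_high - w100$ci_low)
  expect_equal(ratio, 0.5, tolerance = 0.2)
})

test_that("Youden cutoff maximizes J with the lower-cutoff tie-break", {
  p <- make_preds(c(1, 1, 0, 0), c(0.9, 0.3, 0.1, 0.4))
  # exhaustive J over midpoints: ties at 0.2 and 0.65, both J = 0.5
  ct <- youden_cutoff(p)
  expect_equal(as.numeric(ct), 0.2)
  expect_equal(attr(ct, "youden_j"), 0.5)

  sep <- make_preds(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(as.numeric(youden_cutoff(sep)), 0.5)  # gap midpoint

  deg <- youden_cutoff(make_preds(c(1, 0), c(0.4, 0.4)))
  expect_true(attr(deg, "degenerate"))
  expect_equal(attr(deg, "youden_j"), 0)
})

test_that("confusion metrics follow their definitions with the MCC zero rule", {
  perf <- make_preds(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  m <- classification_metrics(perf, 0.5)
  expect_equal(unlist(m[, c("sensitivity", "specificity", "ppv", "mcc")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, mcc = 1))

  # TP=2 TN=2 FP=1 FN=1 -> mcc = 3/9
  p <- make_preds(c(1, 1, 1, 0, 0, 0), c(0.9, 0.8, 0.1, 0.7, 0.2, 0.3))
  m2 <- classification_metrics(p, 0.5)
  expect_equal(m2$tp, 2); expect_equal(m2$fp, 1)
  expect_equal(m2$mcc, 1 / 3)

  # all predicted positive: specificity 0, mcc 0 by the zero-factor rule
  m3 <- classification_metrics(p, 0)
  expect_equal(m3$specificity, 0)
  expect_equal(m3$mcc, 0)
})

test_that("average precision matches brute-force PR construction", {
  expect_equal(mean_precision(make_preds(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))), 1)
  # single event ranked last of 10
  expect_equal(mean_precision(make_preds(c(rep(0, 9), 1),
                                         seq(0.95, 0.05, length.out = 10))), 0.1)

  # brute-force threshold enumeration oracle
  ap_oracle <- function(truth, prob) {
    thr <- sort(unique(prob), decreasing = TRUE)
    r_prev <- 0; ap <- 0
    for (v in thr) {
      tp <- sum(truth == 1 & prob >= v); fp <- sum(truth == 0 & prob >= v)
      r <- tp / sum(truth == 1)
      ap <- ap + (r - r_prev) * tp / (tp + fp)
      r_prev <- r
    }
    ap
  }
  p <- make_preds(c(1, 1, 0, 0), c(0.9, 0.4, 0.8, 0.1))
  expect_equal(mean_precision(p), ap_oracle(p$truth, p$prob))
  set.seed(14)
  p2 <- make_preds(rbinom(60, 1, 0.3), round(runif(60), 2))
  expect_equal(mean_precision(p2), ap_oracle(p2$truth, p2$prob))
})

test_that("rank metrics are invariant under monotone probability transforms", {
  set.seed(15)
  p <- make_preds(rbinom(80, 1, 0.4), runif(80))
  f <- function(x) plogis(3 * qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6)) + 1)
  q <- make_preds(p$truth, f(p$prob))
  expect_equal(roc_auc_delong(q)$auc, roc_auc_delong(p)$auc)
  expect_equal(mean_precision(q), mean_precision(p))
  cm_p <- classification_metrics(p, as.numeric(youden_cutoff(p)))
  cm_q <- classification_metrics(q, as.numeric(youden_cutoff(q)))
  expect_equal(cm_p$tp, cm_q$tp); expect_equal(cm_p$tn, cm_q$tn)
  # label flip mirrors the AUC
  expect_equal(roc_auc_delong(make_preds(1 - p$truth, p$prob))$auc,
               1 - roc_auc_delong(p)$auc)
})

test_that("a perfectly separating feature yields pooled AUC 1", {
  set.seed(30)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  tab <- tibble::tibble(subject_id = as.character(1:n),
                        sep = y * 2 + runif(n),   # disjoint supports
                        noise = rnorm(n),
                        faller = y)
  fit <- nested_cv_evaluate(tab, feature_set_spec("sep", robotic_vars = c("sep", "noise")),
                            nested_cv_config(seed = 5))
  expect_equal(fit$report$roc_auc, 1.0)
})

test_that("fold bookkeeping is leak-free and every subject is scored once", {
  set.seed(33)
  tab <- generate_cohort(cohort_sim_config(n = 100, seed = 8))
  spec <- feature_set_spec("few", clinical_vars = c("age", "low_gs"),
                           robotic_vars = c("ex4_trunk_apo", "ex5_cop_apo"))
  fit <- nested_cv_evaluate(tab, spec, nested_cv_config(seed = 6))
  pr <- fit$predictions
  expect_equal(sort(pr$subject_id), sort(tab$subject_id))
  expect_false(any(duplicated(pr$subject_id)))
  expect_true(all(is.finite(pr$prob)))
  # outer folds partition the cohort and are stratified
  expect_equal(sort(unique(pr$fold)), 1:5)
  by_fold <- dplyr::count(pr, fold, truth)
  expect_true(all(by_fold$n >= 1))
})

test_that("permuted labels drive the cross-validated AUC to chance", {
  set.seed(40)
  n <- 500
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("v", 1:8)))
  aucs <- sapply(1:20, function(s) {
    y <- sample(rep(c(0, 1), c(n - n %/% 3, n %/% 3)))   # permuted outcome
    tab <- dplyr::bind_cols(tibble::tibble(subject_id = as.character(1:n),
                                           faller = y), tibble::as_tibble(x))
    nested_cv_evaluate(tab, feature_set_spec("noise", robotic_vars = colnames(x)),
                       nested_cv_config(seed = s))$report$roc_auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("an overwhelming penalty flattens the model to chance", {
  set.seed(41)
  tab <- generate_cohort(cohort_sim_config(n = 120, seed = 3))
  spec <- feature_set_spec("sig", robotic_vars = c("ex4_trunk_apo", "ex5_cop_apo"))
  fit <- nested_cv_evaluate(tab, spec,
                            nested_cv_config(lambda_grid = c(1e3, 2e3), seed = 2))
  expect_equal(fit$report$roc_auc, 0.5, tolerance = 0.08)
})

test_that("stratification errors surface for degenerate classes", {
  tab <- tibble::tibble(subject_id = as.character(1:10),
                        x = rnorm(10), faller = c(rep(0, 9), 1))
  expect_error(nested_cv_evaluate(tab, feature_set_spec("x", robotic_vars = "x"),
                                  nested_cv_config(seed = 1)),
               class = "fallrisk_error_stratification")
  tab2 <- tibble::tibble(subject_id = as.character(1:40),
                         x = c(NA, rnorm(39)), faller = rep(c(0, 1), 20))
  expect_error(nested_cv_evaluate(tab2, feature_set_spec("x", robotic_vars = "x"),
                                  nested_cv_config(seed = 1)),
               class = "fallrisk_error_validation")
})

test_that("tidy and glance summarize a fit", {
  tab <- generate_cohort(cohort_sim_config(n = 80, seed = 12))
  fit <- nested_cv_evaluate(tab, feature_set_spec("a", robotic_vars = "ex4_trunk_apo"),
                            nested_cv_config(seed = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_true(all(c("fold", "auc", "lambda") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 80)
  expect_true(gl$ci_low <= gl$roc_auc && gl$roc_auc <= gl$ci_high)
})
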