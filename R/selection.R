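#' Evaluate a menu of candidate feature sets
#'
#' Runs [nested_cv_evaluate()] on each candidate with a common seed and
#' returns the trace sorted by pooled ROC AUC (descending), with variable
#' count as the tie-break: among sets whose AUC ties within `auc_tol`,
#' the most parsimonious wins.
#'
#' @param table Cohort table.
#' @param menu Named list of [feature_set_spec()] objects.
#' @param config A [nested_cv_config()]; the same seed is used for every
#'   candidate so folds are shared.
#' @param auc_tol AUC difference regarded as a tie (default 0.005).
#' @param step_id Optional label recorded on every row.
#' @return Tibble of class `selection_trace`: one row per candidate with
#'   `step_id`, `name`, `n_vars`, the performance-report columns and
#'   `chosen` flagging the winner. The fitted objects are in the `fit`
#'   list-column.
#' @export
evaluate_menu <- function(table, menu, config = nested_cv_config(),
                          auc_tol = 0.005, step_id = NA_character_) {
  if (length(menu) == 0) {
    abort("empty menu", class = "fallrisk_error_validation")
  }
  rows <- purrr::map(menu, function(spec) {
    fit <- nested_cv_evaluate(table, spec, config)
    bind_cols(tibble(name = spec$name,
                     n_vars = length(spec$clinical_vars) + length(spec$robotic_vars)),
              fit$report) %>%
      mutate(fit = list(fit))
  })
  trace <- bind_rows(rows) %>%
    arrange(dplyr::desc(.data$roc_auc), .data$n_vars) %>%
    mutate(step_id = step_id, .before = 1)
  best_auc <- max(trace$roc_auc)
  tied <- which(trace$roc_auc >= best_auc - auc_tol)
  winner <- tied[which.min(trace$n_vars[tied])]
  trace$chosen <- seq_len(nrow(trace)) == winner
  class(trace) <- c("selection_trace", class(tibble()))
  trace
}

chosen_spec <- function(trace) trace$fit[[which(trace$chosen)]]$spec

#' Three-step clinical/robotic configuration search
#'
#' Reproduces the staged model-selection procedure: (1) with the robotic
#' variables fixed to an anchor set, compare the clinical menus and keep
#' the winner; (2) with that clinical set fixed, compare the robotic menus;
#' (3) with the winning robotic set fixed, re-compare the clinical menus to
#' confirm the combination. The final model is the step-3 winner. Winners
#' maximize cross-validated ROC AUC with the fewest variables among ties.
#'
#' @param table Cohort table.
#' @param clinical_menu,robotic_menu Named lists of [feature_set_spec()]
#'   carrying only clinical / only robotic variables.
#' @param anchor_robotic A [feature_set_spec()] of robotic variables used
#'   as the fixed context in step 1.
#' @param config A [nested_cv_config()].
#' @param auc_tol Tie tolerance passed to [evaluate_menu()].
#' @return List of class `selection_result`: `trace` (all three steps,
#'   row-bound), `chosen` (the final combined [feature_set_spec()]),
#'   `chosen_fit` (its `fallrisk_cv`), and the per-step winners.
#' @export
stepwise_search <- function(table, clinical_menu, robotic_menu, anchor_robotic,
                            config = nested_cv_config(), auc_tol = 0.005) {
  combine <- function(cl, rb, name) {
    feature_set_spec(name, clinical_vars = cl$clinical_vars,
                     robotic_vars = rb$robotic_vars)
  }
  step1_menu <- purrr::map(clinical_menu, ~ combine(.x, anchor_robotic,
                                                    paste0(.x$name, " + anchor robotic")))
  s1 <- evaluate_menu(table, step1_menu, config, auc_tol,
                      step_id = "clinical_given_robotic")
  best_clinical <- clinical_menu[[which(names(clinical_menu) ==
    sub(" \\+ anchor robotic$", "", chosen_spec(s1)$name))[1]]]

  step2_menu <- purrr::map(robotic_menu, ~ combine(best_clinical, .x,
                                                   paste0(best_clinical$name, " + ", .x$name)))
  s2 <- evaluate_menu(table, step2_menu, config, auc_tol,
                      step_id = "robotic_given_clinical")
  best_robotic_name <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1",
                                            best_clinical$name), " \\+ "),
                           "", chosen_spec(s2)$name)
  best_robotic <- robotic_menu[[which(names(robotic_menu) == best_robotic_name)[1]]]

  step3_menu <- purrr::map(clinical_menu, ~ combine(.x, best_robotic,
                                                    paste0(.x$name, " + ", best_robotic$name)))
  s3 <- evaluate_menu(table, step3_menu, config, auc_tol, step_id = "clinical_confirm")
  trace <- bind_rows(s1, s2, s3)
  class(trace) <- c("selection_trace", class(tibble()))
  structure(list(trace = trace,
                 chosen = chosen_spec(s3),
                 chosen_fit = s3$fit[[which(s3$chosen)]],
                 step1_clinical = best_clinical,
                 step2_robotic = best_robotic),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> final feature set: '%s' (%d clinical + %d robotic variables)\n",
              x$chosen$name, length(x$chosen$clinical_vars),
              length(x$chosen$robotic_vars)))
  print(select(as_tibble(x$trace), "step_id", "name", "n_vars", "roc_auc", "chosen"))
  invisible(x)
}

#' AUC ranking plot of a selection trace
#'
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot of candidate AUCs (with DeLong CIs) per search step.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roc_auc,
                                  y = stats::reorder(.data$name, .data$roc_auc),
                                  colour = .data$chosen)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::facet_wrap(~step_id, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = "cross-validated ROC AUC", y = NULL,
                  title = "Feature-set selection trace")
}

#' Canonical robotic feature catalogue and preset menus
#'
#' `robotic_feature_catalogue()` lists the 46 canonical per-subject robotic
#' feature names produced by the extraction pipeline (4 limits-of-stability
#' reaches; 7 sway/trunk indicators for each of the four standing balance
#' exercises; 11 perturbation-response features; 3 sit-to-stand durations).
#'
#' `clinical_menus()` returns the screening-style clinical variable menus
#' (each individual mobility instrument added to the basic age / sex /
#' fall-history data, then all together, with and without drug count, and
#' the minimal age / fall-history / slow-gait set).
#' `robotic_menus()` returns the robotic menus: all variables, the
#' reconstructed previous-study trunk-control subset, dynamic-only
#' (Exercises 3-7), static-only (Exercises 1-2), and a reconstructed
#' literature-informed dynamic selection. The two reconstructed subsets are
#' synthesized from the published results narrative, not from the original
#' (unavailable) supplementary lists.
#'
#' @return Character vector (catalogue) or named list of
#'   [feature_set_spec()] (menus).
#' @export
robotic_feature_catalogue <- function() {
  balance <- function(ex, src) {
    paste0("ex", ex, "_", c(paste0(src, c("_sa", "_sp", "_apo", "_mlo")),
                            "trunk_apo", "trunk_mlo", "trunk_va"))
  }
  c(paste0("ex1_los_", c("forward", "backward", "left", "right")),
    balance(2, "cop"), balance(3, "cop"), balance(4, "proj"), balance(5, "cop"),
    paste0("ex6_", c("osc_time_forward", "osc_time_left", "osc_time_right",
                     "max_tilt_ap", "max_tilt_ml",
                     "apo_forward", "apo_left", "apo_right",
                     "mlo_forward", "mlo_left", "mlo_right")),
    paste0("ex7_", c("total_duration", "mean_stand", "mean_sit")))
}

#' @rdname robotic_feature_catalogue
#' @export
clinical_menus <- function() {
  base <- c("age", "sex", "history_of_falling")
  list(
    all_clinical = feature_set_spec("all clinical",
      clinical_vars = c(base, "tug", "poma", "sppb", "gait_speed", "low_gs", "n_drugs")),
    base_sppb = feature_set_spec("age sex history sppb", clinical_vars = c(base, "sppb")),
    base_only = feature_set_spec("age sex history", clinical_vars = base),
    base_gs = feature_set_spec("age sex history gait speed",
      clinical_vars = c(base, "gait_speed")),
    base_lowgs = feature_set_spec("age sex history low gs",
      clinical_vars = c(base, "low_gs")),
    minimal = feature_set_spec("age history low gs",
      clinical_vars = c("age", "history_of_falling", "low_gs")),
    screening = feature_set_spec("age sex history tug poma sppb low gs",
      clinical_vars = c(base, "tug", "poma", "sppb", "low_gs")))
}

#' @rdname robotic_feature_catalogue
#' @export
robotic_menus <- function() {
  cat46 <- robotic_feature_catalogue()
  dynamic <- cat46[grepl("^ex[3-7]_", cat46)]
  static <- cat46[grepl("^ex[12]_", cat46)]
  trunk_standing <- cat46[grepl("^ex[2-5]_trunk_", cat46)]  # reconstructed
  literature_dynamic <- c("ex4_trunk_apo", "ex4_proj_apo", "ex4_trunk_va",
                          "ex5_cop_apo", "ex5_cop_mlo", "ex5_trunk_va",
                          "ex6_max_tilt_ml", "ex1_los_forward",
                          "ex6_osc_time_forward", "ex6_osc_time_left",
                          "ex6_osc_time_right", "ex6_max_tilt_ap",
                          "ex5_trunk_apo", "ex5_trunk_mlo", "ex4_trunk_mlo",
                          "ex6_apo_forward", "ex6_mlo_left", "ex6_mlo_right",
                          "ex7_total_duration", "ex7_mean_stand")  # reconstructed
  # the literature set is dynamic-only by construction except the LOS reach,
  # which the results narrative singles out; kept, flagged reconstructed
  list(
    all_robotic = feature_set_spec("all robotic", robotic_vars = cat46),
    previous_study = feature_set_spec("previous-study trunk subset (reconstructed)",
      robotic_vars = trunk_standing),
    dynamic_only = feature_set_spec("all dynamic (ex 3-7)", robotic_vars = dynamic),
    static_only = feature_set_spec("all static (ex 1-2)", robotic_vars = static),
    literature_dynamic = feature_set_spec("literature dynamic (reconstructed)",
      robotic_vars = literature_dynamic))
}

#' Read / write feature-set menus as YAML
#'
#' @param menus Named list of [feature_set_spec()].
#' @param path YAML file path.
#' @return `read_menus()` returns a named list of [feature_set_spec()].
#' @export
write_menus <- function(menus, path) {
  yaml::write_yaml(purrr::map(menus, function(s) {
    list(name = s$name, clinical_vars = as.list(s$clinical_vars),
         robotic_vars = as.list(s$robotic_vars))
  }), path)
  invisible(path)
}

#' @rdname write_menus
#' @export
read_menus <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(s) {
    feature_set_spec(s$name,
                     clinical_vars = unlist(s$clinical_vars) %||% character(),
                     robotic_vars = unlist(s$robotic_vars) %||% character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
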