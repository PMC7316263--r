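#' Dichotomize gait speed at the slow-walker threshold
#'
#' Gait speed below 0.8 m/s is the conventional slow-walking cut-off used
#' in fall-risk screening; the boundary value 0.8 itself counts as not slow
#' (strict inequality).
#'
#' @param gait_speed Gait speed(s) in m/s, strictly positive.
#' @param threshold Threshold in m/s (default 0.8).
#' @return Logical vector: `TRUE` where speed < threshold.
#' @export
dichotomize_gait_speed <- function(gait_speed, threshold = 0.8) {
  if (any(!is.finite(gait_speed) | gait_speed <= 0)) {
    abort("gait_speed must be finite and > 0", class = "fallrisk_error_validation")
  }
  gait_speed < threshold
}

#' Assemble the per-subject analysis table
#'
#' Inner-joins clinical records, extracted robotic feature rows and
#' follow-up fall outcomes on `subject_id`, derives the dichotomous
#' `low_gs` indicator from gait speed, and encodes sex (male 0 / female 1)
#' and the faller outcome (0/1). Subjects without an outcome are dropped
#' with a warning; duplicated ids are an error.
#'
#' @param clinical Data frame with `subject_id`, `age`, `sex`
#'   (`"male"`/`"female"` or 0/1), `history_of_falling` (logical or 0/1),
#'   `n_drugs`, `tug`, `poma`, `sppb`, `gait_speed`, plus any optional
#'   clinical columns.
#' @param features Data frame of robotic features keyed by `subject_id`
#'   (canonical `ex{N}_*` names), or `NULL` for a clinical-only table.
#' @param outcomes Data frame with `subject_id` and `faller` (logical or
#'   0/1).
#' @return Tibble of class `cohort_table`, one row per modelled subject.
#' @export
assemble_cohort <- function(clinical, features = NULL, outcomes) {
  clinical <- as_tibble(clinical)
  outcomes <- as_tibble(outcomes)
  for (nm in c("clinical", "features", "outcomes")) {
    d <- switch(nm, clinical = clinical, features = features, outcomes = outcomes)
    if (!is.null(d) && anyDuplicated(d$subject_id)) {
      abort(paste0("duplicated subject_id in `", nm, "`"),
            class = "fallrisk_error_duplicate_id")
    }
  }
  if (is.character(clinical$sex) || is.factor(clinical$sex)) {
    clinical$sex <- as.integer(as.character(clinical$sex) == "female")
  }
  clinical$history_of_falling <- as.integer(clinical$history_of_falling)
  clinical$low_gs <- as.integer(dichotomize_gait_speed(clinical$gait_speed))
  out <- clinical
  if (!is.null(features)) {
    out <- inner_join(out, as_tibble(features), by = "subject_id")
  }
  missing_outcome <- setdiff(out$subject_id, outcomes$subject_id)
  if (length(missing_outcome) > 0) {
    warn(sprintf("%d subject(s) without follow-up outcome excluded: %s",
                 length(missing_outcome),
                 paste(utils::head(missing_outcome, 5), collapse = ", ")))
  }
  out <- inner_join(out, outcomes, by = "subject_id")
  out$faller <- as.integer(out$faller)
  class(out) <- c("cohort_table", class(tibble()))
  out
}

# variables treated as categorical in group comparisons
cohort_categorical_vars <- c("sex", "history_of_falling", "low_gs", "faller")

#' Faller vs non-faller baseline comparison
#'
#' For every variable in the table (other than `subject_id` and the outcome)
#' compares fallers with non-fallers: continuous variables by an unpaired
#' two-sided t-test (Welch by default) with group means +- SD; categorical
#' variables by a two-sided Fisher exact test on the 2 x 2 contingency
#' table, with counts and percentages.
#'
#' @param table A [assemble_cohort()] table (or any data frame with a
#'   0/1 `faller` column).
#' @param vars Variables to compare; defaults to all non-id, non-outcome
#'   columns.
#' @param categorical Variables to treat as categorical (default: sex,
#'   history of falling, low gait speed, plus any 0/1-valued column).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble: `variable`, `type`, `faller_mean`, `faller_sd`,
#'   `nonfaller_mean`, `nonfaller_sd` (for categorical variables the
#'   mean is the proportion and counts are in `faller_n_pos` /
#'   `nonfaller_n_pos`), `test`, `p_value`. A continuous variable with
#'   fewer than 2 observations in a group gets `NA` p.
#' @export
compare_groups <- function(table, vars = NULL, categorical = NULL,
                           var_equal = FALSE) {
  if (!"faller" %in% names(table)) {
    abort("`table` must contain a 0/1 `faller` outcome column",
          class = "fallrisk_error_validation")
  }
  g <- as.integer(table$faller)
  if (length(unique(g[!is.na(g)])) != 2) {
    abort("both outcome groups must be non-empty",
          class = "fallrisk_error_validation")
  }
  if (is.null(vars)) {
    vars <- setdiff(names(table), c("subject_id", "faller"))
  }
  is_binary <- function(v) all(v[!is.na(v)] %in% c(0, 1))
  if (is.null(categorical)) {
    categorical <- union(intersect(cohort_categorical_vars, vars),
                         vars[vapply(table[vars], is_binary, logical(1))])
  }
  purrr::map_dfr(vars, function(v) {
    x <- table[[v]]
    xf <- x[g == 1 & !is.na(x)]
    xn <- x[g == 0 & !is.na(x)]
    if (v %in% categorical) {
      tab <- matrix(c(sum(xf == 1), sum(xf == 0),
                      sum(xn == 1), sum(xn == 0)), nrow = 2)
      p <- fisher.test(tab, alternative = "two.sided")$p.value
      tibble(variable = v, type = "categorical",
             faller_mean = mean(xf), faller_sd = NA_real_,
             nonfaller_mean = mean(xn), nonfaller_sd = NA_real_,
             faller_n_pos = sum(xf == 1), nonfaller_n_pos = sum(xn == 1),
             test = "fisher_exact", p_value = p)
    } else {
      p <- if (length(xf) < 2 || length(xn) < 2) NA_real_ else
        t.test(xf, xn, var.equal = var_equal)$p.value
      tibble(variable = v, type = "continuous",
             faller_mean = mean(xf), faller_sd = sd(xf),
             nonfaller_mean = mean(xn), nonfaller_sd = sd(xn),
             faller_n_pos = NA_integer_, nonfaller_n_pos = NA_integer_,
             test = if (var_equal) "t_pooled" else "t_welch", p_value = p)
    }
  })
}

#' Read / write a cohort table
#'
#' Plain CSV (UTF-8, comma separated, `.` decimal, NA as empty field) with
#' one row per subject.
#'
#' @param table A `cohort_table`.
#' @param path CSV path.
#' @return `read_cohort()` returns a `cohort_table`; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- as_tibble(utils::read.csv(path, na.strings = ""))
  class(out) <- c("cohort_table", class(tibble()))
  out
}
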