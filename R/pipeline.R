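#' Derive stage seeds from a global seed
#'
#' Deterministic fan-out of one global seed into per-stage, per-subject
#' seeds so every stochastic stage is independently reproducible. Values
#' stay below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Stage index (1 = simulate sessions, 2 = cohort, ...).
#' @param unit Unit index within the stage (subject, session, ...).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage, unit = 0) {
  as.integer((as.numeric(seed) * 1000003 + stage * 10007 + unit) %% 2147483647)
}

#' Write / read a JSON report with provenance metadata
#'
#' Every pipeline artifact carries `meta` (stage name, seed, schema
#' version) next to its `data` payload.
#'
#' @param data A data frame or list to serialize.
#' @param path JSON path.
#' @param stage Stage label recorded in the metadata.
#' @param seed Seed recorded in the metadata.
#' @return `read_report()` returns `list(meta, data)`.
#' @export
write_report <- function(data, path, stage, seed = NA_integer_) {
  jsonlite::write_json(list(meta = list(stage = stage, seed = seed,
                                        schema_version = "1.0",
                                        package = "fallrisk"),
                            data = data),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the simulate - extract - evaluate - compare pipeline
#'
#' End-to-end driver over the package's stages: simulate per-subject
#' session recordings, extract the canonical robotic features, attach
#' simulated clinical variables and outcomes, evaluate feature sets by
#' nested cross-validated lasso, and compare models by NRI/IDI. Identical
#' configurations reproduce identical outputs; every artifact written to
#' `out_dir` carries stage/seed provenance.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Global seed (fanned out via [derive_seed()]).
#' @param exercises Which exercises to simulate per subject (default all 7).
#' @param specs Named list of [feature_set_spec()] to evaluate; default a
#'   clinical-only and a clinical + robotic model.
#' @param cv_config A [nested_cv_config()]; its seed is overridden by the
#'   derived stage seed.
#' @param out_dir Optional output directory; when given, the feature table,
#'   cohort CSV, performance reports and comparison report are written.
#' @param instability_by_outcome Mean instability multipliers for
#'   non-fallers / fallers used when simulating sessions (default
#'   `c(1, 1.35)`), so fallers sway more.
#' @return List of class `fallrisk_pipeline`: `cohort`, `features`, `fits`
#'   (named list of `fallrisk_cv`), `reports` (tibble), `comparison`
#'   (tibble or NULL when fewer than two specs).
#' @export
run_pipeline <- function(n_subjects = 60, seed = 1, exercises = 1:7,
                         specs = NULL, cv_config = nested_cv_config(),
                         out_dir = NULL,
                         instability_by_outcome = c(1, 1.35)) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # stage 1: clinical frame + outcomes from the cohort generator
  cohort_cfg <- cohort_sim_config(n = n_subjects, seed = derive_seed(seed, 2))
  base_cohort <- generate_cohort(cohort_cfg)
  clinical_cols <- c("subject_id", "age", "sex", "history_of_falling",
                     "n_drugs", "tug", "poma", "sppb", "gait_speed", "low_gs")

  # stage 2: simulate sessions per subject and extract measured features
  features <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    ins <- instability_by_outcome[base_cohort$faller[i] + 1] *
      exp(rnorm(1, 0, 0.15))
    profile <- subject_profile(instability = ins)
    sessions <- purrr::map(exercises, function(ex) {
      generate_session(profile, ex, seed = derive_seed(seed, 1, i * 10 + ex),
                       subject_id = base_cohort$subject_id[i])$recording
    })
    extract_features(sessions, subject_id = base_cohort$subject_id[i])
  })

  # stage 3: assemble measured-feature cohort
  cohort <- assemble_cohort(
    clinical = as_tibble(base_cohort)[, intersect(clinical_cols, names(base_cohort))],
    features = features,
    outcomes = tibble(subject_id = base_cohort$subject_id,
                      faller = base_cohort$faller))

  # stage 4: evaluate feature sets
  measured <- setdiff(names(features), "subject_id")
  measured <- measured[vapply(cohort[measured],
                              function(v) all(is.finite(v)), logical(1))]
  if (is.null(specs)) {
    specs <- list(
      clinical = feature_set_spec("clinical",
        clinical_vars = c("age", "sex", "history_of_falling", "tug",
                          "poma", "sppb", "low_gs")),
      combined = feature_set_spec("clinical + robotic",
        clinical_vars = c("age", "history_of_falling", "low_gs"),
        robotic_vars = measured))
  }
  cv_config$seed <- derive_seed(seed, 3)
  fits <- purrr::map(specs, ~ nested_cv_evaluate(cohort, .x, cv_config))
  reports <- purrr::imap_dfr(fits, ~ mutate(glance(.x), model = .y, .before = 1))

  # stage 5: reclassification comparison of the first model against the rest
  comparison <- NULL
  if (length(fits) >= 2) {
    comparison <- purrr::map_dfr(seq(2, length(fits)), function(j) {
      compare_risk_models(fits[[1]], fits[[j]])
    })
  }

  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(as.data.frame(features),
                     file.path(out_dir, "features.csv"), row.names = FALSE, na = "")
    write_report(reports, file.path(out_dir, "performance.json"),
                 stage = "evaluate", seed = seed)
    if (!is.null(comparison)) {
      write_report(comparison, file.path(out_dir, "comparison.json"),
                   stage = "compare", seed = seed)
    }
  }
  structure(list(cohort = cohort, features = features, fits = fits,
                 reports = reports, comparison = comparison, seed = seed),
            class = "fallrisk_pipeline")
}

#' @export
print.fallrisk_pipeline <- function(x, ...) {
  cat(sprintf("<fallrisk_pipeline> %d subjects, %d model(s), seed %d\n",
              nrow(x$cohort), length(x$fits), x$seed))
  print(select(x$reports, "model", "n_features", "roc_auc", "ci_low",
               "ci_high", "sensitivity", "specificity", "mcc"))
  if (!is.null(x$comparison)) {
    print(select(x$comparison, "model_old", "model_new", "nri", "nri_p",
                 "idi", "idi_p"))
  }
  invisible(x)
}
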