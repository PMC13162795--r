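#' Assemble a run configuration
#'
#' A fully serializable bundle of everything a reproducible run needs:
#' input paths, split plan, base-model hyperparameters, fusion parameters,
#' tuning grids, evaluation options, and the root seed. The resolved
#' configuration is written verbatim into every run's manifest.
#'
#' @param input optional input CSV path (cohort or confidence matrix).
#' @param plan a [split_plan()].
#' @param specs base-model specs (see [default_base_specs()]).
#' @param weights fusion [distance_weights()].
#' @param beta membership decay rate.
#' @param normalize metric normalization switch.
#' @param threshold fuzzy-score decision threshold.
#' @param weight_step simplex grid increment for weight tuning.
#' @param n_bins calibration bins.
#' @param bootstrap_B bootstrap resamples.
#' @param alpha significance level.
#' @param generator a [generator_spec()] for `simulate` runs.
#' @param seed root seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, plan = split_plan(),
                       specs = default_base_specs(),
                       weights = distance_weights(), beta = 2.0,
                       normalize = TRUE, threshold = 0.5,
                       weight_step = 0.05, n_bins = 10L,
                       bootstrap_B = 1000L, alpha = 0.05,
                       generator = generator_spec(), seed = 42L) {
  structure(list(input = input, plan = plan, specs = specs,
                 weights = weights, beta = beta, normalize = normalize,
                 threshold = threshold, weight_step = weight_step,
                 n_bins = n_bins, bootstrap_B = bootstrap_B, alpha = alpha,
                 generator = generator, seed = as.integer(seed)),
            class = "run_config")
}

serialize_config <- function(config) {
  enc <- function(x) {
    if (is.list(x)) lapply(unclass(x), enc) else unclass(x)
  }
  enc(config)
}

write_manifest <- function(config, subcommand, out_dir, extra = list()) {
  manifest <- c(list(subcommand = subcommand,
                     package_version = as.character(utils::packageVersion("mmfde")),
                     config = serialize_config(config)),
                extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

read_confidence_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  pos_cols <- grep("_(pos|1)$", names(df), value = TRUE)
  if (length(pos_cols) == 0L) {
    stop("confidence CSV needs positive-class columns named <model>_pos or <model>_1")
  }
  m <- as.matrix(df[pos_cols])
  colnames(m) <- sub("_(pos|1)$", "", pos_cols)
  confidence_matrix(m)
}

#' Run a workbench subcommand
#'
#' Reproducible front end tying the modules together. Every run writes a
#' `manifest.json` carrying the resolved configuration into `out_dir`,
#' alongside the subcommand's artifacts (CSV/JSON). Identical configuration
#' and seed give byte-identical artifacts.
#'
#' Subcommands: `simulate` (synthetic cohort CSV + generator sidecar),
#' `train` (fit base models on the training partition; fold assignments and
#' model metadata), `tune` (weight and beta grid search; traces as JSON),
#' `fuse` (fuse a confidence-matrix CSV; fusion CSV), `evaluate` (fused
#' test-set metrics, calibration JSON), `explain` (attribution and
#' global-importance CSVs, concordance JSON), `report` (worked-example
#' fixture table).
#'
#' @param subcommand one of simulate, train, tune, fuse, evaluate, explain,
#'   report.
#' @param config a [run_config()].
#' @param out_dir artifact directory (created if needed).
#' @return list of artifact paths (plus in-memory results), invisibly.
#' @export
run_workbench <- function(subcommand, config = run_config(),
                          out_dir = tempfile("mmfde-run-")) {
  known <- c("simulate", "train", "tune", "fuse", "evaluate", "explain", "report")
  if (!is.character(subcommand) || length(subcommand) != 1L ||
      !subcommand %in% known) {
    stop(sprintf("usage: unknown subcommand '%s' (expected one of %s)",
                 paste(subcommand, collapse = ","), paste(known, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- write_manifest(config, subcommand, out_dir)
  artifacts <- list(manifest = manifest)

  if (subcommand == "simulate") {
    cohort <- generate_cohort(config$generator)
    artifacts$cohort <- write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(serialize_config(config$generator),
                         file.path(out_dir, "generator.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$generator <- file.path(out_dir, "generator.json")
  } else if (subcommand == "train") {
    cohort <- load_cohort(config)
    sp <- train_test_split(cohort, config$plan)
    pp <- preprocess_cohort(cohort, fit_on = sp$train)
    ens <- train_base_models(cohort_table(pp$features[sp$train, , drop = FALSE],
                                          pp$outcome[sp$train],
                                          check_ranges = FALSE), config$specs)
    folds <- stratified_folds(cohort$outcome[sp$train], config$plan$n_folds,
                              config$plan$seed)
    utils::write.csv(data.frame(row = sp$train, fold = folds),
                     file.path(out_dir, "folds.csv"), row.names = FALSE)
    meta <- lapply(config$specs, unclass)
    meta$adaboost$base_learner_depth <- 1L  # stump default, logged explicitly
    jsonlite::write_json(meta, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$folds <- file.path(out_dir, "folds.csv")
    artifacts$models <- file.path(out_dir, "models.json")
    artifacts$ensemble <- ens
    artifacts$split <- sp
  } else if (subcommand == "tune") {
    cohort <- load_cohort(config)
    sp <- train_test_split(cohort, config$plan)
    train_cohort <- cohort_table(cohort$features[sp$train, , drop = FALSE],
                                 cohort$outcome[sp$train], check_ranges = FALSE)
    cv <- cv_confidences(train_cohort, config$specs, config$plan)
    tw <- search_weights(cv, enumerate_weight_grid(config$weight_step),
                         beta = config$beta, normalize = config$normalize)
    tb <- search_beta(train_cohort, config$specs, tw$best_weights,
                      seed = config$seed, normalize = config$normalize)
    jsonlite::write_json(
      list(best_weights = as.list(unclass(tw$best_weights)),
           best_beta = tb$best_beta,
           beta_trace = as.list(tb$objective_trace),
           n_candidates = length(tw$cv_accuracy_by_candidate),
           best_cv_accuracy = max(tw$cv_accuracy_by_candidate)),
      file.path(out_dir, "tuning.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    surf <- stability_surface(cv, resolution = 0.1, normalize = config$normalize)
    utils::write.csv(surf, file.path(out_dir, "stability_surface.csv"),
                     row.names = FALSE)
    artifacts$tuning <- file.path(out_dir, "tuning.json")
    artifacts$surface <- file.path(out_dir, "stability_surface.csv")
  } else if (subcommand == "fuse") {
    cmat <- read_confidence_csv(config$input)
    res <- fuse_confidences(cmat, config$weights, config$beta,
                            config$normalize, config$threshold)
    artifacts$fusion <- write_fusion_csv(res, file.path(out_dir, "fusion.csv"))
    artifacts$results <- res
  } else if (subcommand == "evaluate") {
    cohort <- load_cohort(config)
    sp <- train_test_split(cohort, config$plan)
    pp <- preprocess_cohort(cohort, fit_on = sp$train)
    ens <- train_base_models(cohort_table(pp$features[sp$train, , drop = FALSE],
                                          pp$outcome[sp$train],
                                          check_ranges = FALSE), config$specs)
    conf <- predict_confidences(ens, pp$features[sp$test, , drop = FALSE])
    res <- fuse_confidences(conf, config$weights, config$beta,
                            config$normalize, config$threshold)
    y_test <- cohort$outcome[sp$test]
    mr <- classification_metrics(confusion_counts(res$label, y_test))
    rk <- ranking_metrics(res$fuzzy_score, y_test)
    cal <- calibration_report(res, y_test, config$n_bins)
    jsonlite::write_json(
      list(accuracy = mr$accuracy, precision = mr$precision,
           recall = mr$recall, f1 = mr$f1, auc = rk$auc, pr_auc = rk$pr_auc,
           pr_convention = rk$pr_convention, n = mr$n, ece = cal$ece,
           ece_bins = cal$n_bins, ece_axis = cal$axis,
           level_distribution = as.list(cal$level_distribution)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(cal$bins, file.path(out_dir, "reliability_bins.csv"),
                     row.names = FALSE)
    artifacts$metrics <- file.path(out_dir, "metrics.json")
    artifacts$reliability <- file.path(out_dir, "reliability_bins.csv")
    artifacts$results <- res
  } else if (subcommand == "explain") {
    cohort <- load_cohort(config)
    sp <- train_test_split(cohort, config$plan)
    pp <- preprocess_cohort(cohort, fit_on = sp$train)
    ens <- train_base_models(cohort_table(pp$features[sp$train, , drop = FALSE],
                                          pp$outcome[sp$train],
                                          check_ranges = FALSE), config$specs)
    x_test <- pp$features[sp$test, , drop = FALSE]
    conf <- predict_confidences(ens, x_test)
    res <- fuse_confidences(conf, config$weights, config$beta,
                            config$normalize, config$threshold)
    attr_tab <- explain_predictions(ens, x_test, mode = "per_model_mean")
    utils::write.csv(as.data.frame(attr_tab$values),
                     file.path(out_dir, "attributions.csv"), row.names = FALSE)
    utils::write.csv(global_importance(attr_tab),
                     file.path(out_dir, "global_importance.csv"),
                     row.names = FALSE)
    conc <- concordance_analysis(attr_tab, res, cohort$outcome[sp$test])
    jsonlite::write_json(
      list(mode = attr_tab$mode,
           concordance_pct = conc$concordance_pct,
           discordance_pct = conc$discordance_pct,
           pct_discordant_with_moderate_confidence =
             conc$pct_discordant_with_moderate_confidence,
           misclassification_rate_concordant =
             conc$misclassification_rate_concordant,
           misclassification_rate_discordant =
             conc$misclassification_rate_discordant,
           n = conc$n, n_excluded_zero = conc$n_excluded_zero),
      file.path(out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    artifacts$attributions <- file.path(out_dir, "attributions.csv")
    artifacts$importance <- file.path(out_dir, "global_importance.csv")
    artifacts$concordance <- file.path(out_dir, "concordance.json")
  } else if (subcommand == "report") {
    fix <- worked_example_fixture()
    score <- fuzzy_score(fix$mu_pos, fix$mu_neg)
    tab <- data.frame(
      sample = rownames(fix$probabilities),
      mu_pos = fix$mu_pos,
      mu_neg = fix$mu_neg,
      fuzzy_score = round(score, 4),
      confidence_level = as.character(confidence_level(pmax(fix$mu_pos, fix$mu_neg))),
      prediction = decide_label(score, config$threshold),
      stringsAsFactors = FALSE
    )
    utils::write.csv(tab, file.path(out_dir, "worked_example.csv"),
                     row.names = FALSE)
    artifacts$report <- file.path(out_dir, "worked_example.csv")
    artifacts$table <- tab
  }
  invisible(artifacts)
}

load_cohort <- function(config) {
  if (is.null(config$input)) {
    generate_cohort(config$generator)
  } else {
    read_cohort_csv(config$input)
  }
}
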