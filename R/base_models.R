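#' Specification of one base classifier
#'
#' The four base learners are gradient-boosting variants. Defaults follow the
#' published configuration: 200 estimators, learning rate 0.05, max depth
#' 6/6/5 for the lightgbm/xgboost/gbm kinds, L1 = L2 = 0.1 for the histogram
#' boosters, subsample 0.8 for the gbm kind, seed 42 everywhere. The
#' `lightgbm`, `xgboost`, and `gbm` kinds are fitted with the xgboost
#' library (the lightgbm kind uses its histogram binning with leaf-wise
#' `lossguide` growth); `adaboost` is SAMME boosting of depth-1 decision
#' stumps, whose base-learner depth (1) is logged in the fitted handle.
#'
#' @param kind one of `"lightgbm"`, `"xgboost"`, `"gbm"`, `"adaboost"`.
#' @param n_estimators number of boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth tree depth; `NA` for adaboost (stumps).
#' @param regularization named list of penalty terms (`l1`, `l2`,
#'   `subsample`).
#' @param seed integer seed.
#' @return object of class `base_model_spec`.
#' @export
base_model_spec <- function(kind = c("lightgbm", "xgboost", "gbm", "adaboost"),
                            n_estimators = 200L, learning_rate = 0.05,
                            max_depth = NULL, regularization = NULL,
                            seed = 42L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    lightgbm = list(max_depth = 6L, regularization = list(l1 = 0.1, l2 = 0.1)),
    xgboost  = list(max_depth = 6L, regularization = list(l1 = 0.1, l2 = 0.1)),
    gbm      = list(max_depth = 5L, regularization = list(subsample = 0.8)),
    adaboost = list(max_depth = NA_integer_, regularization = list())
  )
  if (is.null(max_depth)) max_depth <- defaults$max_depth
  if (is.null(regularization)) regularization <- defaults$regularization
  stopifnot(n_estimators >= 1L, learning_rate > 0)
  structure(list(kind = kind, n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate, max_depth = max_depth,
                 regularization = regularization, seed = as.integer(seed)),
            class = "base_model_spec")
}

#' Default four-model ensemble specification
#'
#' @param seed shared random seed (default 42).
#' @return named list of four [base_model_spec()] objects in the order
#'   lightgbm, xgboost, gbm, adaboost.
#' @export
default_base_specs <- function(seed = 42L) {
  kinds <- c("lightgbm", "xgboost", "gbm", "adaboost")
  stats::setNames(lapply(kinds, base_model_spec, seed = seed), kinds)
}

#' Train the four base classifiers
#'
#' Fits each base learner on the (already preprocessed) cohort. Training is
#' deterministic given the spec seeds (single-threaded boosting).
#'
#' @param cohort a [cohort_table()] whose features are scaled to `[0, 1]`.
#' @param specs named list of exactly four [base_model_spec()]s covering the
#'   kinds lightgbm, xgboost, gbm, adaboost.
#' @return object of class `mmfde_ensemble` exposing [predict_confidences()].
#' @export
train_base_models <- function(cohort, specs = default_base_specs()) {
  stopifnot(inherits(cohort, "cohort_table"))
  kinds <- vapply(specs, function(s) s$kind, character(1L))
  required <- c("lightgbm", "xgboost", "gbm", "adaboost")
  if (length(specs) != 4L || !setequal(kinds, required)) {
    stop("specs must contain exactly the four base-model kinds: ",
         paste(setdiff(required, kinds), collapse = ", "), " missing")
  }
  specs <- specs[match(required, kinds)]
  y <- cohort$outcome
  if (length(unique(y)) < 2L) {
    stop("single-class training data: stratification failed")
  }
  x <- as.matrix(cohort$features)
  models <- lapply(specs, function(s) fit_base_model(s, x, y))
  structure(list(models = models, specs = specs,
                 feature_names = colnames(x)),
            class = "mmfde_ensemble")
}

#' @export
print.mmfde_ensemble <- function(x, ...) {
  cat("mmfde_ensemble of", length(x$models), "base models:",
      paste(names(x$models), collapse = ", "), "\n")
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

fit_base_model <- function(spec, x, y) {
  if (spec$kind == "adaboost") {
    return(fit_adaboost_stumps(x, y, n_rounds = spec$n_estimators,
                               learning_rate = spec$learning_rate,
                               seed = spec$seed))
  }
  reg <- spec$regularization
  params <- list(
    objective = "binary:logistic",
    eta = spec$learning_rate,
    max_depth = spec$max_depth,
    alpha = if (!is.null(reg$l1)) reg$l1 else 0,
    lambda = if (!is.null(reg$l2)) reg$l2 else 1,
    subsample = if (!is.null(reg$subsample)) reg$subsample else 1,
    nthread = 1L,
    seed = spec$seed
  )
  if (spec$kind == "lightgbm") {
    params$tree_method <- "hist"
    params$grow_policy <- "lossguide"
    params$max_leaves <- 2L^spec$max_depth - 1L
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  with_seed(spec$seed,
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = spec$n_estimators, verbose = 0))
}

# SAMME AdaBoost on depth-1 rpart stumps; probability = weighted vote share
fit_adaboost_stumps <- function(x, y, n_rounds = 200L, learning_rate = 0.05,
                                seed = 42L) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0L, 1L))
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  mean_preds <- numeric(n_rounds)  # training-background vote share per stump
  ctrl <- rpart::rpart.control(maxdepth = 1L, cp = 0, minsplit = 2L,
                               minbucket = 1L, xval = 0L, maxcompete = 0L,
                               maxsurrogate = 0L)
  t_used <- 0L
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    mis <- pred != y
    err <- sum(w[mis]) / sum(w)
    if (err >= 0.5 && t > 1L) break
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    trees[[t]] <- fit
    alphas[t] <- alpha
    mean_preds[t] <- mean(pred)
    t_used <- t
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  structure(list(trees = trees[seq_len(t_used)], alphas = alphas[seq_len(t_used)],
                 mean_preds = mean_preds[seq_len(t_used)],
                 base_learner_depth = 1L, n_rounds = t_used),
            class = "adaboost_stumps")
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  a <- model$alphas
  votes <- vapply(model$trees, function(tr) {
    as.integer(as.character(predict(tr, df, type = "class")))
  }, integer(nrow(df)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(df))
  as.numeric(votes %*% a) / sum(a)
}

#' Positive-class confidence matrix from a fitted ensemble
#'
#' @param ensemble an `mmfde_ensemble` from [train_base_models()].
#' @param features data.frame or matrix with the training feature schema
#'   (same columns, already preprocessed).
#' @return a [confidence_matrix()] (samples x 4 models).
#' @export
predict_confidences <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "mmfde_ensemble"))
  x <- as.matrix(as.data.frame(features))
  if (!identical(colnames(x), ensemble$feature_names)) {
    missing_cols <- setdiff(ensemble$feature_names, colnames(x))
    if (length(missing_cols) > 0L) {
      stop(sprintf("feature columns do not match training schema; missing: %s",
                   paste(missing_cols, collapse = ", ")))
    }
    x <- x[, ensemble$feature_names, drop = FALSE]
  }
  probs <- vapply(ensemble$models, function(m) {
    if (inherits(m, "adaboost_stumps")) predict_adaboost(m, x)
    else predict(m, xgboost::xgb.DMatrix(x))
  }, numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(x))
  colnames(probs) <- names(ensemble$models)
  confidence_matrix(pmin(pmax(probs, 0), 1))
}

#' Per-fold out-of-fold confidences with leakage-safe preprocessing
#'
#' For each cross-validation fold, preprocessing (zero imputation and min-max
#' scaling) is fitted on the training part only, the four base models are
#' trained on that part, and confidences are predicted for the held-out part.
#' This is the input to the fusion-weight and beta searches.
#'
#' @param cohort a raw [cohort_table()].
#' @param specs base model specs (see [default_base_specs()]).
#' @param plan a [split_plan()]; its `n_folds` and `seed` drive the folds.
#' @param impute_zeros passed to [preprocess_cohort()].
#' @return list of class `mmfde_cv` with elements `folds` (fold id per
#'   subject) and `per_fold`, a list of `(val_idx, confidences, labels)`.
#' @export
cv_confidences <- function(cohort, specs = default_base_specs(),
                           plan = split_plan(), impute_zeros = TRUE) {
  folds <- stratified_folds(cohort$outcome, plan$n_folds, plan$seed)
  per_fold <- lapply(seq_len(plan$n_folds), function(k) {
    tr <- which(folds != k)
    va <- which(folds == k)
    pp <- preprocess_cohort(cohort, fit_on = tr, impute_zeros = impute_zeros)
    train_cohort <- cohort_table(pp$features[tr, , drop = FALSE],
                                 pp$outcome[tr], check_ranges = FALSE)
    ens <- train_base_models(train_cohort, specs)
    list(val_idx = va,
         confidences = predict_confidences(ens, pp$features[va, , drop = FALSE]),
         labels = cohort$outcome[va])
  })
  structure(list(folds = folds, per_fold = per_fold), class = "mmfde_cv")
}
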