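#' Clinical attribute schema and reference ranges
#'
#' The eight-attribute clinical schema shared by the Frankfurt hospital
#' (HFGDD) and Pima (PIDD) diabetes cohorts, with the published value ranges.
#' Five attributes (glucose, blood pressure, skin thickness, insulin, BMI)
#' may carry physiologically impossible zero codes in PIDD-style data; these
#' are the columns eligible for zero-as-missing imputation.
#'
#' @return data.frame with columns `attribute`, `min`, `max`, `zero_coded`.
#' @export
clinical_schema <- function() {
  data.frame(
    attribute = c("Pregnancies", "Glucose", "BloodPressure", "SkinThickness",
                  "Insulin", "BMI", "DPF", "Age"),
    min = c(0, 0, 0, 0, 0, 0, 0.078, 1),
    max = c(17, 199, 122, 99, 846, 80.6, 2.42, 120),
    zero_coded = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Cohort table: clinical features plus binary outcome
#'
#' @param features numeric data.frame of clinical attributes (one row per
#'   subject).
#' @param outcome binary vector (0 = non-diabetic, 1 = diabetic) of length
#'   `nrow(features)`.
#' @param check_ranges warn when attribute values fall outside the published
#'   reference ranges for columns named in [clinical_schema()].
#' @return object of class `cohort_table`: list with `features` (data.frame)
#'   and `outcome` (integer vector).
#' @export
cohort_table <- function(features, outcome, check_ranges = TRUE) {
  features <- as.data.frame(features)
  if (nrow(features) == 0L) stop("empty cohort")
  not_num <- names(features)[!vapply(features, is.numeric, logical(1L))]
  if (length(not_num) > 0L) {
    stop(sprintf("non-numeric feature column: %s", not_num[1L]))
  }
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(features)) stop("outcome length must match feature rows")
  if (any(is.na(outcome)) || !all(outcome %in% c(0L, 1L))) {
    stop("outcome must be binary 0/1")
  }
  if (check_ranges) {
    sch <- clinical_schema()
    for (k in seq_len(nrow(sch))) {
      a <- sch$attribute[k]
      if (a %in% names(features)) {
        v <- features[[a]]
        if (any(v < sch$min[k] - 1e-9 | v > sch$max[k] + 1e-9, na.rm = TRUE)) {
          warning(sprintf("%s has values outside the reference range [%g, %g]",
                          a, sch$min[k], sch$max[k]))
        }
      }
    }
  }
  structure(list(features = features, outcome = outcome),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects, %d attributes, prevalence %.1f%%\n",
              nrow(x$features), ncol(x$features), 100 * mean(x$outcome)))
  cat("attributes:", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Expects a header with the clinical attribute names plus an `Outcome`
#' column.
#'
#' @param path CSV file path.
#' @param outcome_col name of the binary outcome column.
#' @inheritParams cohort_table
#' @return a [cohort_table()].
#' @export
read_cohort_csv <- function(path, outcome_col = "Outcome", check_ranges = TRUE) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome_col %in% names(df)) {
    stop(sprintf("outcome column '%s' not found in %s", outcome_col, path))
  }
  cohort_table(df[setdiff(names(df), outcome_col)], df[[outcome_col]],
               check_ranges = check_ranges)
}

#' Write a cohort to CSV
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cbind(cohort$features, Outcome = cohort$outcome)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Leakage-safe preprocessing: zero imputation and min-max scaling
#'
#' Treats zero codes in the PIDD-affected columns as missing and replaces
#' them with the median of the non-zero values among the fitting rows, then
#' min-max scales every column using parameters computed on the fitting rows
#' only. Rows outside the fitting range map outside `[0, 1]` and are *not*
#' clipped, preserving the affine map. A constant column maps to 0 with a
#' warning.
#'
#' @param cohort a [cohort_table()].
#' @param fit_on integer indices of the rows used to fit imputation medians
#'   and scaling parameters (typically the training part of a fold). Defaults
#'   to all rows.
#' @param impute_zeros logical; `FALSE` for cohorts known to have no zero
#'   codes (HFGDD-style), skipping imputation.
#' @param zero_cols columns subject to zero-as-missing handling; defaults to
#'   the zero-coded columns of [clinical_schema()] present in the data.
#' @return a `cohort_table` with transformed features; the fitted parameters
#'   are attached as attribute `"preprocess_params"`.
#' @export
preprocess_cohort <- function(cohort, fit_on = seq_len(nrow(cohort$features)),
                              impute_zeros = TRUE, zero_cols = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(fit_on) == 0L) stop("fit_on index set must be non-empty")
  feats <- cohort$features
  if (is.null(zero_cols)) {
    sch <- clinical_schema()
    zero_cols <- intersect(sch$attribute[sch$zero_coded], names(feats))
  }
  params <- list(impute_zeros = impute_zeros, zero_cols = zero_cols,
                 medians = numeric(0), mins = numeric(0), maxs = numeric(0))

  if (impute_zeros) {
    for (col in zero_cols) {
      fit_vals <- feats[[col]][fit_on]
      med <- stats::median(fit_vals[fit_vals != 0])
      if (is.na(med)) med <- 0  # all-zero fitting column: nothing to impute from
      params$medians[col] <- med
      feats[[col]][feats[[col]] == 0] <- med
    }
  }

  for (col in names(feats)) {
    lo <- min(feats[[col]][fit_on])
    hi <- max(feats[[col]][fit_on])
    params$mins[col] <- lo
    params$maxs[col] <- hi
    if (hi == lo) {
      warning(sprintf("constant column '%s' in fitting rows; mapped to 0", col))
      feats[[col]] <- rep(0, nrow(feats))
    } else {
      feats[[col]] <- (feats[[col]] - lo) / (hi - lo)
    }
  }

  out <- cohort_table(feats, cohort$outcome, check_ranges = FALSE)
  attr(out, "preprocess_params") <- params
  out
}

#' Apply previously fitted preprocessing parameters to new features
#'
#' @param features data.frame with the training schema.
#' @param params the `"preprocess_params"` attribute of a preprocessed cohort.
#' @return transformed data.frame.
#' @export
apply_preprocess <- function(features, params) {
  features <- as.data.frame(features)
  if (isTRUE(params$impute_zeros)) {
    for (col in intersect(params$zero_cols, names(features))) {
      features[[col]][features[[col]] == 0] <- params$medians[[col]]
    }
  }
  for (col in names(params$mins)) {
    if (!col %in% names(features)) stop(sprintf("missing column '%s'", col))
    lo <- params$mins[[col]]
    hi <- params$maxs[[col]]
    features[[col]] <- if (hi == lo) rep(0, nrow(features))
                       else (features[[col]] - lo) / (hi - lo)
  }
  features
}

#' Cross-validation / holdout split plan
#'
#' @param train_fraction fraction of subjects in the training partition
#'   (default 0.8; the remainder is the held-out test set).
#' @param n_folds number of stratified cross-validation folds within the
#'   training partition (default 5).
#' @param stratified preserve class proportions in folds and split.
#' @param seed integer seed governing the split.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(train_fraction = 0.8, n_folds = 5L, stratified = TRUE,
                       seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction <= 1, n_folds >= 2L)
  structure(list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of `n_folds` folds, preserving the class
#' proportions within plus/minus one subject per class.
#'
#' @param outcome binary 0/1 vector.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(outcome, n_folds = 5L, seed = 42L) {
  outcome <- as.integer(outcome)
  folds <- integer(length(outcome))
  with_seed(seed, {
    for (cl in sort(unique(outcome))) {
      idx <- which(outcome == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Stratified train/test split
#'
#' @param cohort a [cohort_table()].
#' @param plan a [split_plan()].
#' @return list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(cohort, plan = split_plan()) {
  y <- cohort$outcome
  train <- integer(0)
  with_seed(plan$seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_tr <- round(plan$train_fraction * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
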