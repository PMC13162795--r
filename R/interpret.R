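#' Additive feature attributions for ensemble predictions
#'
#' Two modes. `per_model_mean` (fast, exact): tree-path Shapley values for
#' the positive class are computed per base model — xgboost's exact TreeSHAP
#' for the boosted-tree models (on the log-odds scale) and a closed form for
#' the AdaBoost stumps (a depth-1 tree's whole deviation from its background
#' mean belongs to its split feature) — then averaged with equal weight.
#' `fused_model_agnostic` (faithful, sampling-based): permutation-sampling
#' Shapley values of the end-to-end fuzzy score; per permutation the
#' marginal contributions telescope, so additivity is exact up to Monte
#' Carlo averaging over permutations (which preserves it).
#'
#' In both modes, per sample,
#' `base_value + sum(attributions) = explained_output` holds to numerical
#' precision.
#'
#' @param ensemble an `mmfde_ensemble` from [train_base_models()].
#' @param features preprocessed feature data.frame (training schema).
#' @param mode `"per_model_mean"` or `"fused_model_agnostic"`.
#' @param weights,beta,normalize fusion parameters (used by the fused mode).
#' @param background background rows for the fused mode (defaults to
#'   `features`); a subsample keeps the sampling cheap.
#' @param nsim permutations per sample in the fused mode.
#' @param seed sampling seed for the fused mode.
#' @return object of class `attribution_table`: list with `values`
#'   (samples x features matrix), `base_value` (per sample),
#'   `explained_output`, `feature_names`, `mode`.
#' @export
explain_predictions <- function(ensemble, features,
                                mode = c("per_model_mean", "fused_model_agnostic"),
                                weights = distance_weights(), beta = 2.0,
                                normalize = TRUE, background = NULL,
                                nsim = 32L, seed = 1L) {
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("per_model_mean", "fused_model_agnostic")) {
    stop(sprintf("unknown attribution mode '%s'", mode))
  }
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "mmfde_ensemble"))
  x <- as.matrix(as.data.frame(features))[, ensemble$feature_names, drop = FALSE]
  if (mode == "per_model_mean") {
    shap_per_model_mean(ensemble, x)
  } else {
    if (is.null(background)) background <- x
    background <- as.matrix(as.data.frame(background))[, ensemble$feature_names,
                                                       drop = FALSE]
    shap_fused_sampling(ensemble, x, background, weights, beta, normalize,
                        nsim, seed)
  }
}

shap_per_model_mean <- function(ensemble, x) {
  p <- ncol(x)
  n <- nrow(x)
  vals <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  base <- numeric(n)
  out <- numeric(n)
  for (m in ensemble$models) {
    if (inherits(m, "adaboost_stumps")) {
      sh <- stump_shap(m, x)
    } else {
      contrib <- predict(m, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
      sh <- list(values = contrib[, seq_len(p), drop = FALSE],
                 base_value = contrib[, p + 1L],
                 output = rowSums(contrib))
    }
    vals <- vals + sh$values
    base <- base + sh$base_value
    out <- out + sh$output
  }
  k <- length(ensemble$models)
  structure(list(values = vals / k, base_value = base / k,
                 explained_output = out / k,
                 feature_names = colnames(x), mode = "per_model_mean"),
            class = "attribution_table")
}

# exact Shapley values for a weighted sum of depth-1 stumps: each stump's
# deviation from its mean over the training background is attributed wholly
# to its single split feature
stump_shap <- function(model, x) {
  df <- as.data.frame(x)
  p <- ncol(x)
  n <- nrow(x)
  a <- model$alphas / sum(model$alphas)
  vals <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  base <- 0
  for (t in seq_along(model$trees)) {
    tr <- model$trees[[t]]
    pred <- as.integer(as.character(predict(tr, df, type = "class")))
    split_var <- if (nrow(tr$frame) > 1L) {
      as.character(tr$frame$var[1L])
    } else NA_character_  # degenerate stump with no split
    mean_pred <- model$mean_preds[t]  # training-background vote share
    contrib <- a[t] * (pred - mean_pred)
    base <- base + a[t] * mean_pred
    if (!is.na(split_var) && split_var %in% colnames(vals)) {
      vals[, split_var] <- vals[, split_var] + contrib
    }
  }
  output <- base + rowSums(vals)
  list(values = vals, base_value = rep(base, n), output = output)
}

shap_fused_sampling <- function(ensemble, x, background, weights, beta,
                                normalize, nsim, seed) {
  p <- ncol(x)
  n <- nrow(x)
  fuse_score <- function(z) {
    conf <- predict_confidences(ensemble, as.data.frame(z))
    fuse_confidences(conf, weights, beta = beta, normalize = normalize)$fuzzy_score
  }
  vals <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  base <- numeric(n)
  with_seed(seed, {
    perms <- replicate(nsim, sample.int(p), simplify = FALSE)
    bg_idx <- sample.int(nrow(background), nsim, replace = TRUE)
    for (s in seq_len(nsim)) {
      perm <- perms[[s]]
      bg <- background[bg_idx[s], , drop = FALSE]
      # rows: for each sample, the chain bg -> ... -> x along the permutation
      chain <- matrix(rep(bg, each = n * (p + 1L)), n * (p + 1L), p,
                      dimnames = list(NULL, colnames(x)))
      for (step in seq_len(p)) {
        filled <- perm[seq_len(step)]
        rows <- (step * n + 1L):((step + 1L) * n)
        chain[rows, filled] <- x[, filled, drop = FALSE]
      }
      g <- fuse_score(chain)
      gm <- matrix(g, n, p + 1L)   # column step+1 = after filling 'step' features
      for (step in seq_len(p)) {
        vals[, perm[step]] <- vals[, perm[step]] + (gm[, step + 1L] - gm[, step])
      }
      base <- base + gm[, 1L]
    }
  })
  vals <- vals / nsim
  base <- base / nsim
  structure(list(values = vals, base_value = base,
                 explained_output = base + rowSums(vals),
                 feature_names = colnames(x), mode = "fused_model_agnostic"),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("attribution_table (%s): %d samples x %d features\n",
              x$mode, nrow(x$values), ncol(x$values)))
  print(utils::head(global_importance(x)))
  invisible(x)
}

#' Global feature importance from attributions
#'
#' Mean absolute attribution per feature, sorted descending; ties break
#' alphabetically.
#'
#' @param table an `attribution_table` from [explain_predictions()].
#' @return data.frame with columns `feature`, `importance`, in rank order.
#' @export
global_importance <- function(table) {
  stopifnot(inherits(table, "attribution_table"))
  imp <- colMeans(abs(table$values))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Cross-fold rank stability of feature importance (Kendall's tau)
#'
#' For every pair of folds, takes the union of the two top-`k` feature sets,
#' locates those features by their positions in each *full* ranking (so a
#' feature outside one fold's top-k still has a well-defined rank), computes
#' Kendall's tau on the two position vectors, and averages over all pairs.
#'
#' @param per_fold_rankings list (length >= 2) of character vectors: each a
#'   full feature ranking, most important first, over the same feature set.
#' @param k size of the top set compared (default 5; clamped to the feature
#'   count with a warning).
#' @return mean Kendall's tau over all fold pairs.
#' @export
rank_stability <- function(per_fold_rankings, k = 5L) {
  stopifnot(length(per_fold_rankings) >= 2L)
  universe <- sort(per_fold_rankings[[1L]])
  for (r in per_fold_rankings) {
    if (!setequal(r, universe)) stop("all rankings must cover the same features")
  }
  if (k > length(universe)) {
    warning(sprintf("k = %d exceeds the %d features; clamped", k, length(universe)))
    k <- length(universe)
  }
  pairs <- utils::combn(length(per_fold_rankings), 2L)
  taus <- apply(pairs, 2L, function(ij) {
    r1 <- per_fold_rankings[[ij[1L]]]
    r2 <- per_fold_rankings[[ij[2L]]]
    top <- union(r1[seq_len(k)], r2[seq_len(k)])
    stats::cor(match(top, r1), match(top, r2), method = "kendall")
  })
  mean(taus)
}

#' Concordance between geometric decisions and feature attributions
#'
#' Per sample, the dominant feature is the one with the largest absolute
#' attribution; its sign implies an expected class (positive attribution
#' pushes toward the positive/diabetic class). A sample is concordant when
#' that expected class matches the distance-based fused label. Reports the
#' concordance/discordance percentages, the share of discordant cases that
#' carry only moderate confidence (`mu_max <= 0.7`), and the
#' misclassification rate within each stratum. Samples whose attributions
#' are identically zero are excluded (count reported).
#'
#' @param table an `attribution_table` aligned with `results`.
#' @param results an `mmfde_fusion` data.frame.
#' @param labels true binary labels.
#' @return object of class `concordance_report`.
#' @export
concordance_analysis <- function(table, results, labels) {
  stopifnot(inherits(table, "attribution_table"),
            nrow(table$values) == nrow(results),
            length(labels) == nrow(results))
  labels <- as.integer(labels)
  vals <- table$values
  feats <- colnames(vals)
  all_zero <- rowSums(abs(vals)) == 0
  keep <- which(!all_zero)
  if (length(keep) == 0L) stop("all attribution rows are zero")

  dominant <- vapply(keep, function(i) {
    v <- abs(vals[i, ])
    # tie-break: larger magnitude at full precision, then alphabetical
    ord <- order(-v, feats)
    ord[1L]
  }, integer(1L))
  dom_sign <- vals[cbind(keep, dominant)]
  expected <- as.integer(dom_sign > 0)
  fused_label <- results$label[keep]
  concordant <- expected == fused_label
  mu_max <- pmax(results$mu_pos, results$mu_neg)[keep]
  correct <- fused_label == labels[keep]

  n <- length(keep)
  n_disc <- sum(!concordant)
  report <- list(
    n = n,
    n_excluded_zero = sum(all_zero),
    concordance_pct = 100 * mean(concordant),
    discordance_pct = 100 * mean(!concordant),
    pct_discordant_with_moderate_confidence =
      if (n_disc > 0L) 100 * mean(mu_max[!concordant] <= 0.7) else NA_real_,
    misclassification_rate_concordant =
      if (any(concordant)) 100 * mean(!correct[concordant]) else NA_real_,
    misclassification_rate_discordant =
      if (n_disc > 0L) 100 * mean(!correct[!concordant]) else NA_real_,
    dominant_feature = feats[dominant],
    concordant = concordant
  )
  class(report) <- "concordance_report"
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report (n=%d, %d zero-attribution rows excluded)\n",
              x$n, x$n_excluded_zero))
  cat(sprintf("  concordance %.1f%% / discordance %.1f%%\n",
              x$concordance_pct, x$discordance_pct))
  cat(sprintf("  discordant with moderate confidence: %s%%\n",
              format(round(x$pct_discordant_with_moderate_confidence, 1))))
  cat(sprintf("  misclassification: concordant %s%%, discordant %s%%\n",
              format(round(x$misclassification_rate_concordant, 1)),
              format(round(x$misclassification_rate_discordant, 1))))
  invisible(x)
}
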