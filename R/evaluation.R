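#' Confusion counts from predicted and true labels
#'
#' @param pred,truth binary 0/1 vectors of equal length.
#' @return object of class `confusion_counts`: named integer
#'   `(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  stopifnot(length(pred) == length(truth))
  structure(c(tp = sum(pred == 1L & truth == 1L),
              tn = sum(pred == 0L & truth == 0L),
              fp = sum(pred == 1L & truth == 0L),
              fn = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Threshold classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, positive-class precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, and F1 `2TP/(2TP+FP+FN)`. A zero denominator for
#' precision or recall yields `NA` (an explicit undefined marker, logged via
#' `message()`) rather than a silent 0.
#'
#' @param counts a [confusion_counts()] object, or a binary prediction
#'   vector (then `truth` must be given).
#' @param truth optional true labels when `counts` is a prediction vector.
#' @return list of class `metric_report` with `accuracy`, `precision`,
#'   `recall`, `f1`, `n`.
#' @examples
#' classification_metrics(confusion_counts(c(1,1,1,1,0,0,0,0,0,0),
#'                                         c(1,1,1,0,1,1,0,0,0,0)))
#' @export
classification_metrics <- function(counts, truth = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts, truth)
  }
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  n <- tp + tn + fp + fn
  if (n == 0L) stop("no evaluated samples")
  precision <- if (tp + fp == 0L) {
    message("precision undefined: no positive predictions")
    NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) {
    message("recall undefined: no positive cases")
    NA_real_
  } else tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn == 0L) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1, n = n, counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (n=%d): accuracy %.4f, precision %s, recall %s, f1 %s\n",
    x$n, x$accuracy, format(round(x$precision, 4)),
    format(round(x$recall, 4)), format(round(x$f1, 4))))
  if (!is.null(x$auc)) cat(sprintf("  auc %.4f, pr_auc %.4f\n", x$auc, x$pr_auc))
  invisible(x)
}

#' Ranking metrics: ROC AUC and PR AUC
#'
#' AUC is the Mann-Whitney rank statistic (ties averaged): the probability
#' that a random positive outscores a random negative. PR-AUC uses step-wise
#' integration of the precision-recall curve over descending score
#' thresholds (no interpolation); the convention is recorded in the result.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return list with `auc`, `pr_auc`, and `pr_convention`.
#' @export
ranking_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # evaluate at distinct thresholds
  tp <- cum_tp[keep]
  fp <- cum_fp[keep]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)

  list(auc = auc, pr_auc = pr_auc, pr_convention = "stepwise")
}

#' Dietterich's 5x2cv paired t-test between two classifier builders
#'
#' Five replications of stratified two-fold cross-validation; in each, both
#' builders are trained on one half and evaluated on the other, in both
#' directions. The statistic is the first replication's first-fold accuracy
#' difference divided by the root mean of the per-replication variances,
#' referred to a t distribution with 5 degrees of freedom (two-sided).
#'
#' @param cohort a raw [cohort_table()].
#' @param builder_a,builder_b functions
#'   `(cohort, train_idx, test_idx) -> binary predictions for test_idx`.
#' @param seed integer seed for the five stratified splits.
#' @return list with `statistic`, `p_value`, `df`, `differences` (5 x 2
#'   accuracy differences), and `degenerate` (all-zero variance flag).
#' @export
five_by_two_cv_ttest <- function(cohort, builder_a, builder_b, seed = 42L) {
  y <- cohort$outcome
  diffs <- matrix(NA_real_, 5L, 2L)
  for (rep_i in 1:5) {
    halves <- stratified_folds(y, n_folds = 2L, seed = seed + rep_i)
    for (k in 1:2) {
      tr <- which(halves == k)
      te <- which(halves != k)
      acc_a <- mean(builder_a(cohort, tr, te) == y[te])
      acc_b <- mean(builder_b(cohort, tr, te) == y[te])
      diffs[rep_i, k] <- acc_a - acc_b
    }
  }
  vars <- apply(diffs, 1L, function(d) (d[1] - mean(d))^2 + (d[2] - mean(d))^2)
  denom <- sqrt(mean(vars))
  if (denom == 0) {
    return(list(statistic = 0, p_value = 1, df = 5L, differences = diffs,
                degenerate = TRUE))
  }
  t_stat <- diffs[1L, 1L] / denom
  list(statistic = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = 5L),
       df = 5L, differences = diffs, degenerate = FALSE)
}

#' McNemar comparison of two prediction vectors
#'
#' Continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)` on the
#' discordant counts (correction floored at 0 when `|b - c| < 1`). The
#' p-value uses the exact two-sided binomial when `b + c < 25`, otherwise
#' the chi-square reference with 1 degree of freedom.
#'
#' @param preds_a,preds_b binary predictions from the two classifiers.
#' @param labels true binary labels.
#' @return list with `statistic`, `p_value`, `b`, `c`, `method`, and
#'   `degenerate` flag (`b + c = 0`).
#' @examples
#' # b = 10, c = 2 gives the corrected statistic 49/12 = 4.0833
#' @export
mcnemar_compare <- function(preds_a, preds_b, labels) {
  preds_a <- as.integer(preds_a)
  preds_b <- as.integer(preds_b)
  labels <- as.integer(labels)
  stopifnot(length(preds_a) == length(labels), length(preds_b) == length(labels))
  ok_a <- preds_a == labels
  ok_b <- preds_b == labels
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0L) {
    return(list(statistic = NA_real_, p_value = 1, b = b, c = cc,
                method = "none", degenerate = TRUE))
  }
  stat <- max(abs(b - cc) - 1, 0)^2 / (b + cc)
  if (b + cc < 25L) {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
    method <- "exact-binomial"
  } else {
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = stat, p_value = p, b = b, c = cc, method = method,
       degenerate = FALSE)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param k number of comparisons, k >= 1.
#' @return `alpha / k`.
#' @examples
#' bonferroni_threshold(0.05, 8)  # 0.00625
#' @export
bonferroni_threshold <- function(alpha = 0.05, k = 1L) {
  stopifnot(alpha > 0, alpha < 1, k >= 1L)
  alpha / k
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples `(scores, labels)` pairs with replacement `B` times and returns
#' the percentile interval of the metric. Deterministic given `seed`. When
#' the metric needs both classes (set `needs_both_classes = TRUE`, e.g. for
#' AUC), single-class resamples are redrawn (at most 100 retries each).
#'
#' @param metric_fn function `(scores, labels) -> scalar`.
#' @param scores,labels paired observations.
#' @param B number of bootstrap resamples (default 1000).
#' @param level interval coverage (default 0.95).
#' @param seed integer seed.
#' @param needs_both_classes redraw resamples lacking a class.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 1000L, level = 0.95,
                         seed = 42L, needs_both_classes = FALSE) {
  n <- length(scores)
  stopifnot(n >= 2L, length(labels) == n)
  stats_b <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      tries <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (!needs_both_classes || length(unique(labels[idx])) > 1L) break
        tries <- tries + 1L
        if (tries >= 100L) stop("could not draw a two-class bootstrap resample")
      }
      stats_b[b] <- metric_fn(scores[idx], labels[idx])
    }
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1L], hi = q[2L])
}

#' Reliability binning, expected calibration error, and triage distribution
#'
#' Bins the winning membership `mu_max` (or, optionally, the winning side of
#' the fuzzy score) into `n_bins` equal-width bins over (0, 1], compares the
#' mean predicted confidence with the observed accuracy per bin, and reports
#' `ECE = sum_b (n_b / n) * |acc_b - conf_b|` (empty bins carry zero
#' weight). Also reports the fraction of predictions in each triage
#' confidence level.
#'
#' @param results an `mmfde_fusion` data.frame from [fuse_confidences()].
#' @param labels true binary labels.
#' @param n_bins number of equal-width bins (default 10).
#' @param axis confidence axis: `"mu_max"` (the quantity the triage
#'   thresholds act on; default) or `"fuzzy_score"` (winning-side score).
#' @return object of class `calibration_report`: list with `bins`
#'   (data.frame), `ece`, `level_distribution`, `n_bins`, `axis`.
#' @export
calibration_report <- function(results, labels, n_bins = 10L,
                               axis = c("mu_max", "fuzzy_score")) {
  axis <- match.arg(axis)
  labels <- as.integer(labels)
  stopifnot(nrow(results) > 0L, length(labels) == nrow(results))
  conf <- switch(axis,
    mu_max = pmax(results$mu_pos, results$mu_neg),
    fuzzy_score = pmax(results$fuzzy_score, 1 - results$fuzzy_score))
  correct <- as.integer(results$label == labels)
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bins <- data.frame(
    bin = seq_len(n_bins),
    lower = edges[-length(edges)],
    upper = edges[-1L],
    n = as.integer(tabulate(bin, n_bins)),
    mean_confidence = NA_real_,
    accuracy = NA_real_
  )
  for (k in seq_len(n_bins)) {
    in_bin <- bin == k
    if (any(in_bin)) {
      bins$mean_confidence[k] <- mean(conf[in_bin])
      bins$accuracy[k] <- mean(correct[in_bin])
    }
  }
  occupied <- bins$n > 0L
  ece <- sum(bins$n[occupied] / length(conf) *
             abs(bins$accuracy[occupied] - bins$mean_confidence[occupied]))
  lev <- table(results$confidence_level) / nrow(results)
  structure(list(bins = bins, ece = ece,
                 level_distribution = lev, n_bins = n_bins, axis = axis),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report: ECE %.4f (%d bins on %s)\n",
              x$ece, x$n_bins, x$axis))
  cat("triage distribution:",
      paste(sprintf("%s %.1f%%", names(x$level_distribution),
                    100 * as.numeric(x$level_distribution)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Leave-one-metric-out ablation of the hybrid distance
#'
#' Drops one distance metric, redistributes its weight proportionally among
#' the remaining three, re-runs the fusion on the same confidences, and
#' reports the metrics alongside the change from the full configuration.
#'
#' @param cmat a [confidence_matrix()] for the evaluation samples.
#' @param labels true binary labels.
#' @param weights full-configuration [distance_weights()].
#' @param beta membership decay rate.
#' @param drop metric to remove: `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   or `"chebyshev"`.
#' @param normalize metric normalization switch.
#' @return list with `drop`, `weights` (renormalized), `metrics`
#'   ([classification_metrics()] plus AUC), `full_metrics`, and
#'   `delta_accuracy`.
#' @export
ablation_study <- function(cmat, labels, weights = distance_weights(),
                           beta = 2.0,
                           drop = c("euclidean", "manhattan", "cosine", "chebyshev"),
                           normalize = TRUE) {
  drop <- match.arg(drop)
  weights <- as_distance_weights(weights)
  slot <- c(euclidean = "w_e", manhattan = "w_m",
            cosine = "w_c", chebyshev = "w_ch")[[drop]]
  w <- unclass(weights)
  if (w[[slot]] >= 1 - 1e-12) {
    stop(sprintf("cannot drop '%s': it carries all the weight", drop))
  }
  w_new <- w
  w_new[[slot]] <- 0
  w_new <- w_new / sum(w_new)   # proportional redistribution
  reduced <- distance_weights(w_new[["w_e"]], w_new[["w_m"]],
                              w_new[["w_c"]], w_new[["w_ch"]])

  eval_config <- function(wt) {
    res <- fuse_confidences(cmat, wt, beta = beta, normalize = normalize)
    mr <- classification_metrics(confusion_counts(res$label, labels))
    if (length(unique(labels)) > 1L) {
      rk <- ranking_metrics(res$fuzzy_score, labels)
      mr$auc <- rk$auc
      mr$pr_auc <- rk$pr_auc
    }
    mr
  }
  full <- eval_config(weights)
  abl <- eval_config(reduced)
  list(drop = drop, weights = reduced, metrics = abl, full_metrics = full,
       delta_accuracy = abl$accuracy - full$accuracy)
}
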