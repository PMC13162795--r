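test_that("classification metrics follow the confusion-count formulas", {
  m <- classification_metrics(structure(c(tp = 3L, tn = 4L, fp = 1L, fn = 2L),
                                        class = "confusion_counts"))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 3 / (2 * 3 + 1 + 2), tolerance = 1e-9)
  perfect <- classification_metrics(confusion_counts(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_message(
    und <- classification_metrics(confusion_counts(c(0, 0), c(1, 0))),
    "precision undefined")
  expect_true(is.na(und$precision))
})

test_that("metric formulas agree with an independent count oracle at scale", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    pred <- rbinom(n, 1, 0.5)
    truth <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(pred, truth)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    expect_identical(as.integer(cc), c(tp, tn, fp, fn))
    m <- suppressMessages(classification_metrics(cc))
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
  }
})

test_that("AUC is the Mann-Whitney statistic; PR-AUC integrates stepwise", {
  expect_equal(ranking_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(ranking_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$pr_auc, 1)
  expect_equal(ranking_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # six-sample toy set vs O(n^2) concordant-pair oracle, with a tie
  s <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.7)
  y <- c(0, 0, 1, 0, 1, 1)
  expect_equal(ranking_metrics(s, y)$auc, oracle_auc_pairs(s, y))
  set.seed(5)
  for (i in 1:25) {
    s <- round(runif(12), 1)  # rounded to force ties
    y <- c(rep(0, 6), rep(1, 6))[sample(12)]
    expect_equal(ranking_metrics(s, y)$auc, oracle_auc_pairs(s, y))
  }
  expect_error(ranking_metrics(runif(4), c(1, 1, 1, 1)), "both classes")
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- runif(80)
  y <- rbinom(80, 1, plogis(3 * (s - 0.5)))
  expect_equal(ranking_metrics(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("McNemar comparison handles correction, exact and asymptotic branches", {
  # b = 10, c = 2: corrected statistic (8-1)^2/12
  labels <- rep(0, 12)
  pa <- c(rep(0, 10), rep(1, 2))   # a right where b wrong and vice versa
  pb <- c(rep(1, 10), rep(0, 2))
  r <- mcnemar_compare(pa, pb, labels)
  expect_equal(r$b, 10); expect_equal(r$c, 2)
  expect_equal(r$statistic, 4.0833, tolerance = 5e-5)
  expect_equal(r$method, "exact-binomial")
  expect_equal(r$p_value, binom.test(10, 12, 0.5)$p.value)
  # b = c: correction floors the statistic at 0
  r2 <- mcnemar_compare(c(0, 1), c(1, 0), c(0, 0))
  expect_equal(r2$statistic, 0)
  # identical predictions: degenerate, p = 1
  r3 <- mcnemar_compare(c(1, 0, 1), c(1, 0, 1), c(1, 1, 1))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  # large discordance: chi-square branch agrees with the stats implementation
  la <- rep(0, 60)
  pa <- c(rep(0, 40), rep(1, 20))
  pb <- c(rep(1, 40), rep(0, 20))
  r4 <- mcnemar_compare(pa, pb, la)
  expect_equal(r4$method, "chi-square")
  tab <- table(factor(pa == la, c(FALSE, TRUE)), factor(pb == la, c(FALSE, TRUE)))
  expect_equal(r4$p_value, mcnemar.test(tab, correct = TRUE)$p.value)
})

test_that("5x2cv paired t-test is antisymmetric and degenerates safely", {
  co <- generate_cohort(generator_spec(n = 80, seed = 41))
  # cheap builders: threshold on one standardized feature
  glucose_rule <- function(cohort, tr, te) {
    cut <- median(cohort$features$Glucose[tr])
    as.integer(cohort$features$Glucose[te] > cut)
  }
  bmi_rule <- function(cohort, tr, te) {
    cut <- median(cohort$features$BMI[tr])
    as.integer(cohort$features$BMI[te] > cut)
  }
  r_ab <- five_by_two_cv_ttest(co, glucose_rule, bmi_rule, seed = 7)
  r_ba <- five_by_two_cv_ttest(co, bmi_rule, glucose_rule, seed = 7)
  expect_equal(r_ab$statistic, -r_ba$statistic)
  expect_equal(r_ab$p_value, r_ba$p_value)
  expect_equal(r_ab$df, 5L)
  # straight-line transcription of the formula from the stored differences
  d <- r_ab$differences
  s2 <- (d[, 1] - rowMeans(d))^2 + (d[, 2] - rowMeans(d))^2
  expect_equal(r_ab$statistic, d[1, 1] / sqrt(mean(s2)))
  expect_equal(r_ab$p_value, 2 * pt(-abs(r_ab$statistic), 5))
  # identical builders: zero variance flagged, p = 1
  r_same <- five_by_two_cv_ttest(co, glucose_rule, glucose_rule, seed = 7)
  expect_true(r_same$degenerate)
  expect_equal(r_same$p_value, 1)
})

test_that("Bonferroni threshold is alpha over k", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 4), 0.025)
  expect_error(bonferroni_threshold(1.5, 2))
})

test_that("bootstrap intervals are seed-deterministic and match a seeded oracle", {
  acc_fn <- function(s, y) mean((s >= 0.5) == y)
  set.seed(51)
  s <- runif(40)
  y <- rbinom(40, 1, s)
  ci1 <- bootstrap_ci(acc_fn, s, y, B = 50, seed = 9)
  ci2 <- bootstrap_ci(acc_fn, s, y, B = 50, seed = 9)
  expect_identical(ci1, ci2)
  orc <- oracle_bootstrap(acc_fn, s, y, B = 50, level = 0.95, seed = 9)
  expect_equal(as.numeric(ci1), orc)
  # constant-correct classifier: degenerate interval at 1
  ci3 <- bootstrap_ci(acc_fn, rep(0.9, 10), rep(1, 10), B = 30, seed = 2)
  expect_equal(as.numeric(ci3), c(1, 1))
})

test_that("bootstrap intervals narrow as n grows", {
  acc_fn <- function(s, y) mean((s >= 0.5) == y)
  widths <- vapply(c(50, 200, 1000), function(n) {
    ws <- vapply(1:5, function(seed) {
      set.seed(seed)
      y <- rbinom(n, 1, 0.5)
      s <- ifelse(runif(n) < 0.8, y, 1 - y) * 0.98 + 0.01  # ~80% accuracy
      ci <- bootstrap_ci(acc_fn, s, y, B = 200, seed = seed)
      ci[["hi"]] - ci[["lo"]]
    }, numeric(1))
    mean(ws)
  }, numeric(1))
  expect_true(widths[1] > widths[2])
  expect_true(widths[2] > widths[3])
})

test_that("calibration report computes ECE, bins, and triage distribution", {
  mk_results <- function(mu_pos, mu_neg, labels) {
    fuse_like <- data.frame(
      sample_id = seq_along(mu_pos), lambda_pos = 0, lambda_neg = 0,
      mu_pos = mu_pos, mu_neg = mu_neg,
      fuzzy_score = fuzzy_score(mu_pos, mu_neg),
      label = decide_label(fuzzy_score(mu_pos, mu_neg)),
      confidence_level = confidence_level(pmax(mu_pos, mu_neg)))
    class(fuse_like) <- c("mmfde_fusion", "data.frame")
    fuse_like
  }
  # all mu_max = 1 and all correct: ECE 0
  res <- mk_results(rep(0.9999999, 4), rep(0.2, 4), rep(1, 4))
  expect_equal(calibration_report(res, rep(1, 4))$ece, 0, tolerance = 1e-6)
  # single bin at 0.9 with half correct: ECE |0.5 - 0.9| = 0.4
  res2 <- mk_results(rep(0.9, 4), rep(0.2, 4), c(1, 1, 1, 1))
  expect_equal(calibration_report(res2, c(1, 1, 0, 0))$ece, 0.4)
  # worked-example levels: 2 VeryHigh, 2 High, 1 Moderate
  f <- worked_example_fixture()
  res3 <- mk_results(f$mu_pos, f$mu_neg, f$actual)
  lev <- calibration_report(res3, f$actual)$level_distribution
  expect_equal(as.numeric(lev[c("VeryHigh", "High", "Moderate")]),
               c(2, 2, 1) / 5)
  expect_equal(sum(as.numeric(lev)), 1)
})

test_that("ECE vanishes when per-bin accuracy equals confidence", {
  set.seed(71)
  n <- 10000
  conf <- runif(n, 0.02, 0.999)
  correct <- rbinom(n, 1, conf)
  # construct fusion-shaped results whose mu_max equals conf and whose
  # label is right exactly when 'correct' says so
  labels <- rbinom(n, 1, 0.5)
  pred <- ifelse(correct == 1, labels, 1 - labels)
  res <- data.frame(
    sample_id = 1:n, lambda_pos = 0, lambda_neg = 0,
    mu_pos = ifelse(pred == 1, conf, pmin(1 - conf, conf)),
    mu_neg = ifelse(pred == 0, conf, pmin(1 - conf, conf)),
    fuzzy_score = ifelse(pred == 1, 0.9, 0.1),
    label = pred,
    confidence_level = confidence_level(conf))
  class(res) <- c("mmfde_fusion", "data.frame")
  expect_lt(calibration_report(res, labels)$ece, 0.03)
})

test_that("ablation redistributes weight proportionally and reports deltas", {
  f <- worked_example_fixture()
  cm <- confidence_matrix(f$probabilities)
  ab <- ablation_study(cm, f$actual, distance_weights(0.3, 0.3, 0.2, 0.2),
                       beta = 1.905, drop = "cosine")
  expect_equal(as.numeric(unclass(ab$weights)), c(0.375, 0.375, 0, 0.25))
  # dropping a zero-weight metric is a no-op
  w0 <- distance_weights(0.4, 0.4, 0, 0.2)
  ab0 <- ablation_study(cm, f$actual, w0, beta = 1.905, drop = "cosine")
  expect_equal(ab0$delta_accuracy, 0)
  expect_equal(ab0$metrics$accuracy, ab0$full_metrics$accuracy)
  # dropping a metric holding all the weight is impossible
  expect_error(ablation_study(cm, f$actual, distance_weights(0, 0, 1, 0),
                              drop = "cosine"), "all the weight")
  # all four drops run and report a delta
  for (d in c("euclidean", "manhattan", "cosine", "chebyshev")) {
    r <- ablation_study(cm, f$actual, drop = d, beta = 1.905)
    expect_true(is.finite(r$delta_accuracy))
  }
})
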