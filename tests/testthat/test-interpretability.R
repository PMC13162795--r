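test_that("tree-path attributions are additive and vanish for constant models", {
  fx <- make_trained_fixture(n = 160, seed = 19, n_estimators = 25L)
  at <- explain_predictions(fx$ensemble, fx$x_test)
  expect_identical(at$mode, "per_model_mean")
  expect_equal(dim(at$values), c(nrow(fx$x_test), 8))
  resid <- at$base_value + rowSums(at$values) - at$explained_output
  expect_lt(max(abs(resid)), 1e-4)
  # constant features carry no signal: every attribution is zero
  n <- 60
  const <- cohort_table(
    as.data.frame(matrix(0.5, n, 8,
                         dimnames = list(NULL, names(fx$x_test)))),
    rep(c(0L, 1L), n / 2), check_ranges = FALSE)
  specs <- default_base_specs()
  for (k in names(specs)) specs[[k]]$n_estimators <- 10L
  ens0 <- train_base_models(const, specs)
  at0 <- explain_predictions(ens0, const$features)
  expect_equal(max(abs(at0$values)), 0)
})

test_that("a single informative feature collects nearly all attribution", {
  set.seed(29)
  n <- 1000
  cols <- c("Pregnancies", "Glucose", "BloodPressure", "SkinThickness",
            "Insulin", "BMI", "DPF", "Age")
  feats <- as.data.frame(matrix(runif(n * 8), n, 8, dimnames = list(NULL, cols)))
  y <- as.integer(feats$Glucose > 0.5)
  co <- cohort_table(feats, y, check_ranges = FALSE)
  specs <- default_base_specs()
  for (k in names(specs)) specs[[k]]$n_estimators <- 60L
  ens <- train_base_models(co, specs)
  at <- explain_predictions(ens, feats)
  imp <- colMeans(abs(at$values))
  expect_gte(imp[["Glucose"]] / sum(imp), 0.95)
})

test_that("sampling attributions of the fused score are additive by construction", {
  fx <- make_trained_fixture(n = 120, seed = 37, n_estimators = 15L)
  x <- fx$x_test[1:8, , drop = FALSE]
  at <- explain_predictions(fx$ensemble, x, mode = "fused_model_agnostic",
                            background = fx$x_test, nsim = 8L, seed = 3)
  expect_identical(at$mode, "fused_model_agnostic")
  resid <- at$base_value + rowSums(at$values) - at$explained_output
  expect_lt(max(abs(resid)), 1e-10)
  # explained output is the actual fused fuzzy score
  conf <- predict_confidences(fx$ensemble, x)
  expect_equal(at$explained_output, fuse_confidences(conf)$fuzzy_score,
               tolerance = 1e-10)
  # deterministic given the sampling seed
  at2 <- explain_predictions(fx$ensemble, x, mode = "fused_model_agnostic",
                             background = fx$x_test, nsim = 8L, seed = 3)
  expect_identical(at$values, at2$values)
  expect_error(explain_predictions(fx$ensemble, x, mode = "nonsense"),
               "unknown attribution mode")
})

test_that("global importance ranks by mean absolute attribution, ties alphabetical", {
  tab <- structure(list(values = matrix(c(1, 1, -3, 3), 2,
                                        dimnames = list(NULL, c("a", "b"))),
                        base_value = c(0, 0), explained_output = c(0, 0),
                        feature_names = c("a", "b"), mode = "per_model_mean"),
                   class = "attribution_table")
  gi <- global_importance(tab)
  expect_equal(gi$feature, c("b", "a"))
  expect_equal(gi$importance, c(3, 1))
  zero <- tab
  zero$values[] <- 0
  expect_equal(global_importance(zero)$feature, c("a", "b"))  # alphabetical
  expect_equal(nrow(gi), 2)
})

test_that("rank stability reproduces exact Kendall tau cases", {
  r <- c("Glucose", "BMI", "DPF", "Age", "Insulin")
  expect_equal(rank_stability(list(r, r, r), k = 5), 1)
  expect_equal(rank_stability(list(r, rev(r)), k = 5), -1)
  swap <- r[c(1, 2, 4, 3, 5)]  # one adjacent transposition: 1 - 2/10
  expect_equal(rank_stability(list(r, swap), k = 5), 0.8)
  expect_warning(tau <- rank_stability(list(r, swap), k = 10), "clamped")
  expect_equal(tau, 0.8)
  expect_error(rank_stability(list(r, c(r[-5], "Other"))), "same features")
})

test_that("concordance analysis applies the sign-agreement definitions", {
  mk_results <- function(labels, mu_max = rep(0.95, length(labels))) {
    df <- data.frame(sample_id = seq_along(labels), lambda_pos = 0,
                     lambda_neg = 0, mu_pos = mu_max, mu_neg = 0.1,
                     fuzzy_score = 0.8, label = labels,
                     confidence_level = confidence_level(mu_max))
    class(df) <- c("mmfde_fusion", "data.frame")
    df
  }
  mk_table <- function(vals) {
    structure(list(values = vals, base_value = rep(0, nrow(vals)),
                   explained_output = rowSums(vals),
                   feature_names = colnames(vals), mode = "per_model_mean"),
              class = "attribution_table")
  }
  # constructed full agreement: positive dominant attribution, predicted 1
  v <- matrix(c(2, 1, 3, 0.5), 4, 2)
  colnames(v) <- c("Glucose", "BMI")
  r <- concordance_analysis(mk_table(v), mk_results(rep(1L, 4)), rep(1L, 4))
  expect_equal(r$concordance_pct, 100)
  # signs (+,+,-,-) against fused labels (1,0,0,1): samples 2 and 4 discordant
  v2 <- cbind(Glucose = c(2, 3, -1, -2), BMI = c(0.5, 0.5, 0.5, 0.5))
  res2 <- mk_results(c(1L, 0L, 0L, 1L), mu_max = c(0.95, 0.6, 0.95, 0.65))
  truth2 <- c(1L, 0L, 1L, 1L)
  r2 <- concordance_analysis(mk_table(v2), res2, truth2)
  expect_equal(r2$concordance_pct, 50)
  expect_equal(which(!r2$concordant), c(2L, 4L))
  # both discordant samples sit at moderate confidence
  expect_equal(r2$pct_discordant_with_moderate_confidence, 100)
  # strata misclassification versus an independent group-by oracle
  correct <- res2$label == truth2
  expect_equal(r2$misclassification_rate_concordant,
               100 * mean(!correct[r2$concordant]))
  expect_equal(r2$misclassification_rate_discordant,
               100 * mean(!correct[!r2$concordant]))
  # invariant to feature-order permutation
  r2p <- concordance_analysis(mk_table(v2[, c("BMI", "Glucose")]), res2, truth2)
  expect_equal(r2p$concordance_pct, r2$concordance_pct)
  expect_equal(r2p$misclassification_rate_discordant,
               r2$misclassification_rate_discordant)
  # all-zero rows are excluded with a count
  v3 <- v2
  v3[1, ] <- 0
  r3 <- concordance_analysis(mk_table(v3), res2, truth2)
  expect_equal(r3$n, 3)
  expect_equal(r3$n_excluded_zero, 1)
})

test_that("dominant clinical signals are recovered across folds", {
  # generator truth: Glucose and BMI carry the two largest effects
  co <- generate_cohort(generator_spec(n = 600, noise_sd = 0.4, seed = 43))
  specs <- default_base_specs()
  for (k in names(specs)) specs[[k]]$n_estimators <- 40L
  folds <- stratified_folds(co$outcome, 5, seed = 43)
  top2_hits <- 0L
  rankings <- list()
  for (k in 1:5) {
    tr <- which(folds != k)
    pp <- preprocess_cohort(co, fit_on = tr)
    ens <- train_base_models(
      cohort_table(pp$features[tr, , drop = FALSE], pp$outcome[tr],
                   check_ranges = FALSE), specs)
    at <- explain_predictions(ens, pp$features[folds == k, , drop = FALSE])
    gi <- global_importance(at)
    rankings[[k]] <- gi$feature
    if (setequal(gi$feature[1:2], c("Glucose", "BMI"))) top2_hits <- top2_hits + 1L
  }
  expect_gte(top2_hits, 4L)
  tau <- rank_stability(rankings, k = 5)
  expect_gt(tau, 0.3)  # informative folds agree far beyond chance
})
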