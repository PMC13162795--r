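#' Enumerate the simplex grid of distance weights
#'
#' All compositions of 1 into four parts on a fixed step (default 5%), i.e.
#' every weight vector `(w_e, w_m, w_c, w_ch)` with entries that are integer
#' multiples of `step` summing to 1. The grid size follows the stars-and-bars
#' count `choose(1/step + 3, 3)` (1771 candidates at step 0.05).
#'
#' @param step grid increment; `1/step` must be an integer.
#' @return object of class `weight_grid`: list with `step` and `candidates`
#'   (a 4-column matrix, one candidate per row).
#' @examples
#' nrow(enumerate_weight_grid(0.5)$candidates)  # 10
#' @export
enumerate_weight_grid <- function(step = 0.05) {
  stopifnot(step > 0, step <= 1)
  n <- 1 / step
  if (abs(n - round(n)) > 1e-9) {
    stop(sprintf("1/step must be an integer (got step = %g)", step))
  }
  n <- as.integer(round(n))
  cand <- list()
  i <- 1L
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    cand[[i]] <- c(a, b, cc, n - a - b - cc)
    i <- i + 1L
  }
  candidates <- do.call(rbind, cand) * step
  colnames(candidates) <- c("w_e", "w_m", "w_c", "w_ch")
  structure(list(step = step, candidates = candidates), class = "weight_grid")
}

#' @export
print.weight_grid <- function(x, ...) {
  cat(sprintf("weight_grid: step %.3g, %d candidates on the 4-simplex\n",
              x$step, nrow(x$candidates)))
  invisible(x)
}

# fused accuracy of every weight candidate on one fold's confidences,
# exploiting that the decision depends only on lambda_pos vs lambda_neg
fold_accuracy_by_candidate <- function(conf, labels, candidates, normalize = TRUE) {
  p <- unclass(conf)
  dpos <- metric_components(p, positive = TRUE, normalize = normalize)
  dneg <- metric_components(p, positive = FALSE, normalize = normalize)
  lp <- dpos %*% t(candidates)   # n x n_candidates
  ln <- dneg %*% t(candidates)
  pred <- (lp <= ln) * 1L        # score >= 0.5  <=>  lambda_pos <= lambda_neg
  colMeans(pred == labels)
}

#' Grid search for the distance weights
#'
#' Evaluates every weight candidate by the mean cross-validated accuracy of
#' the fused decision over the per-fold out-of-fold confidences. Ties are
#' broken by maximum Shannon entropy of the weight vector (preferring
#' balanced fusions), then lexicographically — deterministic.
#'
#' @param cv an `mmfde_cv` from [cv_confidences()].
#' @param grid a [enumerate_weight_grid()] result.
#' @param beta membership decay used during the search (default 2.0; the
#'   weight search precedes beta tuning and the fused *decision* is
#'   beta-free).
#' @param normalize metric normalization switch (see
#'   [multi_metric_distances()]).
#' @return object of class `tuning_result` with `best_weights`,
#'   `cv_accuracy_by_candidate` (full trace), and the `grid`.
#' @export
search_weights <- function(cv, grid = enumerate_weight_grid(), beta = 2.0,
                           normalize = TRUE) {
  stopifnot(inherits(cv, "mmfde_cv"))
  cand <- grid$candidates
  if (is.null(cand) || nrow(cand) == 0L) stop("empty weight grid")
  acc_folds <- vapply(cv$per_fold, function(f) {
    fold_accuracy_by_candidate(f$confidences, f$labels, cand, normalize)
  }, numeric(nrow(cand)))
  if (is.null(dim(acc_folds))) acc_folds <- matrix(acc_folds, nrow = nrow(cand))
  mean_acc <- rowMeans(acc_folds)
  best <- pick_best_weights(cand, mean_acc)
  structure(list(
    best_weights = distance_weights(cand[best, 1L], cand[best, 2L],
                                    cand[best, 3L], cand[best, 4L]),
    best_beta = beta,
    cv_accuracy_by_candidate = mean_acc,
    grid = grid
  ), class = "tuning_result")
}

# argmax accuracy; ties -> max weight entropy, then lexicographic (row order)
pick_best_weights <- function(candidates, acc, tol = 1e-12) {
  top <- which(acc >= max(acc) - tol)
  if (length(top) == 1L) return(top)
  ent <- apply(candidates[top, , drop = FALSE], 1L, function(w) {
    w <- w[w > 0]
    -sum(w * log(w))
  })
  top <- top[ent >= max(ent) - tol]
  top[1L]
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("tuning_result\n  best weights: ")
  print(x$best_weights)
  cat(sprintf("  beta: %.3g\n  candidates evaluated: %d (best mean CV accuracy %.4f)\n",
              x$best_beta, length(x$cv_accuracy_by_candidate),
              max(x$cv_accuracy_by_candidate)))
  invisible(x)
}

#' Grid search for the membership decay rate beta
#'
#' Carves a stratified validation split (default 20%) from the training
#' cohort, trains the base models on the remainder, and selects the beta on
#' the grid `[grid_lo, grid_hi]` (default 0.5 to 5.0 by 0.5, ten values)
#' minimizing the mean binary cross-entropy between the fuzzy score and the
#' validation labels. Ties resolve to the smaller beta.
#'
#' @param cohort raw [cohort_table()] (the training partition).
#' @param specs base model specs.
#' @param weights fixed [distance_weights()] (tuned first).
#' @param grid_lo,grid_hi,step beta grid bounds and increment.
#' @param validation_fraction share held out for the beta objective.
#' @param seed split seed.
#' @param impute_zeros passed to [preprocess_cohort()].
#' @param normalize metric normalization switch.
#' @return list with `best_beta` and `objective_trace` (named cross-entropy
#'   per grid value).
#' @export
search_beta <- function(cohort, specs = default_base_specs(),
                        weights = distance_weights(), grid_lo = 0.5,
                        grid_hi = 5.0, step = 0.5,
                        validation_fraction = 0.2, seed = 42L,
                        impute_zeros = TRUE, normalize = TRUE) {
  stopifnot(grid_lo < grid_hi, step > 0)
  betas <- seq(grid_lo, grid_hi, by = step)
  y <- cohort$outcome
  sp <- train_test_split(cohort, split_plan(train_fraction = 1 - validation_fraction,
                                            seed = seed))
  fit_idx <- sp$train
  val_idx <- sp$test
  if (length(unique(y[val_idx])) < 2L || length(unique(y[fit_idx])) < 2L) {
    stop("degenerate validation split: a partition contains a single class")
  }
  pp <- preprocess_cohort(cohort, fit_on = fit_idx, impute_zeros = impute_zeros)
  ens <- train_base_models(cohort_table(pp$features[fit_idx, , drop = FALSE],
                                        y[fit_idx], check_ranges = FALSE), specs)
  conf <- predict_confidences(ens, pp$features[val_idx, , drop = FALSE])
  trace <- vapply(betas, function(b) {
    res <- fuse_confidences(conf, weights, beta = b, normalize = normalize)
    binary_cross_entropy(res$fuzzy_score, y[val_idx])
  }, numeric(1L))
  names(trace) <- as.character(betas)
  list(best_beta = betas[which.min(trace)], objective_trace = trace)
}

binary_cross_entropy <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Accuracy surface over a 2-D slice of the weight simplex
#'
#' Evaluates fused cross-validated accuracy over a grid of
#' `(w_e, w_m)` with the cosine and Chebyshev weights set equal,
#' `w_c = w_ch = (1 - w_e - w_m) / 2`. Points with `w_e + w_m > 1` are
#' marked invalid (`NA`). Suitable for contour rendering of the stability
#' plateau around a tuned optimum.
#'
#' @param cv an `mmfde_cv` from [cv_confidences()].
#' @param resolution grid increment along each axis (default 0.05).
#' @param normalize metric normalization switch.
#' @return data.frame with columns `w_e`, `w_m`, `w_c`, `w_ch`, `accuracy`.
#' @export
stability_surface <- function(cv, resolution = 0.05, normalize = TRUE) {
  stopifnot(inherits(cv, "mmfde_cv"))
  ax <- seq(0, 1, by = resolution)
  pts <- expand.grid(w_e = ax, w_m = ax)
  pts$w_c <- (1 - pts$w_e - pts$w_m) / 2
  pts$w_ch <- pts$w_c
  valid <- pts$w_e + pts$w_m <= 1 + 1e-9
  pts$accuracy <- NA_real_
  cand <- as.matrix(pts[valid, c("w_e", "w_m", "w_c", "w_ch")])
  acc_folds <- vapply(cv$per_fold, function(f) {
    fold_accuracy_by_candidate(f$confidences, f$labels, cand, normalize)
  }, numeric(nrow(cand)))
  if (is.null(dim(acc_folds))) acc_folds <- matrix(acc_folds, nrow = nrow(cand))
  pts$accuracy[valid] <- rowMeans(acc_folds)
  pts
}
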