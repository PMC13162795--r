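# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain, slow, element-by-element arithmetic with no
# shared code with R/.

oracle_distances <- function(s, positive = TRUE, normalize = TRUE) {
  m <- length(s)
  dev <- numeric(m)
  for (z in seq_len(m)) dev[z] <- if (positive) 1 - s[z] else s[z] - 0
  d_e <- 0
  for (z in seq_len(m)) d_e <- d_e + dev[z]^2
  d_e <- sqrt(d_e)
  d_m <- 0
  for (z in seq_len(m)) d_m <- d_m + abs(dev[z])
  d_ch <- max(abs(dev))
  if (normalize) {
    d_e <- d_e / sqrt(m)
    d_m <- d_m / m
  }
  v <- if (positive) s else 1 - s
  nv <- sqrt(sum(v * v))
  d_c <- if (nv == 0) 1 else 1 - sum(v * 1) / (nv * sqrt(m))
  if (d_c < 0) d_c <- 0
  c(d_e, d_m, d_c, d_ch)
}

oracle_fuse_label <- function(s, w, beta = 2, normalize = TRUE) {
  lp <- sum(w * oracle_distances(s, TRUE, normalize))
  ln <- sum(w * oracle_distances(s, FALSE, normalize))
  mu_p <- exp(-beta * lp)
  mu_n <- exp(-beta * ln)
  score <- exp(mu_p) / (exp(mu_p) + exp(mu_n))
  as.integer(score >= 0.5)
}

# brute-force weight search over a candidate matrix on per-fold confidences
oracle_weight_search <- function(per_fold, candidates, beta = 2) {
  acc <- numeric(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    w <- candidates[k, ]
    fold_acc <- numeric(length(per_fold))
    for (f in seq_along(per_fold)) {
      conf <- per_fold[[f]]$confidences
      lab <- per_fold[[f]]$labels
      pred <- integer(nrow(conf))
      for (i in seq_len(nrow(conf))) {
        pred[i] <- oracle_fuse_label(as.numeric(conf[i, ]), w, beta)
      }
      fold_acc[f] <- mean(pred == lab)
    }
    acc[k] <- mean(fold_acc)
  }
  # same tie policy: max accuracy, then max entropy, then first in grid order
  best <- which(acc >= max(acc) - 1e-12)
  if (length(best) > 1L) {
    ent <- apply(candidates[best, , drop = FALSE], 1, function(w) {
      w <- w[w > 0]; -sum(w * log(w))
    })
    best <- best[ent >= max(ent) - 1e-12]
  }
  list(best = best[1L], acc = acc)
}

# stars-and-bars count of compositions of 1/step into 4 non-negative parts
oracle_grid_size <- function(step) {
  n <- round(1 / step)
  count <- 0L
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) count <- count + 1L
  count
}

oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_bootstrap <- function(metric_fn, scores, labels, B, level, seed,
                             needs_both = FALSE) {
  n <- length(scores)
  out <- numeric(B)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (!needs_both || length(unique(labels[idx])) > 1) break
    }
    out[b] <- metric_fn(scores[idx], labels[idx])
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  a <- (1 - level) / 2
  q <- quantile(out, c(a, 1 - a), names = FALSE, type = 7)
  c(q[1], q[2])
}

# a small preprocessed cohort with trained models, shared across test files
make_trained_fixture <- function(n = 240, seed = 11, n_estimators = 40L,
                                 noise_sd = 0.5) {
  cohort <- generate_cohort(generator_spec(n = n, noise_sd = noise_sd,
                                           seed = seed))
  sp <- train_test_split(cohort, split_plan(seed = seed))
  pp <- preprocess_cohort(cohort, fit_on = sp$train)
  specs <- default_base_specs()
  for (k in names(specs)) specs[[k]]$n_estimators <- n_estimators
  ens <- train_base_models(
    cohort_table(pp$features[sp$train, , drop = FALSE],
                 pp$outcome[sp$train], check_ranges = FALSE), specs)
  list(cohort = cohort, split = sp, pp = pp, specs = specs, ensemble = ens,
       x_test = pp$features[sp$test, , drop = FALSE],
       y_test = cohort$outcome[sp$test])
}
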