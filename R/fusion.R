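#' Confidence matrix of base-model probabilities
#'
#' Container for per-sample, per-model positive-class probabilities from an
#' ensemble of M binary classifiers. The negative-class confidence is the
#' complement `1 - p`, so for binary problems only the positive column per
#' model is stored; `S_pos + S_neg = 1` holds by construction.
#'
#' @param pos numeric matrix (samples x models) of positive-class
#'   probabilities in `[0, 1]`, or a data.frame coercible to one.
#' @param model_ids character vector of model labels; defaults to the column
#'   names of `pos`.
#' @return An object of class `confidence_matrix`: the probability matrix with
#'   `model_ids` and `class_ids` attributes.
#' @examples
#' cm <- confidence_matrix(matrix(c(0.9, 0.8, 0.1, 0.2), nrow = 2),
#'                         model_ids = c("a", "b"))
#' @export
confidence_matrix <- function(pos, model_ids = colnames(pos)) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  if (ncol(pos) < 1L) stop("confidence matrix needs at least one model (M >= 1)")
  bad <- which(!is.finite(pos) | pos < 0 | pos > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("confidence for model %d, sample %d outside [0, 1]",
                 bad[1L, 2L], bad[1L, 1L]))
  }
  if (is.null(model_ids)) model_ids <- paste0("model", seq_len(ncol(pos)))
  colnames(pos) <- model_ids
  structure(pos,
            model_ids = model_ids,
            class_ids = c(negative = 0L, positive = 1L),
            class = c("confidence_matrix", "matrix", "array"))
}

#' @export
print.confidence_matrix <- function(x, ...) {
  cat(sprintf("confidence_matrix: %d samples x %d models (%s)\n",
              nrow(x), ncol(x), paste(attr(x, "model_ids"), collapse = ", ")))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Deviation vector from full confidence
#'
#' Elementwise complement `1 - S` of a vector of classifier confidences for a
#' class: entry z measures how far classifier z falls short of full confidence
#' in that class.
#'
#' @param confidences numeric vector of length M with entries in `[0, 1]`.
#' @return numeric vector `1 - confidences`.
#' @examples
#' deviation_vector(c(0.0118, 0.0104, 0.0073, 0.1277))
#' @export
deviation_vector <- function(confidences) {
  confidences <- as.numeric(confidences)
  bad <- which(!is.finite(confidences) | confidences < 0 | confidences > 1)
  if (length(bad) > 0L) {
    stop(sprintf("confidence for model %d outside [0, 1]", bad[1L]))
  }
  1 - confidences
}

#' Convex weights over the four distance metrics
#'
#' @param w_e,w_m,w_c,w_ch non-negative weights for the Euclidean, Manhattan,
#'   cosine, and Chebyshev distances; must sum to 1 (within 1e-9).
#' @return An object of class `distance_weights` (named numeric of length 4).
#' @examples
#' distance_weights(0.30, 0.30, 0.20, 0.20)
#' @export
distance_weights <- function(w_e = 0.30, w_m = 0.30, w_c = 0.20, w_ch = 0.20) {
  w <- c(w_e = w_e, w_m = w_m, w_c = w_c, w_ch = w_ch)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("distance weights must be finite and non-negative")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("distance weights must sum to 1 (got %.12f)", sum(w)))
  }
  structure(w, class = "distance_weights")
}

#' @export
print.distance_weights <- function(x, ...) {
  cat("distance_weights:",
      paste(sprintf("%s=%.3f", names(unclass(x)), unclass(x)), collapse = " "),
      "\n")
  invisible(x)
}

as_distance_weights <- function(w) {
  if (inherits(w, "distance_weights")) return(w)
  w <- as.numeric(w)
  if (length(w) != 4L) stop("expected four distance weights")
  distance_weights(w[1L], w[2L], w[3L], w[4L])
}

#' Four distances between a confidence vector and an ideal reference
#'
#' Computes the Euclidean, Manhattan, cosine, and Chebyshev distances between
#' an M-vector of classifier confidences and an ideal reference vector (the
#' all-ones prototype of full agreement on a class, or the all-zeros
#' prototype of full disagreement).
#'
#' In the default normalized form the Euclidean distance is divided by
#' `sqrt(M)` and the Manhattan distance by `M`, so all four metrics lie in
#' `[0, 1]` and a convex combination of them stays in `[0, 1]`. With
#' `normalize = FALSE` the raw (unbounded) sums are returned.
#'
#' The cosine distance is always taken against the all-ones direction, since
#' the zero vector has no direction: for the zero ideal the deviation vector
#' `1 - S` is compared with the ones vector instead. A zero-magnitude input
#' vector yields maximal misalignment `d_c = 1` rather than 0/0.
#'
#' @param confidences numeric vector of length M in `[0, 1]`.
#' @param ideal either the string `"positive"` / `"negative"`, or a numeric
#'   length-M vector of all ones / all zeros.
#' @param normalize logical; divide Euclidean by `sqrt(M)` and Manhattan by M
#'   (default `TRUE`).
#' @return An object of class `metric_bundle`: named numeric
#'   `(d_e, d_m, d_c, d_ch)`.
#' @examples
#' multi_metric_distances(c(0.5, 0.5, 0.5, 0.5), "positive")
#' @export
multi_metric_distances <- function(confidences, ideal = c("positive", "negative"),
                                   normalize = TRUE) {
  s <- as.numeric(confidences)
  m <- length(s)
  if (m < 1L) stop("confidence vector must have M >= 1 entries")
  bad <- which(!is.finite(s) | s < 0 | s > 1)
  if (length(bad) > 0L) {
    stop(sprintf("confidence for model %d outside [0, 1]", bad[1L]))
  }
  if (is.character(ideal)) {
    ideal <- match.arg(ideal)
    positive <- identical(ideal, "positive")
  } else {
    iv <- as.numeric(ideal)
    if (length(iv) != m) stop("ideal reference length must match M")
    if (all(iv == 1)) positive <- TRUE
    else if (all(iv == 0)) positive <- FALSE
    else stop("ideal reference must be the all-ones or all-zeros vector")
  }

  dev <- if (positive) 1 - s else s      # |ideal - S| componentwise
  d_e <- sqrt(sum(dev^2))
  d_m <- sum(abs(dev))
  d_ch <- max(abs(dev))
  if (normalize) {
    d_e <- d_e / sqrt(m)
    d_m <- d_m / m
  }

  # direction vector compared against the ones prototype; for the zero ideal
  # the deviation vector (1 - S) carries the direction
  v <- if (positive) s else 1 - s
  nv <- sqrt(sum(v^2))
  d_c <- if (nv == 0) 1 else 1 - sum(v) / (nv * sqrt(m))
  d_c <- min(max(d_c, 0), 1)   # clamp tiny negative rounding

  structure(c(d_e = d_e, d_m = d_m, d_c = d_c, d_ch = d_ch),
            class = "metric_bundle")
}

#' Weighted hybrid distance
#'
#' Convex combination of the four metric distances. In normalized form the
#' result lies in `[0, 1]`.
#'
#' @param bundle a `metric_bundle` (or named/plain numeric of length 4 in the
#'   order Euclidean, Manhattan, cosine, Chebyshev).
#' @param weights a [distance_weights()] object (or length-4 numeric summing
#'   to 1).
#' @return non-negative scalar `w_e*d_e + w_m*d_m + w_c*d_c + w_ch*d_ch`.
#' @examples
#' b <- multi_metric_distances(c(0.5, 0.5, 0.5, 0.5), "positive")
#' hybrid_distance(b, distance_weights())
#' @export
hybrid_distance <- function(bundle, weights = distance_weights()) {
  weights <- as_distance_weights(weights)
  d <- as.numeric(bundle)
  if (length(d) != 4L) stop("metric bundle must contain four distances")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and non-negative")
  sum(unclass(weights) * d)
}

#' Exponential-decay fuzzy membership
#'
#' Maps a non-negative hybrid distance to a membership degree
#' `mu = exp(-beta * lambda)` in `(0, 1]`. `beta` controls how sharply
#' confidence decays with distance from the ideal prototype.
#'
#' @param lambda non-negative distance (vectorised).
#' @param beta positive decay rate.
#' @return membership degree(s) in `(0, 1]`.
#' @examples
#' membership(0.5688, beta = 1.905)
#' @export
membership <- function(lambda, beta = 2.0) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("beta must be a single positive number")
  }
  lambda <- as.numeric(lambda)
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("lambda must be finite and non-negative")
  }
  exp(-beta * lambda)
}

#' Normalized fuzzy score
#'
#' Softmax-style reconciliation of the two class memberships:
#' `exp(mu_pos) / (exp(mu_pos) + exp(mu_neg))`. Scores for the two orderings
#' are complementary and a score of 0.5 marks perfect ambiguity.
#'
#' @param mu_pos,mu_neg memberships in `(0, 1]` (vectorised).
#' @return score(s) in `(0, 1)`.
#' @examples
#' fuzzy_score(0.3383, 0.9887)  # 0.3429
#' @export
fuzzy_score <- function(mu_pos, mu_neg) {
  mu_pos <- as.numeric(mu_pos)
  mu_neg <- as.numeric(mu_neg)
  if (any(!is.finite(mu_pos)) || any(!is.finite(mu_neg))) {
    bad <- which(!is.finite(mu_pos) | !is.finite(mu_neg))
    stop(sprintf("non-finite membership for sample %d", bad[1L]))
  }
  if (any(mu_pos <= 0) || any(mu_neg <= 0)) stop("memberships must be positive")
  1 / (1 + exp(mu_neg - mu_pos))
}

#' Threshold decision on the fuzzy score
#'
#' Labels a sample positive (diabetic, 1) when its fuzzy score reaches the
#' threshold. The tie at exactly 0.5 resolves toward the positive class: in a
#' screening setting a miss is costlier than a false alarm. Away from ties the
#' decision coincides with the arg-min over the two hybrid distances.
#'
#' @param score fuzzy score(s) in `(0, 1)`.
#' @param threshold decision threshold, default 0.5.
#' @return integer label(s): 1 positive, 0 negative.
#' @examples
#' decide_label(c(0.3429, 0.5967))
#' @export
decide_label <- function(score, threshold = 0.5) {
  score <- as.numeric(score)
  as.integer(score >= threshold)
}

#' Triage confidence level from the winning membership
#'
#' Maps the larger of the two class memberships to a clinical triage band:
#' `VeryHigh` (`mu > 0.9`, suitable for automated decision support), `High`
#' (`0.7 < mu <= 0.9`, reliable but worth basic verification), `Moderate`
#' (`mu <= 0.7`, near the decision boundary, route to clinician review).
#'
#' @param mu_max membership(s) in `(0, 1]`.
#' @return factor with levels `Moderate < High < VeryHigh`.
#' @examples
#' confidence_level(c(0.9887, 0.6411, 0.9))
#' @export
confidence_level <- function(mu_max) {
  mu_max <- as.numeric(mu_max)
  if (any(!is.finite(mu_max)) || any(mu_max <= 0) || any(mu_max > 1)) {
    stop("mu_max must lie in (0, 1]")
  }
  lev <- ifelse(mu_max > 0.9, "VeryHigh", ifelse(mu_max > 0.7, "High", "Moderate"))
  factor(lev, levels = c("Moderate", "High", "VeryHigh"), ordered = TRUE)
}

#' Fuse a confidence matrix into per-sample predictions
#'
#' Runs the full fusion pipeline per sample: distances of the positive-class
#' probability vector to the ideal positive (all-ones) and ideal negative
#' (all-zeros) prototypes under the four metrics, weighted hybrid distances
#' `lambda_pos` / `lambda_neg`, exponential memberships, normalized fuzzy
#' score, threshold decision, and triage confidence level.
#'
#' @param cmat a [confidence_matrix()] (or samples x models matrix of
#'   positive-class probabilities).
#' @param weights a [distance_weights()] object.
#' @param beta positive membership decay rate (default 2.0; tune per dataset
#'   with [search_beta()]).
#' @param normalize logical; use the `[0, 1]`-commensurable metric form
#'   (default `TRUE`).
#' @param threshold fuzzy-score decision threshold (default 0.5).
#' @return data.frame of class `mmfde_fusion` with columns `sample_id`,
#'   `lambda_pos`, `lambda_neg`, `mu_pos`, `mu_neg`, `fuzzy_score`, `label`,
#'   `confidence_level`.
#' @examples
#' cm <- confidence_matrix(matrix(c(0.95, 0.1, 0.9, 0.2), nrow = 2))
#' fuse_confidences(cm)
#' @export
fuse_confidences <- function(cmat, weights = distance_weights(), beta = 2.0,
                             normalize = TRUE, threshold = 0.5) {
  if (!inherits(cmat, "confidence_matrix")) cmat <- confidence_matrix(cmat)
  if (ncol(cmat) == 0L || nrow(cmat) == 0L) stop("empty ensemble: no models or samples to fuse")
  weights <- as_distance_weights(weights)

  pos <- metric_components(unclass(cmat), positive = TRUE, normalize = normalize)
  neg <- metric_components(unclass(cmat), positive = FALSE, normalize = normalize)
  lambda_pos <- as.numeric(pos %*% unclass(weights))
  lambda_neg <- as.numeric(neg %*% unclass(weights))
  mu_pos <- membership(lambda_pos, beta)
  mu_neg <- membership(lambda_neg, beta)
  score <- fuzzy_score(mu_pos, mu_neg)
  label <- decide_label(score, threshold)
  mu_max <- pmax(mu_pos, mu_neg)

  out <- data.frame(
    sample_id = if (!is.null(rownames(cmat))) rownames(cmat) else seq_len(nrow(cmat)),
    lambda_pos = lambda_pos,
    lambda_neg = lambda_neg,
    mu_pos = mu_pos,
    mu_neg = mu_neg,
    fuzzy_score = score,
    label = label,
    confidence_level = confidence_level(mu_max),
    stringsAsFactors = FALSE
  )
  attr(out, "fusion_params") <- list(weights = unclass(weights), beta = beta,
                                     normalize = normalize, threshold = threshold)
  class(out) <- c("mmfde_fusion", "data.frame")
  out
}

# vectorised per-sample metric components: n x 4 matrix (d_e, d_m, d_c, d_ch)
metric_components <- function(p, positive, normalize = TRUE) {
  m <- ncol(p)
  dev <- if (positive) 1 - p else p
  d_e <- sqrt(rowSums(dev^2))
  d_m <- rowSums(abs(dev))
  d_ch <- apply(abs(dev), 1L, max)
  if (normalize) {
    d_e <- d_e / sqrt(m)
    d_m <- d_m / m
  }
  v <- if (positive) p else 1 - p
  nv <- sqrt(rowSums(v^2))
  d_c <- ifelse(nv == 0, 1, 1 - rowSums(v) / (nv * sqrt(m)))
  d_c <- pmin(pmax(d_c, 0), 1)
  cbind(d_e = d_e, d_m = d_m, d_c = d_c, d_ch = d_ch)
}

#' @export
print.mmfde_fusion <- function(x, ...) {
  p <- attr(x, "fusion_params")
  cat(sprintf("mmfde_fusion: %d samples, beta=%.3g, weights (E,M,C,Ch)=(%s)\n",
              nrow(x), p$beta, paste(sprintf("%.2f", p$weights), collapse = ", ")))
  print.data.frame(utils::head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write fusion results to CSV
#'
#' @param results an `mmfde_fusion` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fusion_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
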