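# Exhaustive feature-subset search with repeated k-fold cross-validation,
# majority-class benchmarking, top-N ranking and the outcome-threshold sweep.

#' Enumerate every non-empty subset of a feature list
#'
#' Binary-counter order over the schema: subset `i` contains feature `j` iff
#' bit `j` of `i` is set, so 6 features yield the 2^6 - 1 = 63 combinations
#' of the full search and 5 features the 31 of the SEP-only fallback.
#'
#' @param features ordered character vector (1-16 names).
#' @return List of character vectors, one per non-empty subset.
#' @examples
#' length(enumerate_feature_subsets(letters[1:6])) # 63
#' @export
enumerate_feature_subsets <- function(features) {
  k <- length(features)
  if (k < 1 || k > 16) stop("between 1 and 16 features required")
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  lapply(seq_len(2L^k - 1L), function(i) features[bitwAnd(i, bits) > 0L])
}

# 0/1 inclusion matrix (subsets x features), the binary coding used in reports.
subset_mask <- function(features, subsets) {
  m <- t(vapply(subsets, function(s) as.integer(features %in% s),
                integer(length(features))))
  colnames(m) <- features
  m
}

#' Accuracy of the majority-class classifier
#'
#' The benchmark every decision tree must beat: always predict the more
#' frequent class, scoring `max(n_pos, n_neg) / n`.
#'
#' @param labels non-empty binary vector (0/1 or logical).
#' @return Proportion in `[0.5, 1]` (for non-degenerate label sets).
#' @examples
#' majority_class_accuracy(rep(c(1, 0), c(58, 38))) # 0.6042
#' @export
majority_class_accuracy <- function(labels) {
  if (length(labels) == 0) stop("empty labels")
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  max(sum(labels == 1L), sum(labels == 0L)) / length(labels)
}

# One repeated-CV evaluation on plain columns (internal hot path).
cv_impl <- function(x, y, schema, features, params, k, iterations, seed,
                    aggregate, stratified) {
  n <- length(y)
  if (n < k) stop("need at least k records for k-fold cross-validation")
  xs <- lapply(x[features], identity)
  acc <- numeric(iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      folds <- if (stratified) {
        f <- integer(n)
        for (cls in c(0L, 1L)) {
          idx <- which(y == cls)
          f[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        f
      } else {
        sample(rep_len(seq_len(k), n))
      }
      correct <- 0L
      fold_acc <- numeric(k)
      for (f in seq_len(k)) {
        te <- which(folds == f)
        if (!length(te)) { fold_acc[f] <- NA_real_; next }
        tr <- which(folds != f)
        # a pure training partition yields a single majority leaf, so every
        # fold is scorable even when no genuine split is fittable
        root <- grow_tree(lapply(xs, `[`, tr), y[tr], schema, params)
        # unseen-level warnings are routine here: a rare categorical level can
        # be absent from any given training partition
        preds <- suppressWarnings(route_tree(root, lapply(xs, `[`, te), length(te)))
        c_f <- sum(preds == y[te])
        correct <- correct + c_f
        fold_acc[f] <- c_f / length(te)
      }
      acc[it] <- if (aggregate == "pooled") correct / n else mean(fold_acc, na.rm = TRUE)
    }
  })
  structure(list(features = features,
                 mean_accuracy = mean(acc),
                 stderr = if (iterations > 1) stats::sd(acc) / sqrt(iterations) else NA_real_,
                 iterations = iterations, k = k, aggregate = aggregate,
                 accuracies = acc),
            class = "dbs_cv")
}

#' Repeated k-fold cross-validation of a tree on one feature subset
#'
#' Each iteration draws a fresh uniform random partition of the patients into
#' `k` near-equal folds (unstratified by default, matching random allocation
#' of each patient to a group), fits a tree on `k - 1` folds and scores the
#' held-out fold. The iteration's accuracy pools correct predictions across
#' folds (`correct / n`; `aggregate = "fold_mean"` averages per-fold
#' accuracies instead). The result reports the mean and standard error of the
#' iteration accuracies. Deterministic given `seed`.
#'
#' @param cohort a labeled `dbs_cohort`.
#' @param features feature subset to use.
#' @param params a [tree_params()] object.
#' @param k number of folds (default 10).
#' @param iterations number of repeated random partitions (default 100).
#' @param seed RNG seed (mandatory: results depend on fold allocation).
#' @param aggregate `"pooled"` (default) or `"fold_mean"`.
#' @param stratified allocate folds within class strata (off by default).
#' @param labels optional labels overriding `cohort$labels`.
#' @return An object of class `dbs_cv` with `mean_accuracy`, `stderr`
#'   (`NA` for a single iteration), `iterations`, `k` and the per-iteration
#'   accuracies.
#' @export
repeated_kfold_cv <- function(cohort, features, params = tree_params(), k = 10,
                              iterations = 100, seed, aggregate = c("pooled", "fold_mean"),
                              stratified = FALSE, labels = NULL) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  aggregate <- match.arg(aggregate)
  labels <- labels %||% cohort$labels
  if (is.null(labels)) stop("labels missing: use set_outcome_labels() first")
  stopifnot(all(features %in% schema_features(cohort$schema)))
  cv_impl(cohort$data, as.integer(labels), cohort$schema, features, params,
          k, iterations, as.integer(seed), aggregate, stratified)
}

#' @export
print.dbs_cv <- function(x, ...) {
  cat(sprintf("<dbs_cv> {%s}: accuracy %.4f (SE %s; %d x %d-fold, %s)\n",
              paste(x$features, collapse = ", "), x$mean_accuracy,
              if (is.na(x$stderr)) "NA" else sprintf("%.4f", x$stderr),
              x$iterations, x$k, x$aggregate))
  invisible(x)
}

#' Exhaustive feature-subset search under repeated cross-validation
#'
#' Evaluates every non-empty subset of `features` with
#' [repeated_kfold_cv()], each subset under its own seed derived
#' deterministically from `(seed, subset index)`, ranks subsets by mean
#' out-of-sample accuracy (ties broken by fewer features, then enumeration
#' order), and tallies how often each feature appears in the top `top_n`
#' subsets. The majority-class accuracy of the labels is recorded as the
#' baseline every tree must beat.
#'
#' @inheritParams repeated_kfold_cv
#' @param features features to search over (defaults to the whole schema).
#' @param top_n size of the ranked head used for feature frequencies
#'   (default 10).
#' @return An object of class `dbs_search`: `results` (one row per subset
#'   with its binary feature coding, mean accuracy, standard error),
#'   `baseline`, `top` (ranked head), `feature_frequency`.
#' @export
run_search <- function(cohort, features = NULL, params = tree_params(), k = 10,
                       iterations = 100, seed, top_n = 10,
                       aggregate = c("pooled", "fold_mean"), stratified = FALSE,
                       labels = NULL) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  aggregate <- match.arg(aggregate)
  labels <- labels %||% cohort$labels
  if (is.null(labels)) stop("labels missing: use set_outcome_labels() first")
  features <- features %||% schema_features(cohort$schema)
  subsets <- enumerate_feature_subsets(features)
  mask <- subset_mask(features, subsets)
  y <- as.integer(labels)

  cvs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    cvs[[i]] <- cv_impl(cohort$data, y, cohort$schema, subsets[[i]], params,
                        k, iterations, derive_seed(seed, i), aggregate, stratified)
  }
  results <- data.frame(
    subset_index = seq_along(subsets),
    mask,
    n_features = vapply(subsets, length, integer(1)),
    mean_accuracy = vapply(cvs, function(z) z$mean_accuracy, numeric(1)),
    stderr = vapply(cvs, function(z) z$stderr, numeric(1)),
    check.names = FALSE
  )
  ranking <- order(-results$mean_accuracy, results$n_features, results$subset_index)
  top_n_eff <- min(top_n, nrow(results))
  top_idx <- ranking[seq_len(top_n_eff)]
  feature_frequency <- colSums(mask[top_idx, , drop = FALSE])
  structure(list(results = results, baseline = majority_class_accuracy(y),
                 top = results[top_idx, , drop = FALSE],
                 feature_frequency = feature_frequency,
                 features = features, subsets = subsets, top_n = top_n_eff,
                 k = k, iterations = iterations, seed = as.integer(seed),
                 params = params, aggregate = aggregate),
            class = "dbs_search")
}

#' @export
print.dbs_search <- function(x, ...) {
  cat(sprintf("<dbs_search> %d subsets of {%s}; baseline %.4f\n",
              nrow(x$results), paste(x$features, collapse = ", "), x$baseline))
  cat(sprintf("top %d feature frequency: %s\n", x$top_n,
              paste(names(x$feature_frequency), x$feature_frequency,
                    sep = "=", collapse = ", ")))
  print(utils::head(x$top, x$top_n), row.names = FALSE)
  invisible(x)
}

#' Robustness of the search to the outcome-definition threshold
#'
#' Re-binarizes the stored percentage change at each threshold, re-runs the
#' exhaustive search, and reports the class split together with the features
#' appearing in more than half of the top-10 models. A threshold leaving
#' either class smaller than `2 * min_leaf` cannot support any admissible
#' split and is flagged as performance degradation; its search is skipped.
#'
#' @inheritParams run_search
#' @param thresholds outcome thresholds in percent (default 0-5).
#' @param mode outcome comparison mode (default `"strict_gt"`, i.e. improved
#'   means change strictly above the threshold).
#' @return An object of class `dbs_threshold_sweep`: a `summary` data frame
#'   (threshold, n_improved, n_not, degraded, best_features) and the list of
#'   per-threshold `dbs_search` objects.
#' @export
outcome_threshold_sweep <- function(cohort, thresholds = 0:5,
                                    mode = c("strict_gt", "ge"),
                                    features = NULL, params = tree_params(),
                                    k = 10, iterations = 100, seed, top_n = 10) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  mode <- match.arg(mode)
  pct <- cohort$data$pct_change
  if (anyNA(pct)) stop("pct_change must be present for all records")
  features <- features %||% schema_features(cohort$schema)

  searches <- vector("list", length(thresholds))
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    thr <- thresholds[i]
    y <- binarize_outcome(pct, thr, mode)
    n_improved <- sum(y == 1L)
    n_not <- sum(y == 0L)
    degraded <- min(n_improved, n_not) < 2L * params$min_leaf
    best_features <- character(0)
    if (!degraded) {
      s <- run_search(cohort, features = features, params = params, k = k,
                      iterations = iterations, seed = derive_seed(seed, 100 + i),
                      top_n = top_n, labels = y)
      searches[[i]] <- s
      best_features <- names(s$feature_frequency)[s$feature_frequency > s$top_n / 2]
    }
    rows[[i]] <- data.frame(threshold = thr, n_improved = n_improved,
                            n_not = n_not, degraded = degraded,
                            best_features = paste(best_features, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), searches = searches,
                 mode = mode, seed = as.integer(seed)),
            class = "dbs_threshold_sweep")
}

#' @export
print.dbs_threshold_sweep <- function(x, ...) {
  cat("<dbs_threshold_sweep> outcome-threshold robustness\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
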