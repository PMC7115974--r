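# Fixed CMCT -> baseline-severity decision tree, confusion metrics, Monte
# Carlo resampling sweep of the severity cutoff, node-1 bounds and ROC points.

#' Prognosis from the fixed CMCT + baseline-severity decision tree
#'
#' The two-node counseling tree: an abnormal CMCT predicts an unfavorable
#' DBS prognosis outright (node 1); with a normal CMCT, the prognosis is
#' favorable iff the baseline BFMDRS-m score is strictly above the chosen
#' severity cutoff (node 2). A score exactly at the cutoff is unfavorable.
#'
#' @param cmct patient-level CMCT status, `"normal"` or `"abnormal"`
#'   (records with status `"NA"` must be removed upstream with
#'   [filter_feature_available()]).
#' @param baseline baseline BFMDRS-m score(s).
#' @param cutoff severity cutoff (single number).
#' @return Integer vector of predictions (1 = favorable).
#' @examples
#' fixed_tree_predict("abnormal", 90, 80) # 0
#' fixed_tree_predict("normal", 81, 80)   # 1
#' @export
fixed_tree_predict <- function(cmct, baseline, cutoff) {
  stopifnot(length(cutoff) == 1, is.finite(cutoff))
  if (any(cmct == "NA")) {
    stop("CMCT status 'NA' is not admissible here; filter the cohort with ",
         "filter_feature_available() first")
  }
  stopifnot(all(cmct %in% c("normal", "abnormal")))
  as.integer(cmct == "normal" & baseline > cutoff)
}

#' Confusion counts of binary prognosis predictions
#'
#' Positive means favorable prognosis: TP = favorable outcomes predicted
#' favorable, TN = poor outcomes predicted poor, FP = poor outcomes predicted
#' favorable, FN = favorable outcomes predicted poor.
#'
#' @param predictions,truths equal-length binary vectors (0/1 or logical).
#' @return An object of class `dbs_confusion`: named integer vector
#'   `c(TP, TN, FP, FN)`.
#' @export
confusion <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  p <- as.integer(predictions)
  t <- as.integer(truths)
  stopifnot(all(p %in% c(0L, 1L)), all(t %in% c(0L, 1L)))
  structure(c(TP = sum(p == 1L & t == 1L), TN = sum(p == 0L & t == 0L),
              FP = sum(p == 1L & t == 0L), FN = sum(p == 0L & t == 1L)),
            class = "dbs_confusion")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`. A metric whose denominator is zero is
#' undefined and reported as `NA` (never coerced to 0), with the undefined
#' metrics named in the `undefined` element.
#'
#' @param cc a `dbs_confusion` (or named vector with TP, TN, FP, FN).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `undefined`.
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0, 1, 0, 1, 0),
#'                           c(1, 0, 0, 1, 1, 0, 1, 0)))
#' @export
compute_metrics <- function(cc) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(cc)), all(cc >= 0))
  tp <- cc[["TP"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
  total <- tp + tn + fp + fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(accuracy = ratio(tp + tn, total),
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp))
  out$undefined <- names(out)[vapply(out[1:3], is.na, logical(1))]
  out
}

#' Node-1 bounds on sensitivity and specificity
#'
#' The first split of the fixed tree (abnormal CMCT -> unfavorable) caps the
#' achievable sensitivity and floors the achievable specificity regardless of
#' the severity cutoff at node 2: every favorable-outcome patient with an
#' abnormal CMCT is irrevocably missed, and every poor-outcome patient with
#' an abnormal CMCT is always correctly called.
#'
#' @param cohort a labeled, CMCT-available `dbs_cohort` (or a character
#'   vector of CMCT statuses, in which case `labels` must be given).
#' @param labels binary outcome labels (defaults to `cohort$labels`).
#' @return List with `sens_upper_bound` = 1 - P(abnormal CMCT | positive) and
#'   `spec_lower_bound` = P(abnormal CMCT | negative).
#' @export
node1_bounds <- function(cohort, labels = NULL) {
  if (inherits(cohort, "dbs_cohort")) {
    cmct <- cohort$data$cmct
    labels <- labels %||% cohort$labels
  } else {
    cmct <- cohort
  }
  if (is.null(labels)) stop("labels missing")
  y <- as.integer(labels)
  if (any(cmct == "NA")) stop("cohort contains CMCT-unavailable records")
  pos <- sum(y == 1L)
  neg <- sum(y == 0L)
  if (pos == 0L || neg == 0L) stop("both outcome classes must be present")
  list(sens_upper_bound = 1 - sum(y == 1L & cmct == "abnormal") / pos,
       spec_lower_bound = sum(y == 0L & cmct == "abnormal") / neg)
}

#' Monte Carlo resampling sweep of the severity cutoff
#'
#' Draws `reps` resamples of `n_sample` patients uniformly with replacement
#' from the CMCT-available pool, applies the fixed CMCT + severity tree at
#' every cutoff on a 0.5-step grid spanning the observed baseline scores, and
#' summarises sensitivity and specificity per cutoff as mean +/- one standard
#' error over resamples. Resamples in which a metric is undefined (no
#' positives or no negatives drawn) are excluded from that metric's summary
#' and counted in the diagnostics. Per-resample node-1 bounds are checked on
#' every draw. Deterministic given `seed`.
#'
#' @param cohort labeled `dbs_cohort` with CMCT available for all records and
#'   both outcome classes present.
#' @param cutoffs explicit cutoff grid (default: `floor(min)` to `ceil(max)`
#'   of the baseline scores in steps of `cutoff_step`).
#' @param cutoff_step grid step in BFMDRS-m points (default 0.5).
#' @param n_sample resample size (default 100).
#' @param reps number of resamples (default 1000).
#' @param seed RNG seed.
#' @param labels optional labels overriding `cohort$labels`.
#' @return An object of class `dbs_mc_sweep`: per-cutoff `sens_mean`,
#'   `sens_se`, `spec_mean`, `spec_se` (in `table`, a data frame), cohort
#'   node-1 bounds, per-cutoff counts of undefined resamples, and
#'   `bounds_respected` (TRUE iff every resample respected its own bounds at
#'   every cutoff).
#' @export
mc_threshold_sweep <- function(cohort, cutoffs = NULL, cutoff_step = 0.5,
                               n_sample = 100, reps = 1000, seed, labels = NULL) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  labels <- labels %||% cohort$labels
  if (is.null(labels)) stop("labels missing: use set_outcome_labels() first")
  y <- as.integer(labels)
  cmct <- cohort$data$cmct
  baseline <- cohort$data$baseline_bfm
  if (any(cmct == "NA")) {
    stop("cohort contains CMCT-unavailable records; apply filter_feature_available() first")
  }
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both outcome classes must be present")
  }
  if (is.null(cutoffs)) {
    cutoffs <- seq(floor(min(baseline)), ceiling(max(baseline)), by = cutoff_step)
  }
  ncut <- length(cutoffs)
  n <- length(y)
  normal <- cmct == "normal"

  sens <- matrix(NA_real_, nrow = reps, ncol = ncut)
  spec <- matrix(NA_real_, nrow = reps, ncol = ncut)
  bounds_ok <- TRUE
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(n, n_sample, replace = TRUE)
      b <- baseline[idx]
      nm <- normal[idx]
      t1 <- y[idx] == 1L
      P <- sum(t1)
      N <- n_sample - P
      pred_pos <- outer(b, cutoffs, `>`) & nm # n_sample x ncut
      if (P > 0L) {
        tp <- colSums(pred_pos[t1, , drop = FALSE])
        sens[r, ] <- tp / P
        ub <- sum(nm[t1]) / P # this resample's node-1 sensitivity ceiling
        if (any(sens[r, ] > ub + 1e-12)) bounds_ok <- FALSE
      }
      if (N > 0L) {
        fp <- colSums(pred_pos[!t1, , drop = FALSE])
        spec[r, ] <- (N - fp) / N
        lb <- sum(!nm[!t1]) / N # this resample's node-1 specificity floor
        if (any(spec[r, ] < lb - 1e-12)) bounds_ok <- FALSE
      }
    }
  })
  summarise <- function(m) {
    defined <- colSums(!is.na(m))
    list(mean = colMeans(m, na.rm = TRUE),
         se = apply(m, 2, function(col) {
           col <- col[!is.na(col)]
           if (length(col) > 1) stats::sd(col) / sqrt(length(col)) else NA_real_
         }),
         n_undefined = reps - defined)
  }
  ss <- summarise(sens)
  sp <- summarise(spec)
  bounds <- node1_bounds(cmct, labels = y)
  structure(list(
    table = data.frame(cutoff = cutoffs,
                       sens_mean = ss$mean, sens_se = ss$se,
                       spec_mean = sp$mean, spec_se = sp$se),
    sens_upper_bound = bounds$sens_upper_bound,
    spec_lower_bound = bounds$spec_lower_bound,
    n_sample = n_sample, reps = reps, seed = as.integer(seed),
    n_pool = n,
    n_undefined_sens = ss$n_undefined, n_undefined_spec = sp$n_undefined,
    bounds_respected = bounds_ok
  ), class = "dbs_mc_sweep")
}

#' @export
print.dbs_mc_sweep <- function(x, ...) {
  cat(sprintf("<dbs_mc_sweep> %d resamples of %d from a pool of %d; %d cutoffs\n",
              x$reps, x$n_sample, x$n_pool, nrow(x$table)))
  cat(sprintf("node-1 bounds: sensitivity <= %.4f, specificity >= %.4f\n",
              x$sens_upper_bound, x$spec_lower_bound))
  print(utils::head(x$table), row.names = FALSE)
  invisible(x)
}

#' Operating point of a Monte Carlo sweep at a given cutoff
#'
#' @param sweep a `dbs_mc_sweep`.
#' @param cutoff cutoff value (must be on the sweep grid).
#' @return One row of the sweep table.
#' @export
sweep_at <- function(sweep, cutoff) {
  i <- which(abs(sweep$table$cutoff - cutoff) < 1e-9)
  if (!length(i)) stop("cutoff ", cutoff, " is not on the sweep grid")
  sweep$table[i, , drop = FALSE]
}

#' ROC points of a Monte Carlo cutoff sweep
#'
#' One `(1 - specificity, sensitivity)` point per cutoff, ordered by cutoff.
#' All points lie (up to Monte Carlo standard error) inside the rectangle
#' bounded by the node-1 sensitivity ceiling and specificity floor.
#'
#' @param sweep a `dbs_mc_sweep`.
#' @return Data frame with `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(sweep) {
  stopifnot(inherits(sweep, "dbs_mc_sweep"))
  data.frame(cutoff = sweep$table$cutoff,
             fpr = 1 - sweep$table$spec_mean,
             tpr = sweep$table$sens_mean)
}
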