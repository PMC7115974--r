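# Independent brute-force oracles, written without reference to the package's
# split-search internals: plain double loops over every admissible candidate.

oracle_gini <- function(y) {
  n <- length(y)
  if (n == 0) return(0)
  p <- sum(y) / n
  1 - p^2 - (1 - p)^2
}

# Enumerate every admissible split of a small table and return them all with
# their weighted Gini decrease.
oracle_all_splits <- function(data, y, schema, min_leaf) {
  n <- length(y)
  parent <- oracle_gini(y)
  out <- list()
  for (f in names(data)) {
    v <- data[[f]]
    if (schema[[f]]$kind == "continuous") {
      vals <- sort(unique(v))
      if (length(vals) < 2) next
      for (i in seq_len(length(vals) - 1)) {
        thr <- (vals[i] + vals[i + 1]) / 2
        left <- v <= thr
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        gain <- parent - mean(left) * oracle_gini(y[left]) -
          mean(!left) * oracle_gini(y[!left])
        out[[length(out) + 1]] <- list(feature = f, threshold = thr,
                                       left_levels = NULL, gain = gain)
      }
    } else {
      lev <- schema[[f]]$levels
      obs <- lev[lev %in% v]
      m <- length(obs)
      if (m < 2) next
      for (code in seq_len(2^m - 2)) {
        sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
        left <- v %in% obs[sel]
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        gain <- parent - mean(left) * oracle_gini(y[left]) -
          mean(!left) * oracle_gini(y[!left])
        out[[length(out) + 1]] <- list(feature = f, threshold = NA_real_,
                                       left_levels = obs[sel], gain = gain)
      }
    }
  }
  out
}

oracle_best_gain <- function(data, y, schema, min_leaf) {
  cands <- oracle_all_splits(data, y, schema, min_leaf)
  if (!length(cands)) return(NA_real_)
  max(vapply(cands, function(c) c$gain, numeric(1)))
}

# Brute-force stump: select the admissible split maximizing weighted Gini
# decrease under the documented tie-breaks (feature order, then lowest
# threshold, then lexicographically smallest left level set), label both
# sides by majority vote (ties -> unfavorable), and return the predictions.
# NULL when no admissible split has positive gain.
oracle_stump_predictions <- function(data, y, schema, min_leaf) {
  best <- NULL
  for (f in names(data)) { # feature order = schema order
    for (cand in oracle_all_splits(data[f], y, schema, min_leaf)) {
      cand$key <- if (is.null(cand$left_levels)) "" else
        paste(cand$left_levels, collapse = ",")
      if (is.null(best) || cand$gain > best$gain + 1e-12) {
        best <- cand
      } else if (cand$gain > best$gain - 1e-12 && cand$feature == best$feature) {
        if (!is.null(cand$left_levels)) {
          if (cand$key < best$key) best <- cand
        } else if (cand$threshold < best$threshold) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(NULL)
  left <- if (is.null(best$left_levels)) {
    data[[best$feature]] <= best$threshold
  } else {
    data[[best$feature]] %in% best$left_levels
  }
  majority <- function(yy) if (sum(yy == 1) > sum(yy == 0)) 1L else 0L
  out <- integer(length(y))
  out[left] <- majority(y[left])
  out[!left] <- majority(y[!left])
  out
}
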