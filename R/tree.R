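# Binary classification-tree induction with native categorical splits.
# Continuous splits route value <= threshold left; categorical splits route
# value in left_levels left. Categorical partitions are enumerated exactly
# (2^(m-1) - 1 binary partitions of the observed levels), so no numeric
# re-encoding of categorical clinical features is ever needed.

#' Tree induction parameters
#'
#' @param min_leaf minimum number of patients in any leaf (both children of
#'   every split must reach this size). Default 10.
#' @param max_depth maximum tree depth (`Inf` = unlimited; a depth-1 tree is
#'   a single split).
#' @param impurity split criterion: Gini index (default, the standard CART
#'   choice) or entropy.
#' @param tie_label leaf label when class counts tie; the default 0
#'   (unfavorable) is the conservative prognosis.
#' @return An object of class `dbs_tree_params`.
#' @export
tree_params <- function(min_leaf = 10L, max_depth = Inf,
                        impurity = c("gini", "entropy"), tie_label = 0L) {
  impurity <- match.arg(impurity)
  stopifnot(min_leaf >= 1, max_depth >= 1, tie_label %in% c(0L, 1L))
  structure(list(min_leaf = as.integer(min_leaf), max_depth = max_depth,
                 impurity = impurity, tie_label = as.integer(tie_label)),
            class = "dbs_tree_params")
}

# Binary impurity from positive count and total, vectorized over candidates.
impurity_counts <- function(pos, n, type) {
  p <- ifelse(n > 0, pos / n, 0)
  q <- 1 - p
  if (type == "gini") {
    1 - p * p - q * q
  } else {
    xlx <- function(z) ifelse(z > 0, z * log2(z), 0)
    -(xlx(p) + xlx(q))
  }
}

GAIN_EPS <- 1e-12

#' Best admissible split of a set of labeled rows
#'
#' Maximizes the weighted impurity decrease over every admissible candidate:
#' for continuous features, midpoints between consecutive distinct sorted
#' values; for categorical features, every binary partition of the observed
#' levels. A split is admissible if both children contain at least
#' `params$min_leaf` rows. Ties in gain are broken deterministically: lowest
#' feature index in `x`, then lowest threshold, then lexicographically
#' smallest left level set.
#'
#' @param x data frame (or named list) of feature columns, in schema order.
#' @param y integer vector of binary labels (0/1).
#' @param schema feature schema covering the columns of `x`.
#' @param params a [tree_params()] object.
#' @return A split descriptor (list with `feature`, `kind`, `threshold` or
#'   `left_levels`/`seen_levels`, `gain`), or `NULL` when no admissible split
#'   has positive gain.
#' @export
best_split <- function(x, y, schema, params = tree_params()) {
  n <- length(y)
  if (n == 0) stop("best_split: empty input")
  feats <- names(x)
  tot_pos <- sum(y)
  parent_imp <- impurity_counts(tot_pos, n, params$impurity)
  min_leaf <- params$min_leaf

  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) { best <<- cand; return(invisible()) }
    if (cand$gain > best$gain + GAIN_EPS) { best <<- cand; return(invisible()) }
    if (cand$gain < best$gain - GAIN_EPS) return(invisible())
    if (cand$feat_index != best$feat_index) {
      if (cand$feat_index < best$feat_index) best <<- cand
      return(invisible())
    }
    if (cand$kind == "continuous_threshold") {
      if (cand$threshold < best$threshold) best <<- cand
    } else if (cand$key < best$key) {
      best <<- cand
    }
    invisible()
  }

  for (j in seq_along(feats)) {
    f <- feats[j]
    kind <- schema[[f]]$kind
    v <- x[[f]]
    if (kind == "continuous") {
      ord <- order(v)
      vs <- v[ord]
      cum_pos <- cumsum(y[ord])
      i <- seq_len(n - 1L)
      ok <- (vs[i] < vs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
      if (!any(ok)) next
      i <- i[ok]
      lp <- cum_pos[i]
      gain <- parent_imp -
        (i / n) * impurity_counts(lp, i, params$impurity) -
        ((n - i) / n) * impurity_counts(tot_pos - lp, n - i, params$impurity)
      # thresholds increase with i, so the first near-maximal gain has the
      # lowest threshold
      bi <- which(gain >= max(gain) - GAIN_EPS)[1L]
      consider(list(gain = gain[bi], feature = f, feat_index = j,
                    kind = "continuous_threshold",
                    threshold = (vs[i[bi]] + vs[i[bi] + 1L]) / 2))
    } else {
      lev <- schema[[f]]$levels
      obs <- lev[lev %in% unique(v)]
      m <- length(obs)
      if (m < 2L) next
      idx <- match(v, obs)
      n_l <- tabulate(idx, m)
      pos_l <- vapply(seq_len(m), function(l) sum(y[idx == l]), numeric(1))
      bits <- bitwShiftL(1L, seq_len(m) - 1L)
      for (code in seq_len(2L^m - 2L)) {
        sel <- bitwAnd(code, bits) > 0L
        nl <- sum(n_l[sel])
        if (nl < min_leaf || (n - nl) < min_leaf) next
        pl <- sum(pos_l[sel])
        gain <- parent_imp -
          (nl / n) * impurity_counts(pl, nl, params$impurity) -
          ((n - nl) / n) * impurity_counts(tot_pos - pl, n - nl, params$impurity)
        consider(list(gain = gain, feature = f, feat_index = j,
                      kind = "categorical_partition",
                      left_levels = obs[sel], seen_levels = obs,
                      key = paste(obs[sel], collapse = ",")))
      }
    }
  }
  if (!is.null(best) && best$gain > GAIN_EPS) {
    best$feat_index <- NULL
    best$key <- NULL
    best
  } else {
    NULL
  }
}

# Recursive greedy induction on a named list of columns (internal).
grow_tree <- function(x, y, schema, params, depth = 0L) {
  n <- length(y)
  pos <- sum(y)
  neg <- n - pos
  label <- if (pos > neg) 1L else if (pos < neg) 0L else params$tie_label
  leaf <- function() list(split = NULL, label = label, n = n,
                          counts = c(neg = neg, pos = pos), depth = depth)
  if (pos == 0L || neg == 0L || n < 2L * params$min_leaf ||
      depth >= params$max_depth) {
    return(leaf())
  }
  s <- best_split(x, y, schema, params)
  if (is.null(s)) return(leaf())
  go_left <- if (s$kind == "continuous_threshold") {
    x[[s$feature]] <= s$threshold
  } else {
    x[[s$feature]] %in% s$left_levels
  }
  list(split = s, label = label, n = n, counts = c(neg = neg, pos = pos),
       depth = depth,
       left = grow_tree(lapply(x, `[`, go_left), y[go_left], schema, params, depth + 1L),
       right = grow_tree(lapply(x, `[`, !go_left), y[!go_left], schema, params, depth + 1L))
}

#' Fit a binary classification tree to a cohort
#'
#' Greedy recursive partitioning with [best_split()] until a stopping rule
#' fires: node purity, node size below `2 * min_leaf`, maximum depth, or no
#' admissible split with positive gain. Leaves predict their majority class
#' (ties go to `params$tie_label`). Fitting is fully deterministic.
#'
#' @param cohort a `dbs_cohort` (or plain data frame, in which case `schema`
#'   must be supplied).
#' @param features character vector of feature names to use (defaults to the
#'   whole schema).
#' @param params a [tree_params()] object.
#' @param labels binary outcome labels; defaults to `cohort$labels`.
#' @param schema required when `cohort` is a plain data frame.
#' @return An object of class `dbs_tree`.
#' @export
fit_tree <- function(cohort, features = NULL, params = tree_params(),
                     labels = NULL, schema = NULL) {
  if (inherits(cohort, "dbs_cohort")) {
    schema <- cohort$schema
    data <- cohort$data
    labels <- labels %||% cohort$labels
  } else {
    data <- cohort
    if (is.null(schema)) stop("schema required when fitting from a data frame")
  }
  if (is.null(labels)) stop("labels missing: supply labels= or use set_outcome_labels()")
  features <- features %||% schema_features(schema)
  stopifnot(all(features %in% schema_features(schema)),
            all(features %in% names(data)))
  if (nrow(data) == 0) stop("cannot fit a tree to an empty cohort")
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(data), all(y %in% c(0L, 1L)))
  x <- lapply(data[features], identity)
  root <- grow_tree(x, y, schema, params)
  structure(list(root = root, features = features,
                 schema = schema[features], params = params),
            class = "dbs_tree")
}

# Vectorized routing on a named list of columns (internal).
route_tree <- function(root, x, n) {
  out <- integer(n)
  n_unseen <- 0L
  rec <- function(node, rows) {
    if (!length(rows)) return(invisible())
    if (is.null(node$split)) {
      out[rows] <<- node$label
      return(invisible())
    }
    s <- node$split
    v <- x[[s$feature]][rows]
    if (s$kind == "continuous_threshold") {
      if (anyNA(v)) stop("missing value for continuous feature '", s$feature, "'")
      left <- v <= s$threshold
    } else {
      known <- v %in% s$seen_levels
      left <- v %in% s$left_levels
      if (!all(known)) {
        # unseen categorical level: follow the majority child
        n_unseen <<- n_unseen + sum(!known)
        left[!known] <- node$left$n >= node$right$n
      }
    }
    rec(node$left, rows[left])
    rec(node$right, rows[!left])
  }
  rec(root, seq_len(n))
  if (n_unseen > 0L) {
    warning(n_unseen, " record(s) had a categorical level unseen at training; ",
            "routed with the majority child", call. = FALSE)
  }
  out
}

#' Predict prognosis labels with a fitted tree
#'
#' Deterministic root-to-leaf routing. Continuous values equal to a threshold
#' go left; the `"NA"` neurophysiology level is an ordinary categorical level;
#' a categorical level unseen at training is routed with the node's majority
#' child (with a warning).
#'
#' @param object a `dbs_tree`.
#' @param newdata a `dbs_cohort` or data frame providing every feature the
#'   tree tests.
#' @param ... unused.
#' @return Integer vector of predicted labels (1 = favorable prognosis).
#' @export
predict.dbs_tree <- function(object, newdata, ...) {
  data <- if (inherits(newdata, "dbs_cohort")) newdata$data else newdata
  missing_cols <- setdiff(object$features, names(data))
  if (length(missing_cols)) {
    stop("newdata is missing feature(s): ", paste(missing_cols, collapse = ", "))
  }
  route_tree(object$root, lapply(data[object$features], identity), nrow(data))
}

#' Depth and leaf count of a fitted tree
#'
#' @param tree a `dbs_tree`.
#' @return Integer; a single-leaf tree has depth 0.
#' @export
tree_depth <- function(tree) {
  rec <- function(node) {
    if (is.null(node$split)) return(0L)
    1L + max(rec(node$left), rec(node$right))
  }
  rec(tree$root)
}

#' @rdname tree_depth
#' @export
n_leaves <- function(tree) {
  rec <- function(node) {
    if (is.null(node$split)) return(1L)
    rec(node$left) + rec(node$right)
  }
  rec(tree$root)
}

#' @export
print.dbs_tree <- function(x, ...) {
  cat(sprintf("<dbs_tree> depth %d, %d leaves, trained on %d records\n",
              tree_depth(x), n_leaves(x), x$root$n))
  cat(format(tree_to_rules(x)), sep = "\n")
  invisible(x)
}

# Rule extraction -------------------------------------------------------------

#' Extract the leaves of a tree as conjunctive rules
#'
#' One rule per leaf, each a conjunction of the split conditions on the path
#' from the root. Applying the rules with [rules_predict()] reproduces
#' [predict.dbs_tree()] exactly on data whose categorical levels were seen at
#' training, which is the basis of the interpretability claim: the tree *is*
#' its rule list.
#'
#' @param tree a `dbs_tree`.
#' @return An object of class `dbs_rules`.
#' @export
tree_to_rules <- function(tree) {
  rules <- list()
  walk <- function(node, conds) {
    if (is.null(node$split)) {
      rules[[length(rules) + 1L]] <<- list(conditions = conds, label = node$label,
                                           n = node$n, counts = node$counts)
      return(invisible())
    }
    s <- node$split
    if (s$kind == "continuous_threshold") {
      walk(node$left, c(conds, list(list(feature = s$feature, op = "<=",
                                         value = s$threshold))))
      walk(node$right, c(conds, list(list(feature = s$feature, op = ">",
                                          value = s$threshold))))
    } else {
      walk(node$left, c(conds, list(list(feature = s$feature, op = "in",
                                         value = s$left_levels))))
      walk(node$right, c(conds, list(list(feature = s$feature, op = "in",
                                          value = setdiff(s$seen_levels, s$left_levels)))))
    }
  }
  walk(tree$root, list())
  structure(list(rules = rules, features = tree$features), class = "dbs_rules")
}

format_condition <- function(cond) {
  if (cond$op == "in") {
    sprintf("%s in {%s}", cond$feature, paste(cond$value, collapse = ", "))
  } else {
    sprintf("%s %s %s", cond$feature, cond$op, format(cond$value))
  }
}

#' @export
format.dbs_rules <- function(x, ...) {
  vapply(x$rules, function(r) {
    lhs <- if (length(r$conditions)) {
      paste(vapply(r$conditions, format_condition, character(1)), collapse = " AND ")
    } else {
      "TRUE"
    }
    sprintf("IF %s THEN %s  (n=%d: %d unfavorable / %d favorable)", lhs,
            if (r$label == 1L) "favorable" else "unfavorable",
            r$n, r$counts[["neg"]], r$counts[["pos"]])
  }, character(1))
}

#' @export
print.dbs_rules <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @rdname tree_to_rules
#' @param rules a `dbs_rules` object.
#' @param newdata a `dbs_cohort` or data frame.
#' @return `rules_predict()`: integer vector of labels; rows matching no rule
#'   (possible only with levels unseen at training) are `NA`.
#' @export
rules_predict <- function(rules, newdata) {
  data <- if (inherits(newdata, "dbs_cohort")) newdata$data else newdata
  n <- nrow(data)
  out <- rep(NA_integer_, n)
  for (r in rules$rules) {
    match_r <- rep(TRUE, n)
    for (cond in r$conditions) {
      v <- data[[cond$feature]]
      match_r <- match_r & switch(cond$op,
        "<=" = v <= cond$value,
        ">"  = v > cond$value,
        "in" = v %in% cond$value)
    }
    assign_rows <- match_r & is.na(out)
    out[assign_rows] <- r$label
  }
  out
}

# Serialization ---------------------------------------------------------------

#' Serialize a fitted tree to JSON text (and back)
#'
#' Nodes are flattened to a list in preorder; splits keep their descriptors
#' (feature, kind, threshold or level partition). `tree_from_json()` inverts
#' `tree_to_json()` exactly, so trees round-trip through plain text.
#'
#' @param tree a `dbs_tree`.
#' @param path optional file to write to.
#' @return `tree_to_json()`: JSON string (invisibly if `path` given);
#'   `tree_from_json()`: a `dbs_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- list()
  flatten <- function(node) {
    id <- length(nodes) + 1L
    rec <- list(id = id, leaf = is.null(node$split), label = node$label,
                n = node$n, counts = as.list(node$counts), depth = node$depth)
    nodes[[id]] <<- rec
    if (!is.null(node$split)) {
      s <- node$split
      rec$split <- list(feature = s$feature, kind = s$kind,
                        gain = s$gain,
                        threshold = s$threshold %||% NULL,
                        left_levels = as.list(s$left_levels %||% character(0)),
                        seen_levels = as.list(s$seen_levels %||% character(0)))
      rec$left_id <- flatten(node$left)
      rec$right_id <- flatten(node$right)
      nodes[[id]] <<- rec
    }
    id
  }
  flatten(tree$root)
  schema_json <- lapply(tree$schema, function(s) {
    list(kind = s$kind, levels = as.list(s$levels %||% character(0)))
  })
  params <- tree$params
  obj <- list(
    features = as.list(tree$features),
    schema = schema_json,
    params = list(min_leaf = params$min_leaf,
                  max_depth = if (is.finite(params$max_depth)) params$max_depth else NULL,
                  impurity = params$impurity, tie_label = params$tie_label),
    nodes = nodes
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname tree_to_json
#' @param json JSON string, or a file path to read from.
#' @export
tree_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  params <- tree_params(min_leaf = obj$params$min_leaf,
                        max_depth = obj$params$max_depth %||% Inf,
                        impurity = obj$params$impurity,
                        tie_label = as.integer(obj$params$tie_label))
  schema <- lapply(obj$schema, function(s) {
    list(kind = s$kind,
         levels = if (length(s$levels)) unlist(s$levels) else NULL)
  })
  class(schema) <- "dbs_schema"
  rebuild <- function(id) {
    nd <- obj$nodes[[id]]
    node <- list(split = NULL, label = as.integer(nd$label), n = as.integer(nd$n),
                 counts = c(neg = as.integer(nd$counts$neg),
                            pos = as.integer(nd$counts$pos)),
                 depth = as.integer(nd$depth))
    if (!isTRUE(nd$leaf)) {
      s <- nd$split
      node$split <- list(gain = s$gain, feature = s$feature, kind = s$kind)
      if (s$kind == "continuous_threshold") {
        node$split$threshold <- s$threshold
      } else {
        node$split$left_levels <- unlist(s$left_levels)
        node$split$seen_levels <- unlist(s$seen_levels)
      }
      node$left <- rebuild(nd$left_id)
      node$right <- rebuild(nd$right_id)
    }
    node
  }
  structure(list(root = rebuild(1L), features = unlist(obj$features),
                 schema = schema, params = params),
            class = "dbs_tree")
}
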