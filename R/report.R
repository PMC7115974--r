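# Pipeline orchestration: one named analysis per invocation, deterministic
# report files (delimited tables + JSON summaries + serialized trees) and a
# run manifest from which every stochastic output is reproducible.

#' Configuration for one analysis run
#'
#' Exactly one analysis is run per invocation:
#' \describe{
#'   \item{whole_cohort_20pct}{binarize at >= 20% improvement and search all
#'     feature subsets on the whole cohort.}
#'   \item{acquired_search}{restrict to acquired dystonia, binarize at the
#'     strict > `outcome_threshold` rule and search all 63 subsets.}
#'   \item{acquired_mc_sweep}{restrict to acquired dystonia with CMCT
#'     available and run the Monte Carlo severity-cutoff sweep.}
#'   \item{sep_fallback_search}{acquired dystonia with SEP available, CMCT
#'     dropped from the schema (31 subsets).}
#'   \item{table2_sweep}{outcome-threshold robustness sweep (0-5%).}
#' }
#'
#' @param analysis one of the five analysis names above.
#' @param seed master seed (mandatory; every stochastic stage derives its
#'   seed from it).
#' @param out_dir output directory (created if needed).
#' @param input path to a cohort file (mutually exclusive with `sim`).
#' @param sim a `dbs_sim_params` object to generate a synthetic cohort
#'   (mutually exclusive with `input`).
#' @param tree_params a [tree_params()] object.
#' @param k,iterations,top_n cross-validation search settings.
#' @param cutoff_step,n_sample,reps Monte Carlo sweep settings.
#' @param outcome_threshold,outcome_mode outcome binarization for the
#'   acquired analyses.
#' @return An object of class `dbs_run_config`.
#' @export
run_config <- function(analysis = c("whole_cohort_20pct", "acquired_search",
                                    "acquired_mc_sweep", "sep_fallback_search",
                                    "table2_sweep"),
                       seed, out_dir, input = NULL, sim = NULL,
                       tree_params = dbsdt::tree_params(), k = 10,
                       iterations = 100, top_n = 10,
                       cutoff_step = 0.5, n_sample = 100, reps = 1000,
                       outcome_threshold = 0,
                       outcome_mode = c("strict_gt", "ge")) {
  analysis <- match.arg(analysis)
  outcome_mode <- match.arg(outcome_mode)
  if (is.null(input) == is.null(sim)) {
    stop("supply exactly one of 'input' (cohort file) or 'sim' (simulation parameters)")
  }
  if (missing(seed)) stop("seed is mandatory")
  structure(list(analysis = analysis, seed = as.integer(seed),
                 out_dir = out_dir, input = input, sim = sim,
                 tree_params = tree_params, k = k, iterations = iterations,
                 top_n = top_n, cutoff_step = cutoff_step,
                 n_sample = n_sample, reps = reps,
                 outcome_threshold = outcome_threshold,
                 outcome_mode = outcome_mode),
            class = "dbs_run_config")
}

config_manifest <- function(config) {
  sim <- config$sim
  list(package = "dbsdt",
       version = as.character(utils::packageVersion("dbsdt")),
       analysis = config$analysis,
       seed = config$seed,
       input = config$input,
       sim = if (!is.null(sim)) unclass(sim),
       tree_params = unclass(config$tree_params)[c("min_leaf", "impurity", "tie_label")],
       max_depth = if (is.finite(config$tree_params$max_depth))
         config$tree_params$max_depth,
       k = config$k, iterations = config$iterations, top_n = config$top_n,
       cutoff_step = config$cutoff_step, n_sample = config$n_sample,
       reps = config$reps,
       outcome_threshold = config$outcome_threshold,
       outcome_mode = config$outcome_mode)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

write_table_file <- function(df, path) {
  # deterministic dialect: fixed formatting, no quoting, \n line endings
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) {
      fmt[[j]] <- vapply(fmt[[j]], function(x) {
        if (is.na(x)) "" else format(x, scientific = FALSE, digits = 15, trim = TRUE)
      }, character(1))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(fmt), collapse = ","), con, sep = "\n")
  if (nrow(fmt)) {
    writeLines(do.call(paste, c(unname(as.list(fmt)), sep = ",")), con, sep = "\n")
  }
  invisible(path)
}

search_outputs <- function(search, cohort, labels, config, out_dir, prefix) {
  write_table_file(search$results, file.path(out_dir, paste0(prefix, "_table.csv")))
  top_subset <- search$subsets[[search$top$subset_index[1]]]
  tree <- fit_tree(cohort, features = top_subset, params = config$tree_params,
                   labels = labels)
  tree_to_json(tree, file.path(out_dir, paste0(prefix, "_top_tree.json")))
  writeLines(format(tree_to_rules(tree)),
             file.path(out_dir, paste0(prefix, "_top_rules.txt")))
  write_json_file(list(baseline = search$baseline,
                       top_subsets = search$top$subset_index,
                       top_accuracy = search$top$mean_accuracy,
                       feature_frequency = as.list(search$feature_frequency)),
                  file.path(out_dir, paste0(prefix, "_summary.json")))
  search
}

#' Run one configured analysis and write its report files
#'
#' Loads or generates the cohort, runs the configured pipeline stage, and
#' writes delimited result tables, JSON summaries, the top-ranked tree (JSON
#' + rule text where applicable) and a run manifest (`manifest.json`:
#' configuration + seed + package version). Identical configurations produce
#' byte-identical outputs.
#'
#' @param config a [run_config()] object.
#' @return Invisibly, a list with the loaded cohort, the stage result and the
#'   paths of the files written.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "dbs_run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    generate_cohort(config$sim, seed = derive_seed(config$seed, 1))
  }
  tp <- config$tree_params
  result <- switch(config$analysis,
    whole_cohort_20pct = {
      labeled <- set_outcome_labels(cohort, threshold = 20, mode = "ge")
      s <- run_search(labeled, params = tp, k = config$k,
                      iterations = config$iterations,
                      seed = derive_seed(config$seed, 2), top_n = config$top_n)
      search_outputs(s, labeled, labeled$labels, config, out_dir, "whole_cohort_20pct")
    },
    acquired_search = {
      acq <- filter_etiology(cohort, acquired_levels())
      labeled <- set_outcome_labels(acq, threshold = config$outcome_threshold,
                                    mode = config$outcome_mode)
      s <- run_search(labeled, params = tp, k = config$k,
                      iterations = config$iterations,
                      seed = derive_seed(config$seed, 3), top_n = config$top_n)
      search_outputs(s, labeled, labeled$labels, config, out_dir, "acquired_search")
    },
    sep_fallback_search = {
      acq <- filter_etiology(cohort, acquired_levels())
      pool <- filter_feature_available(acq, "sep")
      labeled <- set_outcome_labels(pool, threshold = config$outcome_threshold,
                                    mode = config$outcome_mode)
      feats <- setdiff(schema_features(labeled$schema), "cmct")
      s <- run_search(labeled, features = feats, params = tp, k = config$k,
                      iterations = config$iterations,
                      seed = derive_seed(config$seed, 4), top_n = config$top_n)
      search_outputs(s, labeled, labeled$labels, config, out_dir, "sep_fallback_search")
    },
    acquired_mc_sweep = {
      acq <- filter_etiology(cohort, acquired_levels())
      pool <- filter_feature_available(acq, "cmct")
      labeled <- set_outcome_labels(pool, threshold = config$outcome_threshold,
                                    mode = config$outcome_mode)
      sw <- mc_threshold_sweep(labeled, cutoff_step = config$cutoff_step,
                               n_sample = config$n_sample, reps = config$reps,
                               seed = derive_seed(config$seed, 5))
      write_table_file(sw$table, file.path(out_dir, "mc_sweep_table.csv"))
      write_table_file(roc_points(sw), file.path(out_dir, "mc_sweep_roc.csv"))
      write_json_file(list(sens_upper_bound = sw$sens_upper_bound,
                           spec_lower_bound = sw$spec_lower_bound,
                           n_pool = sw$n_pool, n_sample = sw$n_sample,
                           reps = sw$reps,
                           bounds_respected = sw$bounds_respected,
                           n_undefined_sens = sum(sw$n_undefined_sens),
                           n_undefined_spec = sum(sw$n_undefined_spec)),
                      file.path(out_dir, "mc_sweep_summary.json"))
      sw
    },
    table2_sweep = {
      acq <- filter_etiology(cohort, acquired_levels())
      sw <- outcome_threshold_sweep(acq, thresholds = 0:5,
                                    mode = config$outcome_mode,
                                    params = tp, k = config$k,
                                    iterations = config$iterations,
                                    seed = derive_seed(config$seed, 6),
                                    top_n = config$top_n)
      write_table_file(sw$summary, file.path(out_dir, "threshold_sweep_table.csv"))
      sw
    }
  )
  write_json_file(config_manifest(config), file.path(out_dir, "manifest.json"))
  invisible(list(cohort = cohort, result = result,
                 files = list.files(out_dir, full.names = TRUE)))
}

#' Render the combined two-level decision-support document
#'
#' Assembles the counseling tool: an etiology gate first (genetic/idiopathic
#' dystonia carries a favorable DBS prognosis), then -- for acquired dystonia
#' -- the neurophysiology gate from the feature search (CMCT, or SEP when
#' CMCT is unavailable) with the baseline-severity cutoff table from the
#' Monte Carlo sweep, so a family and clinician can pick the operating point
#' whose sensitivity/specificity trade-off matches their preferences.
#'
#' @param search a `dbs_search` from the acquired-dystonia subset search
#'   (optional if `sweep` is given).
#' @param sweep a `dbs_mc_sweep` (optional if `search` is given).
#' @param cutoffs severity cutoffs to tabulate (default: every 10th grid
#'   point of the sweep).
#' @return Character vector of document lines (class `dbs_decision_tool`).
#' @export
render_decision_tool <- function(search = NULL, sweep = NULL, cutoffs = NULL) {
  if (is.null(search) && is.null(sweep)) {
    stop("at least one of 'search' or 'sweep' is required")
  }
  if (!is.null(search) && nrow(search$results) == 0) {
    stop("empty search report")
  }
  lines <- c("DBS prognosis decision support",
             "==============================",
             "",
             "Gate 1 - etiology:",
             "  isolated or complex genetic/idiopathic dystonia -> favorable prognosis",
             "  acquired dystonia -> continue to gate 2",
             "")
  if (!is.null(search)) {
    freq <- sort(search$feature_frequency, decreasing = TRUE)
    gate2 <- names(freq)[1]
    lines <- c(lines,
               sprintf("Gate 2 - from the feature-subset search (baseline accuracy %.4f):",
                       search$baseline),
               sprintf("  features in top-%d models: %s", search$top_n,
                       paste(sprintf("%s (%d/%d)", names(freq), freq, search$top_n),
                             collapse = ", ")),
               sprintf("  primary discriminator: %s", gate2),
               if (gate2 == "cmct") {
                 c("  CMCT abnormal -> less favorable prognosis",
                   "  CMCT normal   -> assess baseline severity (gate 3)")
               } else if (gate2 == "sep") {
                 c("  SEP abnormal -> less favorable prognosis",
                   "  SEP normal   -> more favorable prognosis")
               },
               "")
  }
  if (!is.null(sweep)) {
    tab <- sweep$table
    if (is.null(cutoffs)) {
      cutoffs <- tab$cutoff[seq(1, nrow(tab), by = max(1L, nrow(tab) %/% 10))]
    }
    rows <- tab[tab$cutoff %in% cutoffs, , drop = FALSE]
    lines <- c(lines,
               "Gate 3 - baseline BFMDRS-m cutoff (favorable iff score > cutoff):",
               sprintf("  node-1 bounds: sensitivity <= %.4f, specificity >= %.4f",
                       sweep$sens_upper_bound, sweep$spec_lower_bound),
               sprintf("  %8s  %18s  %18s", "cutoff", "sensitivity (SE)", "specificity (SE)"),
               sprintf("  %8.1f  %10.4f (%.4f)  %10.4f (%.4f)",
                       rows$cutoff, rows$sens_mean, rows$sens_se,
                       rows$spec_mean, rows$spec_se),
               "",
               "  A cutoff further left favors sensitivity (not missing a possible",
               "  benefit); further right favors specificity (more certainty that a",
               "  predicted benefit is real).")
  }
  structure(lines, class = c("dbs_decision_tool", "character"))
}

#' @export
print.dbs_decision_tool <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
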