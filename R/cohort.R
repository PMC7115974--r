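# Cohort data model: per-patient clinical features, limb-level neurophysiology
# coding, outcome computation/binarization, file I/O and filtering.

#' Feature levels used by the cohort schema
#'
#' Etiology follows the six-group classification used at referral: two
#' idiopathic/genetic groups (isolated, complex) and four acquired groups
#' (cerebral palsy, metabolic, other, degenerative). CMCT and SEP carry a
#' patient-level status of `"normal"`, `"abnormal"` or the literal level
#' `"NA"` (no satisfactory recording), which is a first-class categorical
#' level throughout the analyses, not a missing value.
#'
#' @return Character vector of levels.
#' @export
etiology_levels <- function() {
  c("isolated_genetic", "complex_genetic", "acquired_cp",
    "acquired_metabolic", "acquired_other", "acquired_degenerative")
}

#' @rdname etiology_levels
#' @export
acquired_levels <- function() etiology_levels()[3:6]

#' @rdname etiology_levels
#' @export
neurophys_levels <- function() c("normal", "abnormal", "NA")

#' @rdname etiology_levels
#' @export
limb_levels <- function() c("normal", "abnormal", "unsatisfactory")

#' Default feature schema for a dystonia DBS cohort
#'
#' The schema is an ordered list of the six candidate prognostic features:
#' sex, etiology, baseline severity (BFMDRS-m motor score, 0-120, continuous),
#' cranial MRI class, CMCT status and SEP status. Each entry records the
#' feature kind (`"categorical"` or `"continuous"`) and, for categorical
#' features, its admissible levels. MRI is an opaque categorical label whose
#' levels can be redefined by the user.
#'
#' @param mri_levels levels for the cranial MRI feature.
#' @return An object of class `dbs_schema` (named list of feature descriptors).
#' @examples
#' names(default_schema())
#' @export
default_schema <- function(mri_levels = c("normal", "abnormal")) {
  stopifnot(is.character(mri_levels), length(mri_levels) >= 2)
  structure(list(
    sex          = list(kind = "categorical", levels = c("M", "F")),
    etiology     = list(kind = "categorical", levels = etiology_levels()),
    baseline_bfm = list(kind = "continuous",  levels = NULL),
    mri          = list(kind = "categorical", levels = mri_levels),
    cmct         = list(kind = "categorical", levels = neurophys_levels()),
    sep          = list(kind = "categorical", levels = neurophys_levels())
  ), class = "dbs_schema")
}

#' @rdname default_schema
#' @param schema a `dbs_schema`.
#' @export
schema_features <- function(schema) names(schema)

numeric_columns <- function() c("baseline_bfm", "followup_bfm", "pct_change", "copm_change")
limb_columns <- function(feature) paste0(feature, "_limb", 1:4)

#' Construct a validated cohort
#'
#' A cohort bundles a per-patient data frame, the feature schema and
#' (optionally) binary outcome labels. The data frame must contain an `id`
#' column and every schema feature; `followup_bfm`, `pct_change`,
#' `copm_change` and limb-level columns (`cmct_limb1..4`, `sep_limb1..4`) are
#' optional. Where `pct_change` is absent or missing it is completed from
#' baseline and follow-up BFMDRS-m scores.
#'
#' @param data data frame of patient records.
#' @param schema feature schema, see [default_schema()].
#' @param labels optional integer vector of binary outcomes (0/1), aligned
#'   1:1 with rows of `data`.
#' @param validate run invariant checks (range, levels, limb consistency).
#' @return An object of class `dbs_cohort`: a list with elements `data`,
#'   `schema`, `labels`.
#' @export
new_cohort <- function(data, schema = default_schema(), labels = NULL, validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rownames(data) <- NULL
  for (col in numeric_columns()) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  # complete % improvement from scores where possible
  need <- is.na(data$pct_change) & !is.na(data$baseline_bfm) & !is.na(data$followup_bfm)
  if (any(need)) {
    data$pct_change[need] <- percent_improvement(data$baseline_bfm[need],
                                                 data$followup_bfm[need])
  }
  obj <- structure(list(data = data, schema = schema, labels = labels),
                   class = "dbs_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' @rdname new_cohort
#' @param cohort a `dbs_cohort`.
#' @export
validate_cohort <- function(cohort) {
  data <- cohort$data
  schema <- cohort$schema
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)

  required <- c("id", schema_features(schema))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(data$id)) add("duplicated patient id(s)")

  for (f in schema_features(schema)) {
    spec <- schema[[f]]
    v <- data[[f]]
    if (spec$kind == "continuous") {
      v <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v))
      for (i in bad) add(sprintf("row %d: %s is missing or non-numeric", i, f))
      if (f == "baseline_bfm") {
        out <- which(!is.na(v) & (v < 0 | v > 120))
        for (i in out) add(sprintf("row %d: baseline_bfm = %s out of range [0, 120]", i, format(v[i])))
      }
    } else {
      bad <- which(is.na(v) | !(v %in% spec$levels))
      for (i in bad) {
        add(sprintf("row %d: %s = '%s' is not one of {%s}", i, f,
                    if (is.na(v[i])) "" else v[i], paste(spec$levels, collapse = ", ")))
      }
    }
  }
  fb <- data$followup_bfm
  out <- which(!is.na(fb) & (fb < 0 | fb > 120))
  for (i in out) add(sprintf("row %d: followup_bfm = %s out of range [0, 120]", i, format(fb[i])))

  # limb-level consistency: patient-level status must equal the coded limbs
  for (f in c("cmct", "sep")) {
    cols <- limb_columns(f)
    if (all(cols %in% names(data))) {
      for (i in seq_len(nrow(data))) {
        limbs <- unlist(data[i, cols], use.names = FALSE)
        limbs <- limbs[!is.na(limbs) & limbs != ""]
        if (length(limbs) == 0) next # limb data not recorded for this patient
        if (!all(limbs %in% limb_levels())) {
          add(sprintf("row %d: invalid %s limb status", i, f))
        } else if (code_limb_status(limbs) != data[[f]][i]) {
          add(sprintf("row %d: %s = '%s' inconsistent with limb-level coding '%s'",
                      i, f, data[[f]][i], code_limb_status(limbs)))
        }
      }
    }
  }
  if (!is.null(cohort$labels)) {
    if (length(cohort$labels) != nrow(data)) {
      add(sprintf("labels length %d does not match %d records",
                  length(cohort$labels), nrow(data)))
    } else if (!all(cohort$labels %in% c(0L, 1L))) {
      add("labels must be binary (0/1)")
    }
  }
  if (length(problems)) {
    shown <- utils::head(problems, 10L)
    stop("invalid cohort (", length(problems), " problem(s)):\n  ",
         paste(shown, collapse = "\n  "),
         if (length(problems) > 10L) "\n  ..." else "", call. = FALSE)
  }
  invisible(cohort)
}

#' @rdname new_cohort
#' @export
n_patients <- function(cohort) nrow(cohort$data)

#' @export
print.dbs_cohort <- function(x, ...) {
  cat(sprintf("<dbs_cohort> %d patients, %d features (%s)%s\n",
              n_patients(x), length(x$schema),
              paste(schema_features(x$schema), collapse = ", "),
              if (is.null(x$labels)) "" else
                sprintf("; labels: %d positive / %d negative",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

# Row subset preserving schema, labels and limb columns.
cohort_subset <- function(cohort, keep) {
  new_cohort(cohort$data[keep, , drop = FALSE], cohort$schema,
             labels = if (is.null(cohort$labels)) NULL else cohort$labels[keep],
             validate = FALSE)
}

#' Code limb-level neurophysiology recordings to a patient-level status
#'
#' Up to four limbs are tested per patient (CMCT or SEP). The patient is
#' `"abnormal"` if one or more limbs are abnormal; `"NA"` if no limb gave a
#' satisfactory recording (technically unsatisfactory traces are excluded
#' from interpretation); `"normal"` otherwise, i.e. at least one satisfactory
#' limb and none abnormal.
#'
#' @param limbs character vector (length 0-4) with entries from
#'   [limb_levels()]; `NA`/empty entries denote limbs that were not tested
#'   and are dropped.
#' @return One of `"normal"`, `"abnormal"`, `"NA"`.
#' @examples
#' code_limb_status(c("abnormal", "normal", "normal", "unsatisfactory"))
#' code_limb_status(c("unsatisfactory", "unsatisfactory"))
#' @export
code_limb_status <- function(limbs) {
  limbs <- limbs[!is.na(limbs) & limbs != ""]
  if (length(limbs) > 4) stop("at most 4 limb recordings per patient")
  if (!all(limbs %in% limb_levels())) {
    stop("limb status must be one of: ", paste(limb_levels(), collapse = ", "))
  }
  if (any(limbs == "abnormal")) return("abnormal")
  if (any(limbs == "normal")) return("normal")
  "NA"
}

#' Percentage improvement in BFMDRS-m from baseline to follow-up
#'
#' `100 * (baseline - followup) / baseline`; positive values mean the
#' dystonia score fell (improvement), negative values mean worsening.
#'
#' @param baseline,followup BFMDRS-m motor scores in `[0, 120]`; vectorized.
#' @return Numeric vector of percentage changes.
#' @examples
#' percent_improvement(100, 80) # 20
#' percent_improvement(50, 60)  # -20
#' @export
percent_improvement <- function(baseline, followup) {
  if (any(!is.na(baseline) & baseline <= 0)) {
    stop("percentage improvement is undefined for baseline <= 0")
  }
  100 * (baseline - followup) / baseline
}

#' Binarize a percentage-improvement outcome at a threshold
#'
#' Two comparison modes reflect the two outcome definitions in use: strictly
#' greater (`"strict_gt"`, e.g. any improvement means `> 0%` change) and
#' greater-or-equal (`"ge"`, e.g. the literature cutoff of `>= 20%` change).
#'
#' @param pct percentage change(s) in BFMDRS-m.
#' @param threshold threshold in percent.
#' @param mode `"strict_gt"` or `"ge"`.
#' @return Integer vector of labels (1 = positive/favorable outcome).
#' @examples
#' binarize_outcome(0, 0, "strict_gt")  # 0
#' binarize_outcome(20, 20, "ge")       # 1
#' @export
binarize_outcome <- function(pct, threshold = 0, mode = c("strict_gt", "ge")) {
  mode <- match.arg(mode)
  out <- if (mode == "strict_gt") pct > threshold else pct >= threshold
  as.integer(out)
}

#' Binarize a COPM change score
#'
#' A change of at least 2 points on the Canadian Occupational Performance
#' Measure is considered clinically significant; the boundary is inclusive.
#'
#' @param copm_change COPM change score(s); must be present (no `NA`).
#' @param threshold clinical-significance threshold (default 2).
#' @return Integer vector of labels (1 = clinically significant improvement).
#' @export
binarize_copm <- function(copm_change, threshold = 2) {
  if (anyNA(copm_change)) stop("copm_change contains missing values")
  as.integer(copm_change >= threshold)
}

#' Restrict a cohort to selected etiology groups
#'
#' @param cohort a `dbs_cohort`.
#' @param groups non-empty character vector of etiology levels, e.g.
#'   [acquired_levels()] for the acquired-dystonia subcohort.
#' @return The subcohort, record order preserved.
#' @export
filter_etiology <- function(cohort, groups) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  if (length(groups) == 0) stop("groups must be non-empty")
  unknown <- setdiff(groups, cohort$schema$etiology$levels)
  if (length(unknown)) {
    stop("unknown etiology group(s): ", paste(unknown, collapse = ", "))
  }
  cohort_subset(cohort, cohort$data$etiology %in% groups)
}

#' Drop records whose neurophysiology status is unavailable
#'
#' Removes patients whose patient-level status for `feature` is the `"NA"`
#' level (no satisfactory recording), e.g. to form the CMCT-available pool
#' used by the Monte Carlo cutoff sweep.
#'
#' @param cohort a `dbs_cohort`.
#' @param feature `"cmct"` or `"sep"`.
#' @return The subcohort with available recordings only.
#' @export
filter_feature_available <- function(cohort, feature) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  if (!feature %in% names(cohort$schema) ||
      !identical(cohort$schema[[feature]]$levels, neurophys_levels())) {
    stop("'", feature, "' is not a neurophysiology status feature of this schema")
  }
  cohort_subset(cohort, cohort$data[[feature]] != "NA")
}

#' Attach binary outcome labels derived from the stored percentage change
#'
#' @param cohort a `dbs_cohort` with `pct_change` present for all records.
#' @inheritParams binarize_outcome
#' @return The cohort with `labels` set.
#' @export
set_outcome_labels <- function(cohort, threshold = 0, mode = c("strict_gt", "ge")) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  pct <- cohort$data$pct_change
  if (anyNA(pct)) {
    stop("pct_change missing for ", sum(is.na(pct)),
         " record(s); cannot derive outcome labels")
  }
  cohort$labels <- binarize_outcome(pct, threshold, mode)
  cohort
}

# File I/O --------------------------------------------------------------------

cohort_column_order <- function(data) {
  known <- c("id", "sex", "etiology", "mri", "baseline_bfm", "followup_bfm",
             "pct_change", "copm_change", "cmct", "sep",
             limb_columns("cmct"), limb_columns("sep"))
  c(intersect(known, names(data)), setdiff(names(data), known))
}

#' Read a cohort from a delimited text file
#'
#' Expects a UTF-8 delimited file with a header row and one row per patient.
#' Missing numeric values may be written as the empty string or `NA`; the
#' CMCT/SEP columns use the literal level `"NA"` for "not available". If
#' limb-level columns (`cmct_limb1..4`, `sep_limb1..4`) are present and a
#' patient-level status is empty it is derived via [code_limb_status()];
#' when both are present they must agree. Invalid rows are rejected with
#' row-indexed diagnostics.
#'
#' @param path file path.
#' @param schema feature schema, see [default_schema()].
#' @param delim field delimiter (default comma).
#' @return A validated `dbs_cohort`.
#' @seealso [write_cohort()] for the exact dialect emitted (round-trip safe).
#' @export
read_cohort <- function(path, schema = default_schema(), delim = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, strip.white = TRUE,
                           fileEncoding = "UTF-8")
  required <- c("id", setdiff(schema_features(schema), c("cmct", "sep")))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  data <- raw
  for (col in intersect(c("baseline_bfm", numeric_columns()), names(data))) {
    v <- data[[col]]
    v[v %in% c("", "NA")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("row ", bad[1], ": non-numeric value '", v[bad[1]], "' in column ", col)
    }
    data[[col]] <- num
  }
  # derive patient-level neurophysiology status from limb columns when absent
  for (f in c("cmct", "sep")) {
    cols <- limb_columns(f)
    has_limbs <- all(cols %in% names(data))
    if (!f %in% names(data)) data[[f]] <- NA_character_
    data[[f]][data[[f]] == ""] <- NA_character_
    if (has_limbs) {
      for (i in which(is.na(data[[f]]))) {
        limbs <- unlist(data[i, cols], use.names = FALSE)
        data[[f]][i] <- code_limb_status(limbs)
      }
    }
    if (anyNA(data[[f]])) {
      stop("row ", which(is.na(data[[f]]))[1], ": column ", f,
           " is empty and no limb-level columns are available")
    }
  }
  new_cohort(data, schema)
}

#' Write a cohort to a delimited text file
#'
#' Emits the same dialect [read_cohort()] parses, deterministically: fixed
#' column order, missing values as empty strings, no quoting, `\n` line
#' endings. Writing the same cohort twice produces byte-identical files.
#'
#' @param cohort a `dbs_cohort`.
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(inherits(cohort, "dbs_cohort"))
  data <- cohort$data[, cohort_column_order(cohort$data), drop = FALSE]
  fmt <- vapply(seq_along(data), function(j) {
    v <- data[[j]]
    if (is.numeric(v)) {
      ifelse(is.na(v), "", vapply(v, function(x) {
        if (is.na(x)) "" else format(x, scientific = FALSE, digits = 15, trim = TRUE)
      }, character(1)))
    } else {
      ifelse(is.na(v), "", as.character(v))
    }
  }, character(nrow(data))) |> matrix(nrow = nrow(data))
  out <- as.data.frame(fmt, stringsAsFactors = FALSE)
  names(out) <- names(data)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = delim), con, sep = "\n")
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = delim)), con, sep = "\n")
  }
  invisible(path)
}
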