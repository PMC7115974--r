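# Programmatic fixtures: small cohorts built in code.

# A tiny schema with one continuous and one 3-level categorical feature, for
# split-oracle tests.
toy_schema <- function() {
  structure(list(
    xnum = list(kind = "continuous", levels = NULL),
    xcat = list(kind = "categorical", levels = c("a", "b", "c"))
  ), class = "dbs_schema")
}

random_toy_table <- function(n = 30) {
  data.frame(xnum = round(runif(n, 0, 10), 1),
             xcat = sample(c("a", "b", "c"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Deterministic hand-built cohort of n patients with prescribed columns.
make_cohort <- function(n = 12, etiology = NULL, cmct = NULL, sep = NULL,
                        baseline = NULL, pct = NULL) {
  etiology <- etiology %||% rep_len(etiology_levels(), n)
  data <- data.frame(
    id = sprintf("T%03d", seq_len(n)),
    sex = rep_len(c("M", "F"), n),
    etiology = rep_len(etiology, n),
    mri = rep_len(c("normal", "abnormal"), n),
    baseline_bfm = baseline %||% rep_len(seq(20, 110, by = 10), n),
    cmct = rep_len(cmct %||% "normal", n),
    sep = rep_len(sep %||% "normal", n),
    stringsAsFactors = FALSE
  )
  data$pct_change <- rep_len(pct %||% rep(c(30, -10), length.out = n), n)
  data$followup_bfm <- round(pmin(pmax(
    data$baseline_bfm * (1 - data$pct_change / 100), 0), 120) * 2) / 2
  data$pct_change <- percent_improvement(data$baseline_bfm, data$followup_bfm)
  new_cohort(data, default_schema())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free cohort whose outcome is exactly the fixed CMCT + severity tree
# at cutoff s0: favorable iff CMCT normal and baseline > s0.
oracle_fixed_tree_cohort <- function(n = 78, s0 = 80, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    baseline <- sample(seq(30, 115, by = 0.5), n, replace = TRUE)
    cmct <- sample(c("normal", "abnormal"), n, replace = TRUE, prob = c(0.7, 0.3))
    labels <- as.integer(cmct == "normal" & baseline > s0)
    cohort <- make_cohort(n, etiology = "acquired_cp", cmct = cmct,
                          baseline = baseline)
    cohort$data$cmct <- cmct
    cohort$labels <- labels
    cohort
  })
}
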