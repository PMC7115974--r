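test_that("a perfectly separating binary feature is found with full gain", {
  schema <- structure(list(xbin = list(kind = "categorical", levels = c("lo", "hi"))),
                      class = "dbs_schema")
  x <- data.frame(xbin = rep(c("lo", "hi"), each = 10), stringsAsFactors = FALSE)
  y <- rep(c(0L, 1L), each = 10)
  s <- best_split(x, y, schema, tree_params(min_leaf = 5))
  expect_equal(s$feature, "xbin")
  expect_equal(s$gain, 0.5) # parent Gini 0.5, children pure
  expect_null(best_split(x, rep(1L, 20), schema, tree_params(min_leaf = 5)))
})

test_that("best_split matches exhaustive enumeration on random tables", {
  set.seed(101)
  schema <- toy_schema()
  params <- tree_params(min_leaf = 5)
  for (i in 1:200) {
    data <- random_toy_table(30)
    y <- sample(0:1, 30, replace = TRUE)
    cands <- oracle_all_splits(data, y, schema, 5)
    oracle_gain <- if (length(cands)) max(vapply(cands, `[[`, numeric(1), "gain")) else -Inf
    s <- best_split(data, y, schema, params)
    if (is.null(s)) {
      expect_lte(oracle_gain, 1e-12)
    } else {
      expect_equal(s$gain, oracle_gain, tolerance = 1e-10)
      # the chosen split must be one of the oracle's argmax candidates
      argmax <- Filter(function(c) abs(c$gain - oracle_gain) < 1e-10, cands)
      hit <- any(vapply(argmax, function(c) {
        c$feature == s$feature &&
          (if (is.null(c$left_levels)) isTRUE(all.equal(c$threshold, s$threshold))
           else setequal(c$left_levels, s$left_levels) ||
                setequal(c$left_levels, setdiff(s$seen_levels, s$left_levels)))
      }, logical(1)))
      expect_true(hit)
    }
  }
})

test_that("depth-1 fits equal the brute-force stump search", {
  set.seed(202)
  schema <- toy_schema()
  params <- tree_params(min_leaf = 5, max_depth = 1)
  for (i in 1:50) {
    data <- random_toy_table(40)
    y <- as.integer(data$xnum + 3 * (data$xcat == "b") + rnorm(40, 0, 3) > 6)
    if (length(unique(y)) < 2) next
    tree <- fit_tree(data, params = params, labels = y, schema = schema)
    oracle <- oracle_stump_predictions(data, y, schema, 5)
    if (is.null(oracle)) {
      expect_null(tree$root$split)
    } else {
      expect_equal(predict(tree, data), oracle)
    }
  }
})

test_that("min_leaf >= n forces a single majority leaf", {
  cohort <- make_cohort(12, pct = c(rep(30, 7), rep(-10, 5)))
  cohort <- set_outcome_labels(cohort)
  tree <- fit_tree(cohort, params = tree_params(min_leaf = 12))
  expect_null(tree$root$split)
  expect_equal(tree$root$label, 1L)
  expect_equal(predict(tree, cohort), rep(1L, 12))
})

test_that("planted single-feature structure is recovered as a depth-1 tree", {
  set.seed(303)
  cohort <- generate_cohort(sim_params(n = 200, p_cmct_na = 0), seed = 9)
  labels <- as.integer(cohort$data$cmct == "normal")
  tree <- fit_tree(cohort, params = tree_params(min_leaf = 10), labels = labels)
  expect_equal(tree_depth(tree), 1L)
  expect_equal(tree$root$split$feature, "cmct")
  expect_equal(mean(predict(tree, cohort) == labels), 1.0)
})

test_that("XOR-like structure needs depth 2 and is fit exactly", {
  # class-balanced interaction (20/20) with unequal cell sizes so the root
  # split has positive impurity gain (with exactly equal cells every split
  # has zero Gini gain and a greedy positive-gain learner correctly stalls)
  xo <- data.frame(
    xnum = rep(c(1, 1, 9, 9), c(12, 8, 12, 8)),
    xcat = rep(c("a", "b", "a", "b"), c(12, 8, 12, 8)),
    stringsAsFactors = FALSE
  )
  y <- as.integer(xor(xo$xnum > 5, xo$xcat == "b"))
  stopifnot(sum(y) == 20)
  tree <- fit_tree(xo, params = tree_params(min_leaf = 5), labels = y,
                   schema = toy_schema())
  expect_equal(mean(predict(tree, xo) == y), 1.0)
  expect_gte(tree_depth(tree), 2L)
  # brute force: no depth-1 tree separates an interaction perfectly
  stump <- oracle_stump_predictions(xo, y, toy_schema(), 5)
  expect_lt(mean(stump == y), 1.0)
})

test_that("training accuracy never falls below the majority proportion", {
  set.seed(404)
  for (i in 1:20) {
    cohort <- generate_cohort(sim_params(n = 80), seed = 500 + i)
    tree <- fit_tree(cohort, params = tree_params(min_leaf = 10))
    acc <- mean(predict(tree, cohort) == cohort$labels)
    expect_gte(acc, majority_class_accuracy(cohort$labels))
  }
})

test_that("fitting is deterministic and leaf sizes respect min_leaf", {
  cohort <- generate_cohort(sim_params(n = 150), seed = 77)
  t1 <- fit_tree(cohort, params = tree_params(min_leaf = 10))
  t2 <- fit_tree(cohort, params = tree_params(min_leaf = 10))
  expect_identical(t1, t2)
  check <- function(node) {
    expect_equal(node$n, sum(node$counts))
    if (is.null(node$split)) {
      expect_gte(node$n, 10)
    } else {
      expect_equal(unname(node$counts),
                   unname(node$left$counts + node$right$counts))
      check(node$left); check(node$right)
    }
  }
  check(t1$root)
})

test_that("single-leaf prediction and unseen-level routing behave", {
  cohort <- oracle_fixed_tree_cohort(n = 100, s0 = 80)
  # single-leaf tree predicts its label everywhere
  leafy <- fit_tree(cohort, params = tree_params(min_leaf = 100))
  expect_equal(unique(predict(leafy, cohort)), leafy$root$label)

  # unseen categorical level goes to the majority child, with a warning
  schema <- toy_schema()
  data <- data.frame(xnum = c(rep(1, 12), rep(9, 8)),
                     xcat = rep(c("a", "b"), 10), stringsAsFactors = FALSE)
  y <- as.integer(data$xnum > 5)
  tr <- fit_tree(data, features = "xcat", params = tree_params(min_leaf = 5),
                 labels = as.integer(data$xcat == "b"), schema = schema)
  newdata <- data.frame(xcat = "c", stringsAsFactors = FALSE)
  expect_warning(p <- predict(tr, newdata), "unseen")
  expect_true(p %in% c(0L, 1L))
})

test_that("continuous records at the split threshold go left", {
  data <- data.frame(xnum = c(rep(1, 10), rep(3, 10)),
                     xcat = "a", stringsAsFactors = FALSE)
  y <- rep(c(0L, 1L), each = 10)
  tree <- fit_tree(data, features = "xnum", params = tree_params(min_leaf = 5),
                   labels = y, schema = toy_schema())
  expect_equal(tree$root$split$threshold, 2)
  expect_equal(predict(tree, data.frame(xnum = 2)), 0L)
  expect_equal(predict(tree, data.frame(xnum = 2.0001)), 1L)
})

test_that("rules reproduce predictions exactly and read sensibly", {
  cohort <- generate_cohort(sim_params(n = 100), seed = 15)
  tree <- fit_tree(cohort, params = tree_params(min_leaf = 10))
  rules <- tree_to_rules(tree)
  expect_equal(rules_predict(rules, cohort), predict(tree, cohort))

  leafy <- fit_tree(cohort, params = tree_params(min_leaf = 200))
  r1 <- tree_to_rules(leafy)
  expect_length(r1$rules, 1)
  expect_match(format(r1), "^IF TRUE THEN")

  labels <- as.integer(cohort$data$cmct == "normal")
  stump <- fit_tree(cohort, features = "cmct",
                    params = tree_params(min_leaf = 10), labels = labels)
  r2 <- tree_to_rules(stump)
  expect_length(r2$rules, 2)
  expect_true(all(grepl("cmct", format(r2))))
})

test_that("trees round-trip through JSON text", {
  cohort <- generate_cohort(sim_params(n = 120), seed = 21)
  tree <- fit_tree(cohort, params = tree_params(min_leaf = 10))
  json <- tree_to_json(tree)
  back <- tree_from_json(json)
  expect_equal(predict(back, cohort), predict(tree, cohort))
  expect_equal(format(tree_to_rules(back)), format(tree_to_rules(tree)))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  expect_equal(predict(tree_from_json(path), cohort), predict(tree, cohort))
})

test_that("gini and rpart agree on the dominant first split", {
  set.seed(55)
  n <- 300
  data <- data.frame(xnum = runif(n, 0, 10),
                     xcat = sample(c("a", "b", "c"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  y <- as.integer(data$xnum > 6) # clean continuous signal
  tree <- fit_tree(data, params = tree_params(min_leaf = 10, max_depth = 1),
                   labels = y, schema = toy_schema())
  rp <- rpart::rpart(factor(y) ~ xnum + xcat, data = data, method = "class",
                     control = rpart::rpart.control(minbucket = 10, cp = 0,
                                                    maxdepth = 1, xval = 0))
  expect_equal(tree$root$split$feature,
               as.character(rp$frame$var[1]))
  expect_equal(tree$root$split$threshold, rp$splits[1, "index"],
               tolerance = 0.1)
})
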