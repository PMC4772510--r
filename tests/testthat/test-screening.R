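# Majority voting, batched stream screening, model persistence.

# a hand-assembled leaf/stump keeps voting tests independent of training
leaf_tree <- function(label, feature_count = 3L) {
  structure(list(
    nodes = list(feature = 0L, threshold = NA_real_, left = 0L, right = 0L,
                 label = as.integer(label), impurity = 0, n_samples = 1L,
                 depth = 0L),
    root_id = 1L, n_nodes = 1L, feature_count = feature_count,
    tree_seed = 0L, bfs_threshold_used = 0), class = "decision_tree")
}

stump_tree <- function(feature, threshold, left_label, right_label,
                       feature_count = 3L) {
  structure(list(
    nodes = list(feature = c(as.integer(feature), 0L, 0L),
                 threshold = c(threshold, NA_real_, NA_real_),
                 left = c(2L, 0L, 0L), right = c(3L, 0L, 0L),
                 label = c(NA_integer_, as.integer(left_label),
                           as.integer(right_label)),
                 impurity = c(0.5, 0, 0), n_samples = c(2L, 1L, 1L),
                 depth = c(0L, 1L, 1L)),
    root_id = 1L, n_nodes = 3L, feature_count = feature_count,
    tree_seed = 0L, bfs_threshold_used = 0), class = "decision_tree")
}

toy_model <- function(trees) {
  structure(list(
    trees = trees, params = forest_params(n_trees = length(trees)),
    feature_count = trees[[1]]$feature_count,
    class_labels = c(inactive = 0L, active = 1L),
    training_summary = list(n = 0L,
                            class_counts = c(inactive = 0L, active = 0L),
                            oob_indices = rep(list(integer(0)),
                                              length(trees)))),
    class = "forest_model")
}

test_that("tree traversal follows the <= threshold rule", {
  expect_identical(predict_tree(leaf_tree(1L), c(9, 9, 9)), 1L)
  st <- stump_tree(1, 2.5, left_label = 0L, right_label = 1L)
  expect_identical(predict_tree(st, c(1, 0, 0)), 0L)
  expect_identical(predict_tree(st, c(2.5, 0, 0)), 0L)  # boundary goes left
  expect_identical(predict_tree(st, c(3, 0, 0)), 1L)
  expect_error(predict_tree(st, c(1, 2)), "length 2")
})

test_that("fully grown trees reproduce their training labels", {
  tab <- generate_assay(assay_spec(n = 120, effect_size = 1, seed = 13))
  rows <- unique(bootstrap_sample(120, 5))
  tr <- build_tree_hybrid(tab, rows, forest_params(), tree_seed = 3)
  pred <- vapply(rows, function(i) predict_tree(tr, tab$matrix[i, ]),
                 integer(1))
  expect_identical(pred, tab$labels[rows])
})

test_that("forest voting is majority with ties resolved to active", {
  X <- matrix(0, 2, 3)
  m3 <- toy_model(list(leaf_tree(1L), leaf_tree(1L), leaf_tree(0L)))
  pr <- predict_forest(m3, X)
  expect_identical(pr$labels, c(1L, 1L))
  expect_equal(pr$votes$score, c(2 / 3, 2 / 3))
  expect_identical(pr$votes$votes_active + pr$votes$votes_inactive,
                   c(3L, 3L))

  tie <- toy_model(list(leaf_tree(1L), leaf_tree(0L)))
  expect_identical(predict_forest(tie, X)$labels, c(1L, 1L))

  expect_error(predict_forest(m3, matrix(0, 2, 5)), "5 features")
})

test_that("duplicating an agreeing tree never flips a prediction", {
  tab <- generate_assay(assay_spec(n = 200, effect_size = 1, seed = 17))
  m <- train_forest(tab, forest_params(n_trees = 5, seed = 2))
  base <- predict_forest(m, tab)
  for (t in c(1L, 3L, 5L)) {
    dup <- m
    dup$trees <- c(m$trees, m$trees[t])
    votes_t <- rfscreen:::.predict_tree_matrix(m$trees[[t]], tab$matrix)
    agreed <- votes_t == base$labels
    flipped <- predict_forest(dup, tab)$labels != base$labels
    expect_false(any(agreed & flipped))
  }
})

test_that("stream screening partitions correctly and is batch invariant", {
  out <- generate_molecules(10, seed = 31, path = tempfile())
  tab <- featurize(read_sdf(out$sdf, activity_tag = "ACTIVITY"))
  model <- train_forest(tab, forest_params(n_trees = 5, seed = 1))

  r3 <- screen_stream(model, molecule_stream(out$smi), batch_size = 3)
  expect_identical(r3$batch_count, 4L)
  expect_identical(r3$n_screened, 10L)
  expect_identical(r3$results$n_votes_active + (r3$results$n_trees -
                     r3$results$n_votes_active),
                   rep(5L, 10))

  for (bs in c(1, 2, 7, 10)) {
    rb <- screen_stream(model, molecule_stream(out$smi), batch_size = bs)
    expect_identical(rb$results, r3$results)
    expect_identical(rb$n_screened, 10L)
  }

  # an unparseable entry is recorded as failed, not dropped silently
  smi2 <- tempfile(fileext = ".smi")
  lines <- readLines(out$smi)
  writeLines(c(lines[1:4], "xx)(bad BADMOL", lines[5:10]), smi2)
  rf <- screen_stream(model, molecule_stream(smi2), batch_size = 4)
  expect_identical(rf$n_screened, 10L)
  expect_identical(rf$n_failed, 1L)
  expect_identical(rf$results$status[5], "failed")
  expect_identical(rf$results$id[5], "BADMOL")

  # list input and stream input agree
  rl <- screen_stream(model, read_smiles(out$smi), batch_size = 3)
  expect_identical(rl$results, r3$results)
})

test_that("models survive the JSON round trip prediction-identically", {
  tab <- generate_assay(assay_spec(n = 150, effect_size = 1, seed = 23))
  model <- train_forest(tab, forest_params(n_trees = 5, seed = 3))
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)

  set.seed(99)
  X <- matrix(rnorm(100 * 179), 100, 179)
  X[, 33:179] <- (X[, 33:179] > 0) + 0
  expect_identical(predict_forest(model, X), predict_forest(back, X))
  expect_identical(back$params, model$params)
  expect_identical(back$training_summary$oob_indices,
                   model$training_summary$oob_indices)

  # truncated file: parse error
  txt <- readLines(path)
  half <- tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), half)
  expect_error(load_model(half), "cannot parse")

  # wrong version: explicit rejection naming the expected schema
  bad <- tempfile(fileext = ".json")
  writeLines(sub("rfscreen-forest/1", "rfscreen-forest/99",
                 paste(txt, collapse = "")), bad)
  expect_error(load_model(bad), "rfscreen-forest/1")
})
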