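# Forest core: impurity, crossover rule, bootstrap, feature subsets, split
# search and hybrid tree construction.

test_that("gini impurity matches closed forms and rejects empty nodes", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)  # 1 - (0.75^2 + 0.25^2)
  expect_error(gini_impurity(c(0, 0)), "empty")
  expect_error(gini_impurity(c(-1, 2)), "negative")
  # bounds: <= 1 - 1/k, zero iff pure
  for (i in 1:20) {
    cc <- c(i, 23 - i)
    g <- gini_impurity(cc)
    expect_gte(g, 0)
    expect_lte(g, 0.5)
    expect_identical(g == 0, any(cc == 0))
  }
})

test_that("crossover threshold reproduces the regression", {
  expect_identical(crossover_threshold(0, 0), 3705)
  expect_equal(crossover_threshold(10000, 100), 6466.0)  # 3705 + 577 + 2184
  expect_error(crossover_threshold(-1, 5), "non-negative")
})

test_that("bootstrap samples are reproducible and have the right coverage", {
  b <- bootstrap_sample(5, 123)
  expect_length(b, 5L)
  expect_true(all(b >= 1 & b <= 5))
  expect_identical(b, bootstrap_sample(5, 123))
  expect_false(identical(b, bootstrap_sample(5, 124)))
  # mean fraction of distinct indices ~ 1 - (1 - 1/n)^n
  n <- 50
  frac <- vapply(seq_len(10000), function(s) {
    length(unique(bootstrap_sample(n, s))) / n
  }, numeric(1))
  expect_equal(mean(frac), 1 - (1 - 1 / n)^n, tolerance = 0.01 / 0.636)
})

test_that("node feature subsets are path-keyed, distinct and complete", {
  full <- node_feature_subset(7, "", 179, 179)
  expect_identical(full, 1:179)
  s1 <- node_feature_subset(7, "LRL", 14, 179)
  expect_identical(s1, node_feature_subset(7, "LRL", 14, 179))
  expect_length(s1, 14L)
  expect_false(anyDuplicated(s1) > 0)
  # sibling nodes should almost never draw the same subset
  collisions <- sum(vapply(seq_len(1000), function(s) {
    identical(node_feature_subset(s, "L", 14, 179),
              node_feature_subset(s, "R", 14, 179))
  }, logical(1)))
  expect_lt(collisions / 1000, 0.05)
})

test_that("best_split matches hand-worked cases and the tie rule", {
  t1 <- make_table(matrix(c(1, 2, 3, 4)), y = c(0L, 0L, 1L, 1L))
  s <- best_split(1:4, t1, 1L)
  expect_identical(s$feature, 1L)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 0.5)

  # pure node: nothing to gain
  t2 <- make_table(matrix(c(1, 2, 3, 4)), y = c(1L, 1L, 1L, 1L))
  expect_null(best_split(1:4, t2, 1L))

  # duplicated identical features: the lower index wins
  X <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  t3 <- make_table(X, y = c(0L, 0L, 1L, 1L))
  expect_identical(best_split(1:4, t3, c(1L, 2L))$feature, 1L)
  expect_identical(best_split(1:4, t3, 2L)$feature, 2L)

  # binary fingerprint column splits at exactly 0.5
  t4 <- make_table(matrix(c(0, 0, 1, 1)), y = c(0L, 0L, 1L, 1L))
  expect_equal(best_split(1:4, t4, 1L)$threshold, 0.5)
})

test_that("best_split equals the exhaustive oracle on random instances", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    p <- sample(1:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    if (rep %% 3 == 0) X <- round(X)  # force ties and repeated values
    y <- sample(0:1, n, replace = TRUE)
    tab <- make_table(X, y = as.integer(y))
    got <- best_split(seq_len(n), tab, seq_len(p))
    want <- oracle_best_split(X, as.integer(y))
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("degenerate trees collapse to a single majority leaf", {
  tab <- make_table(matrix(rnorm(40), 20, 2), y = rep(1L, 20))
  # single-class tables are rejected by train_forest but fine for one tree
  tr <- build_tree_hybrid(tab, 1:20, forest_params(), tree_seed = 1)
  expect_identical(tr$n_nodes, 1L)
  expect_identical(tr$nodes$label[1], 1L)
  expect_identical(predict_tree(tr, rnorm(2)), 1L)
})

test_that("axis-separable data is memorized exactly", {
  set.seed(1)
  X <- cbind(c(runif(20, 0, 1), runif(20, 2, 3)), runif(40))
  y <- rep(c(0L, 1L), each = 20)
  tab <- make_table(X, y = y)
  tr <- build_tree_hybrid(tab, 1:40, forest_params(max_features = 2),
                          tree_seed = 5)
  pred <- vapply(1:40, function(i) predict_tree(tr, X[i, ]), integer(1))
  expect_identical(pred, y)
})

test_that("internal nodes conserve their sample counts", {
  tab <- generate_assay(assay_spec(n = 200, effect_size = 1, seed = 8))
  tr <- build_tree_hybrid(tab, bootstrap_sample(200, 3), forest_params(),
                          tree_seed = 9)
  nd <- tr$nodes
  internal <- which(nd$feature > 0L)
  expect_gt(length(internal), 0L)
  for (i in internal) {
    expect_identical(nd$n_samples[nd$left[i]] + nd$n_samples[nd$right[i]],
                     nd$n_samples[i])
  }
  # every non-root node has exactly one parent; frontier fully consumed
  kids <- c(nd$left[internal], nd$right[internal])
  expect_identical(sort(kids), 2:tr$n_nodes)
})

test_that("the depth/breadth crossover does not change the predictor", {
  tab <- generate_assay(assay_spec(n = 300, effect_size = 1, seed = 21))
  rows <- bootstrap_sample(300, 77)
  grid <- generate_assay(assay_spec(n = 150, effect_size = 1, seed = 22))
  preds <- lapply(list(0, "auto", 1e9), function(bt) {
    tr <- build_tree_hybrid(tab, rows, forest_params(bfs_threshold = bt),
                            tree_seed = 42)
    .predict <- vapply(seq_len(150),
                       function(i) predict_tree(tr, grid$matrix[i, ]),
                       integer(1))
  })
  expect_identical(preds[[1]], preds[[2]])
  expect_identical(preds[[1]], preds[[3]])
})

test_that("forests are deterministic, seeded and reject single-class input", {
  tab <- generate_assay(assay_spec(n = 150, effect_size = 1, seed = 4))
  p <- forest_params(n_trees = 3, seed = 11)
  m1 <- train_forest(tab, p)
  m2 <- train_forest(tab, p)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_model(m1, f1); save_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical

  one <- train_forest(tab, forest_params(n_trees = 1, seed = 11))
  pr <- predict_forest(one, tab)
  tree_pred <- vapply(seq_len(150),
                      function(i) predict_tree(one$trees[[1]],
                                               tab$matrix[i, ]),
                      integer(1))
  expect_identical(pr$labels, tree_pred)

  bad <- make_table(matrix(rnorm(20), 10, 2), y = rep(0L, 10))
  expect_error(train_forest(bad, p), "single class")
})

test_that("a separable assay is recovered out of bag", {
  tab <- generate_assay(assay_spec(n = 500, effect_size = 3, seed = 1))
  m <- train_forest(tab, forest_params(n_trees = 50, seed = 1))
  expect_gte(oob_accuracy(m, tab), 0.9)
})
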