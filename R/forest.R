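# Forest core: GINI split selection, the depth-first -> breadth-first
# crossover rule, and non-recursive tree construction from an explicit
# frontier (a flat array of unexpanded nodes that is popped LIFO while the
# tree is small and FIFO once the node count crosses the threshold).
#
# The crossover node-count threshold is the regression
#     3705 + 0.0577 * n + 21.84 * f
# where n is the number of training samples and f the number of features
# considered at each node split. Construction order never changes the fitted
# tree: the candidate-feature subset of a node is keyed by its root-to-node
# path, not by expansion order, so any bfs_threshold yields an identical
# predictor (only the order in which nodes are materialized differs).

#' Hyper-parameters of a screening forest
#'
#' @param n_trees number of trees in the forest.
#' @param max_features number of candidate features per node split (the
#'   crossover formula's `f`). Default `ceiling(sqrt(179)) = 14`.
#' @param bfs_threshold `"auto"` (resolve via [crossover_threshold()] from
#'   the bootstrap-sample size and `max_features`) or a non-negative number:
#'   the node count at which tree construction switches from depth-first
#'   (stack frontier) to breadth-first (queue frontier).
#' @param gini_leaf_threshold impurity at or below which a frontier node is
#'   finalized as a leaf. Default 0 (only pure nodes stop early), which
#'   reproduces fully grown trees.
#' @param min_gain smallest admissible split gain; a node whose best split
#'   gains no more than this becomes a leaf.
#' @param min_samples_leaf minimum training samples in each child.
#' @param max_depth optional depth cap (root has depth 0); `Inf` = none.
#' @param seed integer seed for the forest's reproducible RNG streams.
#' @return object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 50L, max_features = 14L,
                          bfs_threshold = "auto", gini_leaf_threshold = 0,
                          min_gain = 1e-7, min_samples_leaf = 1L,
                          max_depth = Inf, seed = 1L) {
  stopifnot(n_trees >= 1, max_features >= 1,
            gini_leaf_threshold >= 0, gini_leaf_threshold <= 0.5,
            min_gain >= 0, min_samples_leaf >= 1, max_depth >= 0)
  if (!identical(bfs_threshold, "auto")) {
    stopifnot(is.numeric(bfs_threshold), bfs_threshold >= 0)
  }
  structure(list(n_trees = as.integer(n_trees),
                 max_features = as.integer(max_features),
                 bfs_threshold = if (identical(bfs_threshold, "auto"))
                   "auto" else as.numeric(bfs_threshold),
                 gini_leaf_threshold = as.numeric(gini_leaf_threshold),
                 min_gain = as.numeric(min_gain),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_depth = as.numeric(max_depth),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' GINI impurity of a class-count vector
#'
#' `1 - sum(p_i^2)` with `p_i = count_i / total`; 0 for a pure node, 0.5 at
#' the symmetric binary maximum.
#'
#' @param class_counts non-negative integer counts, summing to >= 1.
#' @return impurity in `[0, 1)`.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("negative class count")
  s <- sum(class_counts)
  if (s < 1) stop("gini_impurity of an empty node is undefined")
  1 - sum((class_counts / s)^2)
}

#' Depth-first to breadth-first crossover threshold
#'
#' The node count at which iterative tree construction should switch from a
#' stack-driven (depth-first) to a queue-driven (breadth-first) frontier:
#' `3705 + 0.0577 * n + 21.84 * f`.
#'
#' @param n number of training samples.
#' @param f number of features considered at each node split.
#' @return the threshold, in nodes.
#' @export
crossover_threshold <- function(n, f) {
  if (n < 0 || f < 0) stop("n and f must be non-negative")
  3705 + 0.0577 * n + 21.84 * f
}

#' Bootstrap resample of n indices
#'
#' `n` draws uniformly with replacement from `1..n`, from the package's
#' reproducible counter-based RNG: the same `rng_state` always yields the
#' same resample, on every platform.
#'
#' @param n sample count (>= 1).
#' @param rng_state integer seed keying the draw stream.
#' @return integer vector of n indices in `[1, n]`.
#' @export
bootstrap_sample <- function(n, rng_state) {
  stopifnot(n >= 1)
  rng_draws_with_replacement(rng_fold(rng_state, "bootstrap"), n)$values
}

#' Candidate-feature subset for one tree node
#'
#' Draws `f` distinct feature indices from a deterministic stream keyed by
#' `(tree_seed, node_path_key)`, where the path key encodes the root-to-node
#' left/right path (e.g. `""` for the root, `"LR"` for its left child's
#' right child). Because the key depends only on the node's position in the
#' tree, the subset is independent of the order in which the frontier is
#' consumed -- the property that makes the depth/breadth crossover free of
#' any effect on the fitted model.
#'
#' @param tree_seed integer seed of the tree being built.
#' @param node_path_key character path key ("" for root, "L"/"R" steps).
#' @param f subset size.
#' @param total_features number of features to draw from.
#' @return sorted integer vector of f distinct indices in `[1, total_features]`.
#' @export
node_feature_subset <- function(tree_seed, node_path_key, f, total_features) {
  stopifnot(f <= total_features, f >= 1)
  st <- rng_fold(tree_seed, "node", node_path_key)
  sort(rng_sample_distinct(st, total_features, f)$values)
}

#' Best GINI split of a row subset
#'
#' Maximizes the impurity gain (parent GINI minus the sample-weighted mean
#' child GINI) over every candidate feature and every midpoint between
#' consecutive distinct sorted values of that feature (for a 0/1 fingerprint
#' column the only midpoint is 0.5). Ties are broken toward the lowest
#' feature index, then the lowest threshold. Splitting sends rows with
#' `value <= threshold` left.
#'
#' @param rows integer vector of row indices into `table` (length >= 2).
#' @param table labelled [feature_table()].
#' @param candidate_features integer vector of feature indices to consider.
#' @param min_gain smallest admissible gain; below or at it, no split.
#' @param min_samples_leaf minimum rows in each child.
#' @return `NULL` when no admissible split exists, else a list with
#'   `feature` (global column index), `threshold`, `gain`.
#' @export
best_split <- function(rows, table, candidate_features, min_gain = 1e-7,
                       min_samples_leaf = 1L) {
  stopifnot(length(rows) >= 2, length(candidate_features) >= 1)
  if (is.null(table$labels)) stop("best_split requires a labelled table")
  cand <- sort(as.integer(candidate_features))
  X <- table$matrix[rows, cand, drop = FALSE]
  y <- table$labels[rows]
  res <- rf_best_split_cpp(X, y, min_gain, as.integer(min_samples_leaf))
  if (res$feature == 0L) return(NULL)
  list(feature = cand[res$feature], threshold = res$threshold,
       gain = res$gain)
}

# empty node store; grown by doubling in .tree_add_node
.tree_store <- function() {
  list(feature = integer(0), threshold = numeric(0), left = integer(0),
       right = integer(0), label = integer(0), impurity = numeric(0),
       n_samples = integer(0), depth = integer(0), n = 0L)
}

.tree_add_node <- function(st, depth, n_samples, impurity) {
  n <- st$n + 1L
  if (n > length(st$feature)) {
    grow <- max(16L, length(st$feature))
    st$feature <- c(st$feature, integer(grow))
    st$threshold <- c(st$threshold, numeric(grow))
    st$left <- c(st$left, integer(grow))
    st$right <- c(st$right, integer(grow))
    st$label <- c(st$label, rep(NA_integer_, grow))
    st$impurity <- c(st$impurity, numeric(grow))
    st$n_samples <- c(st$n_samples, integer(grow))
    st$depth <- c(st$depth, integer(grow))
  }
  st$n <- n
  st$depth[n] <- depth
  st$n_samples[n] <- n_samples
  st$impurity[n] <- impurity
  st
}

#' Build one decision tree by hybrid depth/breadth iterative construction
#'
#' Non-recursive induction: the frontier (the working array of created but
#' unexpanded nodes) starts with the root and is popped last-in-first-out (a
#' stack, i.e. depth-first growth) while the number of nodes created so far
#' is below the crossover value, and first-in-first-out (a queue, level by
#' level) from then on. A frontier node is finalized as a leaf -- labelled by
#' the majority class of its rows, ties resolved toward active -- when its
#' impurity is at or below `gini_leaf_threshold`, its row count is below
#' `2 * min_samples_leaf`, its depth reaches `max_depth`, or [best_split()]
#' finds no admissible split; otherwise it is split and its two children are
#' appended to the frontier. Candidate features per node come from
#' [node_feature_subset()], so the fitted predictor is identical for every
#' `bfs_threshold` value.
#'
#' @param table labelled [feature_table()].
#' @param rows integer vector of training row indices (typically a bootstrap
#'   resample; duplicates allowed).
#' @param params a [forest_params()].
#' @param tree_seed integer seed keying this tree's RNG streams.
#' @return object of class `decision_tree` with a flat node store.
#' @export
build_tree_hybrid <- function(table, rows, params, tree_seed) {
  stopifnot(inherits(table, "feature_table"), length(rows) >= 1)
  if (is.null(table$labels)) stop("tree induction requires a labelled table")
  p <- ncol(table$matrix)
  f <- min(params$max_features, p)
  xover <- if (identical(params$bfs_threshold, "auto")) {
    crossover_threshold(length(rows), f)
  } else {
    params$bfs_threshold
  }

  st <- .tree_store()
  y_all <- table$labels
  root_rows <- as.integer(rows)
  n1 <- sum(y_all[root_rows] == 1L)
  st <- .tree_add_node(st, depth = 0L, n_samples = length(root_rows),
                       impurity = gini_impurity(c(length(root_rows) - n1, n1)))
  # frontier entries: node id, row set, path key
  frontier <- list(list(id = 1L, rows = root_rows, path = ""))

  while (length(frontier) > 0) {
    # hybrid rule: stack (LIFO) below the crossover node count, queue (FIFO)
    # at and beyond it -- compared against nodes created before this expansion
    take <- if (st$n < xover) length(frontier) else 1L
    cur <- frontier[[take]]
    frontier[[take]] <- NULL

    rws <- cur$rows
    y <- y_all[rws]
    k1 <- sum(y == 1L); k0 <- length(y) - k1
    imp <- st$impurity[cur$id]
    split <- NULL
    if (imp > params$gini_leaf_threshold &&
        length(rws) >= 2L * params$min_samples_leaf &&
        st$depth[cur$id] < params$max_depth) {
      cand <- node_feature_subset(tree_seed, cur$path, f, p)
      split <- best_split(rws, table, cand, min_gain = params$min_gain,
                          min_samples_leaf = params$min_samples_leaf)
    }
    if (is.null(split)) {
      st$label[cur$id] <- if (k1 >= k0) 1L else 0L  # tie -> active
      next
    }
    xv <- table$matrix[rws, split$feature]
    go_left <- xv <= split$threshold
    lrows <- rws[go_left]; rrows <- rws[!go_left]
    l1 <- sum(y_all[lrows] == 1L); r1 <- k1 - l1
    dep <- st$depth[cur$id] + 1L
    st <- .tree_add_node(st, dep, length(lrows),
                         gini_impurity(c(length(lrows) - l1, l1)))
    lid <- st$n
    st <- .tree_add_node(st, dep, length(rrows),
                         gini_impurity(c(length(rrows) - r1, r1)))
    rid <- st$n
    st$feature[cur$id] <- split$feature
    st$threshold[cur$id] <- split$threshold
    st$left[cur$id] <- lid
    st$right[cur$id] <- rid
    frontier[[length(frontier) + 1L]] <- list(id = lid, rows = lrows,
                                              path = paste0(cur$path, "L"))
    frontier[[length(frontier) + 1L]] <- list(id = rid, rows = rrows,
                                              path = paste0(cur$path, "R"))
  }

  n <- st$n
  structure(list(
    nodes = list(feature = st$feature[seq_len(n)],
                 threshold = st$threshold[seq_len(n)],
                 left = st$left[seq_len(n)],
                 right = st$right[seq_len(n)],
                 label = st$label[seq_len(n)],
                 impurity = st$impurity[seq_len(n)],
                 n_samples = st$n_samples[seq_len(n)],
                 depth = st$depth[seq_len(n)]),
    root_id = 1L,
    n_nodes = n,
    feature_count = p,
    tree_seed = as.integer(tree_seed),
    bfs_threshold_used = xover
  ), class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("<decision_tree: %d nodes (%d leaves), max depth %d>\n",
              x$n_nodes, sum(x$nodes$feature == 0L), max(x$nodes$depth)))
  invisible(x)
}

#' Train a random forest for virtual screening
#'
#' Grows `params$n_trees` trees, each on its own bootstrap resample of the
#' training rows, by [build_tree_hybrid()]. Tree seeds are derived from
#' `(params$seed, tree_index)`, so the model is a pure function of
#' `(table, params)`: trees are mutually independent given their seeds and
#' any execution order yields the same forest. Out-of-bag row indices are
#' recorded per tree for internal error estimation.
#'
#' @param table labelled [feature_table()] with both classes present.
#' @param params a [forest_params()].
#' @return object of class `forest_model`.
#' @export
train_forest <- function(table, params = forest_params()) {
  stopifnot(inherits(table, "feature_table"), inherits(params, "forest_params"))
  if (is.null(table$labels)) stop("training requires a labelled table")
  n <- nrow(table$matrix)
  cc <- c(inactive = sum(table$labels == 0L), active = sum(table$labels == 1L))
  if (any(cc == 0L)) {
    stop("training set contains a single class (",
         names(cc)[cc > 0], " only)")
  }
  trees <- vector("list", params$n_trees)
  oob <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    tree_seed <- rng_fold(params$seed, "tree", t)
    boot <- bootstrap_sample(n, rng_fold(params$seed, "boot", t))
    trees[[t]] <- build_tree_hybrid(table, boot, params, tree_seed)
    oob[[t]] <- setdiff(seq_len(n), unique(boot))
  }
  structure(list(
    trees = trees,
    params = params,
    feature_count = ncol(table$matrix),
    class_labels = c(inactive = 0L, active = 1L),
    training_summary = list(n = n, class_counts = cc, oob_indices = oob)
  ), class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(
    "<forest_model: %d trees, %d features, trained on %d compounds (%d active)>\n",
    length(x$trees), x$feature_count, x$training_summary$n,
    x$training_summary$class_counts[["active"]]))
  invisible(x)
}

#' Out-of-bag accuracy of a trained forest
#'
#' Each training row is voted on only by the trees whose bootstrap resample
#' excluded it; rows never out of bag are skipped.
#'
#' @param model a [forest_model()].
#' @param table the labelled [feature_table()] the model was trained on.
#' @return out-of-bag accuracy in `[0, 1]`.
#' @export
oob_accuracy <- function(model, table) {
  n <- nrow(table$matrix)
  votes1 <- numeric(n)
  total <- numeric(n)
  for (t in seq_along(model$trees)) {
    idx <- model$training_summary$oob_indices[[t]]
    if (length(idx) == 0) next
    lab <- .predict_tree_matrix(model$trees[[t]],
                                table$matrix[idx, , drop = FALSE])
    votes1[idx] <- votes1[idx] + (lab == 1L)
    total[idx] <- total[idx] + 1
  }
  use <- total > 0
  pred <- ifelse(votes1[use] * 2 >= total[use], 1L, 0L)  # tie -> active
  mean(pred == table$labels[use])
}
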