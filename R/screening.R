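# Screening: majority-vote forest prediction and batched evaluation of
# compound streams. Per-tree evaluations are independent, so results are
# identical for any batch size or evaluation order; batches only bound
# memory so that arbitrarily large libraries can be screened.

.model_format_version <- "rfscreen-forest/1"

# batch traversal of one tree over a plain feature matrix
.predict_tree_matrix <- function(tree, X) {
  rf_predict_tree_cpp(tree$nodes$feature, tree$nodes$threshold,
                      tree$nodes$left, tree$nodes$right,
                      ifelse(is.na(tree$nodes$label), 0L, tree$nodes$label),
                      X, tree$root_id)
}

#' Classify one descriptor vector with one tree
#'
#' Deterministic root-to-leaf traversal; at each internal node the instance
#' goes left iff its value at the node's feature is `<= threshold`.
#'
#' @param tree a `decision_tree`.
#' @param x numeric descriptor vector of length `tree$feature_count`.
#' @return the leaf label: 1 (active) or 0 (inactive).
#' @export
predict_tree <- function(tree, x) {
  if (length(x) != tree$feature_count) {
    stop("descriptor vector has length ", length(x),
         " but the tree expects ", tree$feature_count)
  }
  node <- tree$root_id
  nd <- tree$nodes
  while (nd$feature[node] > 0L) {
    node <- if (x[nd$feature[node]] <= nd$threshold[node]) {
      nd$left[node]
    } else {
      nd$right[node]
    }
  }
  nd$label[node]
}

#' Majority-vote prediction of a forest over a feature table
#'
#' Every tree votes on every row; the predicted label is the class with the
#' most votes, with exact ties resolved toward active (the screening-oriented
#' choice: a compound the forest cannot separate is kept for follow-up rather
#' than discarded). The vote fraction `score = votes_active / n_trees` is
#' returned as a ranking statistic for ROC analysis.
#'
#' @param model a `forest_model`.
#' @param X a [feature_table()] or numeric matrix with
#'   `model$feature_count` columns.
#' @return list with `labels` (integer 0/1 per row) and `votes` (data.frame
#'   with `votes_active`, `votes_inactive`, `score`).
#' @export
predict_forest <- function(model, X) {
  stopifnot(inherits(model, "forest_model"))
  m <- if (inherits(X, "feature_table")) X$matrix else as.matrix(X)
  if (ncol(m) != model$feature_count) {
    stop("input has ", ncol(m), " features but the model expects ",
         model$feature_count)
  }
  n_trees <- length(model$trees)
  votes1 <- integer(nrow(m))
  for (tree in model$trees) {
    votes1 <- votes1 + (.predict_tree_matrix(tree, m) == 1L)
  }
  labels <- ifelse(votes1 * 2L >= n_trees, 1L, 0L)  # tie -> active
  list(labels = labels,
       votes = data.frame(votes_active = votes1,
                          votes_inactive = n_trees - votes1,
                          score = votes1 / n_trees))
}

#' Open a molecule stream for batched screening
#'
#' Returns a pull-based reader over a SMILES (`.smi`/`.smiles`, one molecule
#' per line) or SDF file, exposing `next_batch(k)` which parses and returns
#' up to `k` further molecule records (possibly fewer after skipping
#' unparseable entries, which are returned as failure stubs so the screening
#' report can account for them). Only one batch is held in memory at a time.
#'
#' @param path path to a `.smi`/`.smiles` or `.sdf` file.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @return object of class `molecule_stream`.
#' @export
molecule_stream <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("smi", "smiles", "txt")) "smiles"
    else if (ext == "sdf") "sdf"
    else stop("cannot infer format from extension '", ext, "'")
  }
  if (!file.exists(path)) stop("cannot read ", path)
  # files are line-indexed up front (cheap: text only), parsed per batch
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (format == "smiles") {
    keep <- which(nzchar(trimws(lines)))
    pos <- 0L
    nxt <- function(k) {
      if (pos >= length(keep)) return(list())
      idx <- keep[(pos + 1L):min(pos + k, length(keep))]
      pos <<- pos + length(idx)
      lapply(idx, function(i) {
        tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
        id <- if (length(tok) >= 2) tok[2] else sprintf("SMI%05d", i)
        tryCatch({
          rec <- parse_smiles(tok[1], id = id)
          rec$source_index <- i
          rec
        }, error = function(e) {
          structure(list(id = id, error = conditionMessage(e)),
                    class = "molecule_failure")
        })
      })
    }
  } else {
    ends <- grep("^\\$\\$\\$\\$", lines)
    if (length(ends) == 0 && length(lines) > 0) ends <- length(lines) + 1L
    starts <- c(1L, head(ends, -1L) + 1L)
    pos <- 0L
    nxt <- function(k) {
      if (pos >= length(ends)) return(list())
      take <- (pos + 1L):min(pos + k, length(ends))
      pos <<- pos + length(take)
      lapply(take, function(b) {
        block <- lines[starts[b]:(ends[b] - 1L)]
        first <- which(nzchar(trimws(block)))[1]
        if (is.na(first)) return(NULL)
        block <- block[first:length(block)]
        tryCatch(.parse_sdf_block(block, b)$record, error = function(e) {
          structure(list(id = sprintf("MOL%05d", b),
                         error = conditionMessage(e)),
                    class = "molecule_failure")
        })
      })
    }
  }
  structure(list(next_batch = nxt, path = path, format = format),
            class = "molecule_stream")
}

#' Screen a compound stream in batches
#'
#' Consumes the input in successive batches of at most `batch_size`
#' molecules, featurizes and classifies each batch, and accumulates a
#' screening report. Memory use is bounded by the batch size, so libraries
#' of arbitrary length can be screened; the per-compound output is
#' independent of `batch_size`. Compounds that fail to parse or featurize
#' are recorded with status `"failed"` and screening continues.
#'
#' @param model a `forest_model`.
#' @param mols a [molecule_stream()], a list of [molecule_record()]s, or a
#'   file path (opened via [molecule_stream()]).
#' @param batch_size maximum compounds per batch (>= 1).
#' @return object of class `screening_report`: `results` data.frame (id,
#'   predicted_label, score, n_votes_active, n_trees, status), `n_screened`,
#'   `n_active`, `n_failed`, `batch_count`.
#' @export
screen_stream <- function(model, mols, batch_size = 1024L) {
  stopifnot(inherits(model, "forest_model"), batch_size >= 1)
  batch_size <- as.integer(batch_size)
  if (is.character(mols)) mols <- molecule_stream(mols)
  if (is.list(mols) && !inherits(mols, "molecule_stream")) {
    records <- mols
    pos <- 0L
    nxt <- function(k) {
      if (pos >= length(records)) return(list())
      idx <- (pos + 1L):min(pos + k, length(records))
      pos <<- pos + length(idx)
      records[idx]
    }
  } else {
    nxt <- mols$next_batch
  }

  n_trees <- length(model$trees)
  chunks <- list()
  batch_count <- 0L
  repeat {
    batch <- Filter(Negate(is.null), nxt(batch_size))
    if (length(batch) == 0) break
    batch_count <- batch_count + 1L
    ok <- !vapply(batch, inherits, logical(1), "molecule_failure")
    ids <- vapply(batch, function(x) x$id, character(1))
    lab <- rep(NA_integer_, length(batch))
    v1 <- rep(NA_integer_, length(batch))
    status <- ifelse(ok, "ok", "failed")
    if (any(ok)) {
      feat <- lapply(batch[ok], function(m) {
        tryCatch(compute_descriptors(m), error = function(e) NULL)
      })
      good <- !vapply(feat, is.null, logical(1))
      status[which(ok)[!good]] <- "failed"
      if (any(good)) {
        X <- do.call(rbind, feat[good])
        pr <- predict_forest(model, X)
        rows <- which(ok)[good]
        lab[rows] <- pr$labels
        v1[rows] <- pr$votes$votes_active
      }
    }
    chunks[[batch_count]] <- data.frame(
      id = ids,
      predicted_label = ifelse(is.na(lab), NA_character_,
                               ifelse(lab == 1L, "active", "inactive")),
      score = v1 / n_trees,
      n_votes_active = v1,
      n_trees = n_trees,
      status = status,
      stringsAsFactors = FALSE
    )
  }
  results <- if (length(chunks) > 0) do.call(rbind, chunks) else
    data.frame(id = character(0), predicted_label = character(0),
               score = numeric(0), n_votes_active = integer(0),
               n_trees = integer(0), status = character(0))
  rownames(results) <- NULL
  structure(list(
    results = results,
    n_screened = sum(results$status == "ok"),
    n_active = sum(results$predicted_label == "active", na.rm = TRUE),
    n_failed = sum(results$status == "failed"),
    batch_count = batch_count
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report: %d screened (%d predicted active, %d failed) in %d batches>\n",
    x$n_screened, x$n_active, x$n_failed, x$batch_count))
  invisible(x)
}

#' Write a screening report to CSV
#'
#' @param report a `screening_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path) {
  data.table::fwrite(report$results, path)
  invisible(path)
}

#' Save a forest model as JSON
#'
#' A documented, versioned schema: hyper-parameters, class labels, training
#' summary, and one flat node array per tree, at full floating-point
#' precision so a reloaded model predicts identically.
#'
#' @param model a `forest_model`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  payload <- list(
    format_version = .model_format_version,
    params = unclass(model$params),
    feature_count = model$feature_count,
    class_labels = as.list(model$class_labels),
    training_summary = list(
      n = model$training_summary$n,
      class_counts = as.list(model$training_summary$class_counts),
      oob_indices = model$training_summary$oob_indices
    ),
    trees = lapply(model$trees, function(tr) {
      nd <- tr$nodes
      nd$label <- ifelse(is.na(nd$label), -1L, nd$label)  # -1: internal node
      list(nodes = nd, root_id = tr$root_id, n_nodes = tr$n_nodes,
           feature_count = tr$feature_count, tree_seed = tr$tree_seed,
           bfs_threshold_used = tr$bfs_threshold_used)
    })
  )
  # max_depth may be Inf, which JSON cannot carry as a number
  if (is.infinite(payload$params$max_depth)) {
    payload$params$max_depth <- "Inf"
  }
  # I(17) significant digits: doubles survive the text round trip exactly,
  # so a reloaded model predicts identically
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a forest model saved by [save_model()]
#'
#' @param path path to the JSON model file.
#' @return a `forest_model` that predicts identically to the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model file: ", path)
  # simplifyVector = FALSE: tree node arrays have tree-specific lengths and
  # must not be collapsed across trees; every field is converted explicitly
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
                        stop("cannot parse model file ", path, ": ",
                             conditionMessage(e))
                      })
  if (is.null(payload$format_version) ||
      !identical(payload$format_version, .model_format_version)) {
    stop("unsupported model format version '", payload$format_version,
         "' (expected '", .model_format_version, "')")
  }
  pp <- payload$params
  if (identical(pp$max_depth, "Inf")) pp$max_depth <- Inf
  params <- forest_params(n_trees = pp$n_trees, max_features = pp$max_features,
                          bfs_threshold = if (is.character(pp$bfs_threshold))
                            pp$bfs_threshold else as.numeric(pp$bfs_threshold),
                          gini_leaf_threshold = pp$gini_leaf_threshold,
                          min_gain = pp$min_gain,
                          min_samples_leaf = pp$min_samples_leaf,
                          max_depth = pp$max_depth, seed = pp$seed)
  as_int <- function(x) as.integer(unlist(x, use.names = FALSE))
  as_num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  trees <- lapply(payload$trees, function(tr) {
    lb <- as_int(tr$nodes$label)
    structure(list(
      nodes = list(feature = as_int(tr$nodes$feature),
                   threshold = as_num(tr$nodes$threshold),
                   left = as_int(tr$nodes$left),
                   right = as_int(tr$nodes$right),
                   label = ifelse(lb < 0L, NA_integer_, lb),
                   impurity = as_num(tr$nodes$impurity),
                   n_samples = as_int(tr$nodes$n_samples),
                   depth = as_int(tr$nodes$depth)),
      root_id = as.integer(tr$root_id),
      n_nodes = as.integer(tr$n_nodes),
      feature_count = as.integer(tr$feature_count),
      tree_seed = as.integer(tr$tree_seed),
      bfs_threshold_used = as.numeric(tr$bfs_threshold_used)
    ), class = "decision_tree")
  })
  structure(list(
    trees = trees,
    params = params,
    feature_count = as.integer(payload$feature_count),
    class_labels = c(inactive = 0L, active = 1L),
    training_summary = list(
      n = as.integer(payload$training_summary$n),
      class_counts = unlist(payload$training_summary$class_counts),
      oob_indices = lapply(payload$training_summary$oob_indices, as_int)
    )
  ), class = "forest_model")
}
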