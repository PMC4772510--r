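# FeatureTable: the n x p training/prediction matrix with compound ids and
# optional binary labels (active = 1, inactive = 0). The descriptor pipeline
# always produces p = 179, but the container itself is dimension-agnostic so
# that small hand-built tables can be used in tests and examples.

#' Construct a feature table
#'
#' @param matrix numeric matrix, n compounds x p descriptors.
#' @param ids character vector of n compound identifiers (default
#'   `"ROW1"..."ROWn"`).
#' @param labels optional integer/numeric vector of n binary labels
#'   (1 = active, 0 = inactive), or `NULL` for an unlabelled table.
#' @return object of class `feature_table` with fields `matrix`, `ids`,
#'   `labels`, `column_names`.
#' @export
feature_table <- function(matrix, ids = NULL, labels = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (nrow(m) < 1 || ncol(m) < 1) stop("feature matrix must be non-empty")
  if (any(!is.finite(m))) stop("feature matrix contains non-finite values")
  if (is.null(ids)) ids <- sprintf("ROW%d", seq_len(nrow(m)))
  ids <- as.character(ids)
  if (length(ids) != nrow(m)) stop("ids length must equal row count")
  if (is.null(colnames(m))) colnames(m) <- sprintf("X%d", seq_len(ncol(m)))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(m)) stop("labels length must equal row count")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  }
  structure(list(matrix = m, ids = ids, labels = labels,
                 column_names = colnames(m)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d compounds x %d descriptors, %s>\n",
              nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$labels)) "unlabelled"
              else sprintf("%d active / %d inactive",
                           sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

# subset rows, keeping ids/labels aligned
ft_rows <- function(table, rows) {
  feature_table(table$matrix[rows, , drop = FALSE],
                ids = table$ids[rows],
                labels = if (is.null(table$labels)) NULL else
                  table$labels[rows])
}

#' Write a feature table to CSV
#'
#' Layout: an `id` column, one column per descriptor, and (when the table is
#' labelled) a trailing `activity` column with 0/1 values. UTF-8, `.` decimal
#' separator, full floating-point precision, so that
#' `read_feature_table(write_feature_table(t))` reproduces `t`.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  dt <- data.table::data.table(id = table$ids)
  dt <- cbind(dt, data.table::as.data.table(table$matrix))
  if (!is.null(table$labels)) dt$activity <- table$labels
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the layout written by [write_feature_table()]. The number of
#' descriptor columns is validated against `expected_features` (179, the
#' pipeline's contract) and a mismatch is a fatal error reporting the actual
#' count; pass `expected_features = NULL` to accept any width. An `activity`
#' column may contain 0/1 or active/inactive strings.
#'
#' @param path path to the CSV file.
#' @param expected_features required descriptor-column count, or `NULL`.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, expected_features = 179L) {
  if (!file.exists(path)) stop("cannot read feature table: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"id" %in% names(dt)) stop("feature CSV must have an 'id' column")
  has_act <- "activity" %in% names(dt)
  feats <- setdiff(names(dt), c("id", "activity"))
  if (!is.null(expected_features) &&
      length(feats) != expected_features) {
    stop("expected ", expected_features, " descriptor columns, found ",
         length(feats))
  }
  labels <- NULL
  if (has_act) {
    a <- dt$activity
    if (is.character(a) || is.factor(a)) {
      a <- tolower(trimws(as.character(a)))
      mapped <- ifelse(a %in% c("active", "1", "true"), 1L,
                       ifelse(a %in% c("inactive", "0", "false"), 0L,
                              NA_integer_))
      if (anyNA(mapped)) stop("unmappable activity values in ", path)
      labels <- mapped
    } else {
      labels <- as.integer(a)
    }
  }
  m <- as.matrix(dt[, feats, drop = FALSE])
  feature_table(m, ids = as.character(dt$id), labels = labels)
}
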