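#' Samples-by-features table with binary labels
#'
#' The tabular handoff between feature extraction, MRMD selection and
#' the classifier: an N x M numeric matrix, ordered sample ids, ordered
#' feature names, and an optional 0/1 label vector (1 = DNA-binding).
#'
#' @param values Numeric N x M matrix, no missing values.
#' @param sample_ids Character vector of length N.
#' @param feature_names Character vector of length M.
#' @param labels Optional integer vector in \{0, 1\} of length N.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids, feature_names, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop_validation("feature table contains missing values")
  if (nrow(values) != length(sample_ids)) {
    stop_validation("sample_ids length != row count")
  }
  if (ncol(values) != length(feature_names)) {
    stop_validation("feature_names length != column count")
  }
  if (anyDuplicated(feature_names)) {
    stop_validation("duplicate feature names")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values) || !all(labels %in% c(0L, 1L))) {
      stop_validation("labels must be a 0/1 vector matching the row count")
    }
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 feature_names = as.character(feature_names),
                 labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " features", if (!is.null(x$labels)) sprintf(
        " (%d pos / %d neg)", sum(x$labels == 1L), sum(x$labels == 0L)),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset the columns of a feature table
#'
#' @param t A [feature_table()].
#' @param features Character vector of feature names (order preserved as
#'   given) or integer column indices.
#' @return A [feature_table()] restricted to those features.
#' @export
subset_features <- function(t, features) {
  stopifnot(inherits(t, "feature_table"))
  if (is.character(features)) {
    missing <- setdiff(features, t$feature_names)
    if (length(missing)) {
      stop_schema("unknown feature(s): ", paste(missing, collapse = ", "))
    }
  }
  feature_table(t$values[, features, drop = FALSE], t$sample_ids,
                if (is.character(features)) features else
                  t$feature_names[features],
                t$labels)
}

#' Write a feature table as tab-separated text
#'
#' Layout: `sample_id`, optional `label`, then one named column per
#' feature. Values are printed with 12 significant digits, which
#' round-trips through [read_feature_table()] to that precision.
#'
#' @param t A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  header <- c("sample_id", if (!is.null(t$labels)) "label", t$feature_names)
  rows <- vapply(seq_len(nrow(t$values)), function(i) {
    paste(c(t$sample_ids[i],
            if (!is.null(t$labels)) t$labels[i],
            sprintf("%.12g", t$values[i, ])), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Tab-separated file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (!nrow(df)) stop_empty("empty feature table: ", path)
  if (names(df)[1] != "sample_id") {
    stop_parse("first column must be 'sample_id'")
  }
  has_label <- ncol(df) >= 2L && names(df)[2] == "label"
  feat_cols <- names(df)[-(1:(1L + has_label))]
  vals <- vapply(df[feat_cols], as.numeric, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, feat_cols))
  feature_table(vals, df$sample_id, feat_cols,
                labels = if (has_label) as.integer(df$label))
}
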