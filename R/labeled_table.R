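#' Labeled numeric table
#'
#' The universal data container of the pipeline: an `n x b` numeric feature
#' matrix together with a categorical label per row and stable instance
#' identifiers. All pipeline stages (normalization, feature selection,
#' outlier rejection, classification) consume and return this structure.
#'
#' @param values Numeric matrix (or object coercible to one), one row per
#'   instance, one column per feature. No missing or non-finite entries.
#' @param labels Vector of class labels, length `nrow(values)`; coerced to a
#'   factor. Existing factor levels are preserved.
#' @param feature_names Optional character vector of column names; defaults
#'   to existing column names or `f1 .. fb`.
#' @param instance_ids Optional identifiers, one per row (duplicates are
#'   allowed, e.g. repeated sample IDs); defaults to the row index.
#'
#' @return An object of class `labeled_table` with elements `values`,
#'   `labels`, `feature_names`, `instance_ids`.
#' @examples
#' lt <- labeled_table(matrix(1:6, 3, 2), c("a", "b", "a"))
#' n_instances(lt)
#' @export
labeled_table <- function(values, labels, feature_names = NULL,
                          instance_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("labeled_table requires at least one instance and one feature")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("labeled_table values must be finite with no missing entries")
  }
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(labels) != nrow(values)) {
    stop("length of labels (", length(labels),
         ") must equal the number of rows (", nrow(values), ")")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- paste0("f", seq_len(ncol(values)))
    }
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must equal the number of columns")
  }
  if (is.null(instance_ids)) instance_ids <- as.character(seq_len(nrow(values)))
  instance_ids <- as.character(instance_ids)
  if (length(instance_ids) != nrow(values)) {
    stop("instance_ids length must equal the number of rows")
  }
  colnames(values) <- feature_names
  rownames(values) <- NULL
  structure(
    list(values = values, labels = labels,
         feature_names = feature_names, instance_ids = instance_ids),
    class = "labeled_table"
  )
}

#' @export
print.labeled_table <- function(x, ...) {
  cat("<labeled_table> ", n_instances(x), " instances x ",
      n_features(x), " features\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of instances / features of a labeled table
#' @param table A [labeled_table()].
#' @return Integer count.
#' @export
n_instances <- function(table) nrow(table$values)

#' @rdname n_instances
#' @export
n_features <- function(table) ncol(table$values)

#' Subset a labeled table
#'
#' Row subsetting keeps labels and instance identifiers aligned; column
#' subsetting keeps feature names aligned.
#'
#' @param table A [labeled_table()].
#' @param idx Row (or column) indices, logical or integer.
#' @return A new `labeled_table`.
#' @export
subset_instances <- function(table, idx) {
  labeled_table(table$values[idx, , drop = FALSE],
                table$labels[idx],
                feature_names = table$feature_names,
                instance_ids = table$instance_ids[idx])
}

#' @rdname subset_instances
#' @export
subset_features <- function(table, idx) {
  labeled_table(table$values[, idx, drop = FALSE],
                table$labels,
                feature_names = table$feature_names[idx],
                instance_ids = table$instance_ids)
}

#' @export
as.data.frame.labeled_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  names(df) <- x$feature_names
  df$class <- x$labels
  df
}

# training-stage guard: at least two observed classes
check_two_classes <- function(table, what = "training") {
  if (nlevels(droplevels(table$labels)) < 2L) {
    stop(what, " table must contain at least two classes")
  }
  invisible(table)
}
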