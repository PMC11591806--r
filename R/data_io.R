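#' Read a Wisconsin breast cancer (original) file
#'
#' Parses the classic comma-separated dialect: eleven fields per row
#' (sample ID, nine integer cytology features on a 1-10 scale, class code),
#' with `?` marking a missing value and class codes 2 = benign,
#' 4 = malignant. Rows containing any missing value are dropped, never
#' imputed; the load summary (rows read / kept / dropped) is reported via
#' [message()] and stored as attributes `n_read`, `n_kept`, `n_dropped`.
#'
#' @param path Path to the file.
#' @return A [labeled_table()] with nine features, labels
#'   `benign`/`malignant`, and instance IDs taken from the leading ID column
#'   (duplicates allowed).
#' @export
read_wbcd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep_line <- nzchar(trimws(lines))
  line_no <- which(keep_line)
  parts <- strsplit(trimws(lines[keep_line]), ",", fixed = TRUE)
  bad <- which(lengths(parts) != 11L)
  if (length(bad)) {
    stop("line ", line_no[bad[1L]], ": expected 11 comma-separated fields, ",
         "got ", lengths(parts)[bad[1L]])
  }
  n_read <- length(parts)
  if (n_read == 0L) stop("no data rows in ", path)
  fields <- do.call(rbind, parts)
  missing_row <- apply(fields == "?", 1L, any)
  kept <- fields[!missing_row, , drop = FALSE]
  kept_line <- line_no[!missing_row]
  n_dropped <- sum(missing_row)
  if (nrow(kept) == 0L) {
    stop("empty table after dropping rows with missing values (all ",
         n_read, " rows contained '?')")
  }
  feat <- suppressWarnings(
    matrix(as.numeric(kept[, 2:10]), nrow = nrow(kept))
  )
  if (anyNA(feat)) {
    i <- which(rowSums(is.na(feat)) > 0)[1L]
    stop("line ", kept_line[i], ": non-numeric feature value")
  }
  code <- kept[, 11L]
  unknown <- which(!code %in% c("2", "4"))
  if (length(unknown)) {
    stop("line ", kept_line[unknown[1L]], ": unknown class code '",
         code[unknown[1L]], "' (expected 2 or 4)")
  }
  labels <- factor(ifelse(code == "2", "benign", "malignant"),
                   levels = c("benign", "malignant"))
  message("read_wbcd: ", n_read, " rows read, ", nrow(kept), " kept, ",
          n_dropped, " dropped (missing values)")
  out <- labeled_table(feat, labels,
                       feature_names = wbcd_feature_names(),
                       instance_ids = kept[, 1L])
  attr(out, "n_read") <- n_read
  attr(out, "n_kept") <- nrow(kept)
  attr(out, "n_dropped") <- n_dropped
  out
}

wbcd_feature_names <- function() {
  c("clump_thickness", "uniformity_cell_size", "uniformity_cell_shape",
    "marginal_adhesion", "single_epithelial_cell_size", "bare_nuclei",
    "bland_chromatin", "normal_nucleoli", "mitoses")
}

#' Read a generic labeled CSV
#'
#' Header required. Every non-label column is parsed as a numeric feature;
#' rows with any missing cell (empty, `NA` or `?`) are dropped with a
#' logged count. A non-numeric, non-missing feature cell is an error naming
#' the offending row and column.
#'
#' @param path CSV path.
#' @param label_column Name of the label column.
#' @return A [labeled_table()] with attributes `n_read`, `n_kept`,
#'   `n_dropped`.
#' @export
read_csv_labeled <- function(path, label_column = "class") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in header")
  }
  feat_cols <- setdiff(names(df), label_column)
  if (length(feat_cols) == 0L) stop("no feature columns besides the label")
  raw <- as.matrix(df[feat_cols])
  is_missing <- is.na(raw) | raw == "" | raw == "NA" | raw == "?"
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("row ", bad[1L, 1L], ", column '", feat_cols[bad[1L, 2L]],
         "': non-numeric value '", raw[bad[1L, , drop = FALSE]], "'")
  }
  drop_row <- rowSums(is_missing) > 0 | is.na(df[[label_column]]) |
    df[[label_column]] == ""
  n_read <- nrow(df)
  n_dropped <- sum(drop_row)
  if (n_dropped > 0) {
    message("read_csv_labeled: dropped ", n_dropped,
            " row(s) with missing values")
  }
  if (all(drop_row)) stop("empty table after dropping incomplete rows")
  out <- labeled_table(num[!drop_row, , drop = FALSE],
                       factor(df[[label_column]][!drop_row]),
                       feature_names = feat_cols,
                       instance_ids = which(!drop_row))
  attr(out, "n_read") <- n_read
  attr(out, "n_kept") <- n_read - n_dropped
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write / read a machine-readable report
#'
#' Serializes any report produced by the pipeline (a metrics report, a
#' cross-validation report, or a full run manifest) as JSON. The document
#' round-trips: `read_report(write_report(x, p))` preserves all numeric
#' values.
#'
#' @param report A list-like report object.
#' @param path Output path; the parent directory must exist.
#' @return `write_report` invisibly returns `path`; `read_report` returns
#'   the parsed list.
#' @export
write_report <- function(report, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  jsonlite::write_json(strip_classes(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                     simplifyDataFrame = FALSE)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.factor(x)) {
    as.character(x)
  } else if (is.matrix(x)) {
    apply(x, 1L, identity, simplify = FALSE)
  } else {
    attributes(x) <- if (is.null(names(x))) NULL else list(names = names(x))
    x
  }
}
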