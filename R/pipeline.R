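#' Run the full discovery pipeline end to end
#'
#' Loads (or generates) a labeled table, runs the cross-validated
#' pipeline — normalization, information-gain feature selection, CORT
#' outlier rejection, ensemble classification — and assembles a run
#' manifest whose every number is recomputable from config + seed +
#' input.
#'
#' @param input One of: a [labeled_table()], a [synthetic_spec()], or a
#'   file path (format controlled by `format`).
#' @param config A [pipeline_config()].
#' @param report_path Optional path; when given, the manifest is written
#'   there with [write_report()].
#' @param format For path input: `"auto"` (WBCD dialect for `.data`
#'   files, labeled CSV otherwise), `"wbcd"` or `"csv"`.
#' @param label_column Label column name for CSV input.
#' @return An object of class `run_manifest`: `input` (descriptor),
#'   `config`, `seed`, `cv` (the [cross_validate()] report),
#'   `mean_metrics_percent`, `version`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_per_class = 30, b = 5, seed = 3)
#' cfg <- pipeline_config(bhho = list(it_max = 10), cv_folds = 3)
#' man <- run_pipeline(spec, cfg)
#' man$mean_metrics_percent
#' }
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         report_path = NULL,
                         format = c("auto", "wbcd", "csv"),
                         label_column = "class") {
  format <- match.arg(format)
  if (inherits(input, "labeled_table")) {
    table <- input
    descriptor <- list(type = "labeled_table", n = n_instances(input),
                       b = n_features(input))
  } else if (inherits(input, "synthetic_spec")) {
    table <- generate_synthetic(input)$table
    descriptor <- c(list(type = "synthetic"), unclass(input))
  } else if (is.character(input) && length(input) == 1L) {
    if (format == "auto") {
      format <- if (grepl("\\.data$", input)) "wbcd" else "csv"
    }
    table <- if (format == "wbcd") read_wbcd(input)
             else read_csv_labeled(input, label_column)
    descriptor <- list(type = format, path = input,
                       n_read = attr(table, "n_read"),
                       n_kept = attr(table, "n_kept"),
                       n_dropped = attr(table, "n_dropped"))
  } else {
    stop("input must be a labeled_table, a synthetic_spec, or a file path")
  }
  cv <- cross_validate(table, config)
  manifest <- structure(list(
    tool = "cortecm",
    version = as.character(utils::packageVersion("cortecm")),
    input = descriptor,
    config = unclass(config),
    seed = config$seed,
    folds = lapply(cv$folds, function(f) list(
      fold = f$fold, n_train = f$n_train, n_test = f$n_test,
      selected_features = f$selected_features,
      cort_counts = f$cort_counts,
      confusion = f$confusion[c("TP", "TN", "FP", "FN")],
      metrics = unclass(f$metrics))),
    mean_metrics = unclass(cv$mean_metrics),
    mean_metrics_percent = as.list(metrics_percent(cv$mean_metrics)),
    cv = cv), class = "run_manifest")
  if (!is.null(report_path)) {
    write_report(manifest[setdiff(names(manifest), "cv")], report_path)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", x$tool, " ", x$version, "; input type ",
      x$input$type, "\n", sep = "")
  print(x$cv)
  invisible(x)
}
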