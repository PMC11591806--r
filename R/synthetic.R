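#' Specification for synthetic two-class tabular data
#'
#' Describes a two-class Gaussian dataset with planted outliers, emulating
#' integer-scaled cytology feature tables: bounded feature values, two
#' balanced classes separated in feature space, and a small minority of
#' anomalous training instances. The defaults generate a table on the
#' familiar 1-10 scale with 9 features per instance.
#'
#' @param n_per_class Instances per class (>= 2).
#' @param b Number of features (>= 1).
#' @param class_separation Euclidean distance between the two class mean
#'   vectors.
#' @param within_sd Within-class standard deviation per feature.
#' @param outlier_rate Fraction of instances perturbed into outliers, in
#'   `[0, 0.5)`.
#' @param outlier_mode One of `"mean_shift"` (instance moved at least
#'   `4 * within_sd` from its class mean), `"label_flip"` (label inverted)
#'   or `"uniform_noise"` (features redrawn uniformly over `value_range`).
#' @param value_range Length-2 numeric `(low, high)`; generated values are
#'   clipped to this range.
#' @param integer_scale If `TRUE`, round features to integers for full
#'   fidelity with 10-point integer dialects.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 100, b = 9, class_separation = 4,
                           within_sd = 1, outlier_rate = 0.05,
                           outlier_mode = c("mean_shift", "label_flip",
                                            "uniform_noise"),
                           value_range = c(1, 10), integer_scale = FALSE,
                           seed = 1) {
  outlier_mode <- match.arg(outlier_mode)
  if (n_per_class < 2) stop("n_per_class must be >= 2")
  if (b < 1) stop("b must be >= 1")
  if (within_sd <= 0) stop("within_sd must be > 0")
  if (outlier_rate < 0 || outlier_rate >= 0.5) {
    stop("outlier_rate must be in [0, 0.5)")
  }
  if (length(value_range) != 2 || value_range[1] >= value_range[2]) {
    stop("value_range must be (low, high) with low < high")
  }
  structure(list(n_per_class = as.integer(n_per_class), b = as.integer(b),
                 class_separation = class_separation, within_sd = within_sd,
                 outlier_rate = outlier_rate, outlier_mode = outlier_mode,
                 value_range = value_range,
                 integer_scale = isTRUE(integer_scale),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic labeled data with planted outliers
#'
#' Draws two Gaussian classes (`benign` low, `malignant` high) whose mean
#' vectors are `class_separation` apart, clips values to the configured
#' range, then perturbs a fraction `outlier_rate` of instances according to
#' `outlier_mode`. Mean-shift outliers are placed `4.5 * within_sd` from
#' their class mean (toward the roomier side of each feature, so clipping
#' cannot pull them back under the guaranteed `4 * within_sd`).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_data` with elements `table` (a
#'   [labeled_table()]) and `truth` (logical mask, `TRUE` = planted
#'   outlier).
#' @examples
#' sd <- generate_synthetic(synthetic_spec(n_per_class = 20, seed = 7))
#' sum(sd$truth)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- 2L * spec$n_per_class
    b <- spec$b
    lo <- spec$value_range[1]
    hi <- spec$value_range[2]
    mid <- (lo + hi) / 2
    half <- spec$class_separation / (2 * sqrt(b))
    mu <- rbind(benign = rep(mid - half, b), malignant = rep(mid + half, b))
    labels <- factor(rep(c("benign", "malignant"), each = spec$n_per_class),
                     levels = c("benign", "malignant"))
    x <- matrix(stats::rnorm(n * b, sd = spec$within_sd), n, b) +
      mu[as.integer(labels), , drop = FALSE]

    n_out <- round(spec$outlier_rate * n)
    truth <- rep(FALSE, n)
    if (n_out > 0) {
      out_idx <- sample.int(n, n_out)
      truth[out_idx] <- TRUE
      if (spec$outlier_mode == "label_flip") {
        labels[out_idx] <- factor(
          ifelse(labels[out_idx] == "benign", "malignant", "benign"),
          levels = levels(labels))
      } else if (spec$outlier_mode == "uniform_noise") {
        x[out_idx, ] <- matrix(stats::runif(n_out * b, lo, hi), n_out, b)
      } else { # mean_shift
        step <- 4.5 * spec$within_sd / sqrt(b)
        for (i in out_idx) {
          m <- mu[as.integer(labels[i]), ]
          dir <- ifelse(hi - m >= m - lo, 1, -1)
          x[i, ] <- m + dir * step
        }
      }
    }
    x <- clip(x, lo, hi)
    if (spec$outlier_mode == "mean_shift" && n_out > 0) {
      # the placement guarantee refers to the continuous positions; integer
      # rounding below is a dialect-fidelity option and may move points by
      # up to 0.5 per feature
      shifted <- which(truth)
      d <- sqrt(rowSums((x[shifted, , drop = FALSE] -
                           mu[as.integer(labels[shifted]), , drop = FALSE])^2))
      if (any(d < 4 * spec$within_sd)) {
        stop("value_range too narrow to place mean_shift outliers ",
             ">= 4 within_sd from their class mean; widen value_range ",
             "or reduce within_sd")
      }
    }
    if (spec$integer_scale) x <- clip(round(x), lo, hi)
    tab <- labeled_table(x, labels,
                         feature_names = if (b == 9) wbcd_feature_names()
                                         else paste0("f", seq_len(b)),
                         instance_ids = sprintf("syn%04d", seq_len(n)))
    structure(list(table = tab, truth = truth, spec = spec),
              class = "synthetic_data")
  })
}

#' Write a labeled table in the Wisconsin breast cancer file dialect
#'
#' Emits `id,f1,...,f9,code` rows with class codes 2 (benign) and
#' 4 (malignant), so that [read_wbcd()] round-trips generated data. The
#' table must have exactly nine features and the benign/malignant label
#' set.
#'
#' @param table A [labeled_table()] with 9 features.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wbcd <- function(table, path) {
  if (n_features(table) != 9L) {
    stop("the WBCD dialect requires exactly 9 features, got ",
         n_features(table))
  }
  if (!all(levels(droplevels(table$labels)) %in% c("benign", "malignant"))) {
    stop("labels must be benign/malignant")
  }
  code <- ifelse(table$labels == "benign", 2L, 4L)
  vals <- apply(table$values, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = ","))
  writeLines(paste(table$instance_ids, vals, code, sep = ","), path)
  invisible(path)
}

#' Split a labeled table into train and test partitions
#'
#' @param table A [labeled_table()].
#' @param fraction Fraction of instances assigned to the test partition,
#'   in (0, 1).
#' @param stratified If `TRUE` (default) the split preserves class
#'   proportions to within one instance per class; every class then needs
#'   at least 2 instances.
#' @param seed Integer seed.
#' @return A list with `labeled_table` elements `train` and `test`; the two
#'   are disjoint and their union is the input.
#' @export
holdout_split <- function(table, fraction, stratified = TRUE, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- n_instances(table)
  if (n < 2) stop("need at least 2 instances to split")
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      counts <- table(table$labels)
      if (any(counts == 1)) {
        stop("stratified split requires >= 2 instances per class")
      }
      test_idx <- integer(0)
      for (cl in levels(table$labels)) {
        members <- which(table$labels == cl)
        k <- round(fraction * length(members))
        k <- max(min(k, length(members) - 1L), if (fraction * n >= 1) 1L else 0L)
        test_idx <- c(test_idx, sample(members, k))
      }
    } else {
      test_idx <- sample.int(n, max(1L, round(fraction * n)))
    }
  })
  list(train = subset_instances(table, setdiff(seq_len(n), test_idx)),
       test = subset_instances(table, sort(test_idx)))
}
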