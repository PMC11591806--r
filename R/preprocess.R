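#' Fit min-max normalization on a training table
#'
#' Stores the column-wise minimum and maximum of the training table only;
#' test data are later mapped through the same model (no leakage of test
#' statistics into the scaling).
#'
#' @param train A [labeled_table()].
#' @return An object of class `minmax_model` with numeric vectors `min`
#'   and `max`.
#' @export
fit_minmax <- function(train) {
  structure(list(min = apply(train$values, 2L, min),
                 max = apply(train$values, 2L, max)),
            class = "minmax_model")
}

#' Apply a fitted min-max model
#'
#' Each value is mapped to `(x - min) / (max - min)`. Constant training
#' features (max == min) map to 0, and out-of-range test values are
#' clipped so the output always lies in `[0, 1]`.
#'
#' @param model A [fit_minmax()] model.
#' @param table A [labeled_table()] with the model's feature count.
#' @return The rescaled `labeled_table`.
#' @export
apply_minmax <- function(model, table) {
  stopifnot(inherits(model, "minmax_model"))
  if (n_features(table) != length(model$min)) {
    stop("feature count mismatch: model has ", length(model$min),
         ", table has ", n_features(table))
  }
  rng <- model$max - model$min
  scaled <- sweep(table$values, 2L, model$min, "-")
  scaled <- sweep(scaled, 2L, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  labeled_table(clip(scaled, 0, 1), table$labels,
                feature_names = table$feature_names,
                instance_ids = table$instance_ids)
}

#' Shannon entropy of a label vector (bits)
#'
#' @param labels Non-empty categorical vector.
#' @return Entropy in bits, with `0 * log(0)` taken as 0.
#' @examples
#' shannon_entropy(c("a", "b")) # 1 bit
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for a label vector
#'
#' `IG = H(labels) - sum_v (n_v / n) H(labels | feature = v)` on discrete
#' feature values. Integer-valued features taking at most `bins` distinct
#' values are used as-is (the natural treatment for 10-point integer
#' scales); other features are discretized into `bins` equal-width bins
#' over their observed range.
#'
#' @param feature Numeric vector.
#' @param labels Categorical vector, same length.
#' @param bins Number of equal-width bins for continuous features (>= 2).
#' @return Information gain in bits (non-negative, at most `H(labels)`).
#' @export
information_gain <- function(feature, labels, bins = 10) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length")
  }
  if (bins < 2) stop("bins must be >= 2")
  v <- discretize_feature(feature, bins)
  labels <- factor(labels)
  h <- shannon_entropy(labels)
  cond <- 0
  for (val in unique(v)) {
    sel <- v == val
    cond <- cond + mean(sel) * shannon_entropy(labels[sel])
  }
  max(h - cond, 0)
}

discretize_feature <- function(feature, bins) {
  ux <- unique(feature)
  if (all(feature == round(feature)) && length(ux) <= bins) {
    return(as.character(feature))
  }
  rng <- range(feature)
  if (rng[1] == rng[2]) return(rep("bin1", length(feature)))
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  as.character(cut(feature, breaks = breaks, include.lowest = TRUE,
                   labels = FALSE))
}

#' Rank and select features by information gain
#'
#' Features are ranked by information gain (descending, ties broken by
#' original column order). Selection follows the policy: `"top_k"` keeps
#' the `top_k` best; `"above_mean"` keeps all features whose gain strictly
#' exceeds the mean gain, falling back to all features when none does
#' (e.g. all-equal gains), so the selection is never empty.
#'
#' @param train A [labeled_table()] with at least two instances and two
#'   classes.
#' @param policy `"above_mean"` (default) or `"top_k"`.
#' @param top_k Number of features to keep under the `top_k` policy.
#' @param bins Passed to [information_gain()].
#' @return An object of class `feature_ranking`: named `gains`, `ranking`
#'   (column indices, best first), `selected` (column indices, best
#'   first), `policy`, `bins`.
#' @export
select_features <- function(train, policy = c("above_mean", "top_k"),
                            top_k = NULL, bins = 10) {
  policy <- match.arg(policy)
  check_two_classes(train)
  if (n_instances(train) < 2) stop("need at least 2 instances")
  b <- n_features(train)
  gains <- vapply(seq_len(b), function(j)
    information_gain(train$values[, j], train$labels, bins), numeric(1))
  names(gains) <- train$feature_names
  ranking <- order(-gains, seq_len(b))
  if (policy == "top_k") {
    if (is.null(top_k)) stop("top_k must be given for the top_k policy")
    if (top_k < 1 || top_k > b) {
      stop("top_k must be between 1 and the number of features (", b, ")")
    }
    selected <- ranking[seq_len(top_k)]
  } else {
    above <- gains > mean(gains)
    selected <- if (any(above)) ranking[above[ranking]] else ranking
  }
  structure(list(gains = gains, ranking = ranking, selected = selected,
                 policy = policy, bins = bins),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking> policy=", x$policy, "; selected ",
      length(x$selected), "/", length(x$gains), " features\n", sep = "")
  print(round(sort(x$gains, decreasing = TRUE), 4))
  invisible(x)
}
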