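#' Train the majority-vote ensemble
#'
#' Fits the three base classifiers on the same training table: a Gaussian
#' naive Bayes model, a k-nearest-neighbour classifier (Euclidean,
#' deterministic tie handling) and a kernel support-vector machine. At
#' prediction time the modal label of the three base votes wins; with two
#' classes and three voters no tie can occur, and `tie_order` resolves
#' ties in more general configurations.
#'
#' @param train A [labeled_table()] with at least two classes and
#'   `n > knn_k` instances.
#' @param knn_k Neighbourhood size of the KNN voter (default 5).
#' @param svm_kernel,svm_cost Kernel name and regularization cost of the
#'   SVM voter (defaults: radial, 1).
#' @param tie_order Optional character vector of class labels, highest
#'   priority first.
#' @return An object of class `ecm_model`.
#' @export
train_ecm <- function(train, knn_k = 5, svm_kernel = "radial", svm_cost = 1,
                      tie_order = NULL) {
  check_two_classes(train)
  labels <- droplevels(train$labels)
  if (n_instances(train) <= knn_k) {
    stop("training size (", n_instances(train),
         ") must exceed knn_k (", knn_k, ")")
  }
  if (is.null(tie_order)) tie_order <- levels(labels)
  if (!setequal(tie_order, levels(labels))) {
    stop("tie_order must permute the class labels")
  }
  df <- as.data.frame(train$values)
  nb <- e1071::naiveBayes(x = df, y = labels)
  svm <- e1071::svm(x = train$values, y = labels, kernel = svm_kernel,
                    cost = svm_cost, scale = FALSE)
  structure(list(nb = nb, svm = svm,
                 knn = list(x = train$values, y = labels, k = knn_k),
                 tie_order = tie_order,
                 feature_names = train$feature_names),
            class = "ecm_model")
}

#' Predict with the ensemble (majority vote)
#'
#' @param object An [train_ecm()] model.
#' @param table A [labeled_table()] (or numeric matrix) with the training
#'   feature count.
#' @param ... Unused.
#' @return Factor of predicted labels; the individual base predictions
#'   are attached as the `"base_predictions"` attribute (a data frame
#'   with columns `nb`, `knn`, `svm`).
#' @export
predict.ecm_model <- function(object, table, ...) {
  x <- if (inherits(table, "labeled_table")) table$values else as.matrix(table)
  if (ncol(x) != ncol(object$knn$x)) {
    stop("feature count mismatch: model has ", ncol(object$knn$x),
         ", input has ", ncol(x))
  }
  df <- as.data.frame(x)
  names(df) <- names(as.data.frame(object$knn$x))
  nb_pred <- stats::predict(object$nb, df)
  knn_pred <- knn_from_dist(euclidean_cross(x, object$knn$x),
                            object$knn$y, object$knn$k, object$tie_order)
  svm_pred <- stats::predict(object$svm, x)
  base <- data.frame(nb = nb_pred, knn = knn_pred, svm = svm_pred)
  lv <- levels(object$knn$y)
  votes <- sapply(lv, function(cl) rowSums(base == cl))
  votes <- matrix(votes, ncol = length(lv),
                  dimnames = list(NULL, lv))
  priority <- match(lv, object$tie_order) * 1e-6
  win <- max.col(sweep(votes, 2L, priority, "-"), ties.method = "first")
  out <- factor(lv[win], levels = lv)
  attr(out, "base_predictions") <- base
  out
}

#' Confusion matrix for a binary decision
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The positive class (default `"malignant"`, the
#'   clinically standard choice for tumour diagnosis).
#' @return An object of class `confusion_matrix` with integer counts
#'   `TP`, `TN`, `FP`, `FN` and the `positive` label.
#' @export
confusion_matrix <- function(y_true, y_pred, positive = "malignant") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> positive=", x$positive, "\n", sep = "")
  print(matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
               dimnames = list(truth = c("pos", "neg"),
                               predicted = c("pos", "neg"))))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/total`, error `1 - accuracy` and F1 `2PR/(P+R)`. A zero
#' denominator defines the corresponding metric (and then F1) as 0, with
#' a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report` with elements `precision`,
#'   `recall`, `accuracy`, `error`, `f1`, all proportions in [0, 1].
#' @seealso [metrics_percent()] for the truncated-percentage rendering.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; defining it as 0")
      0
    } else num / den
  }
  p <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  r <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  acc <- (cm$TP + cm$TN) / total
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, accuracy = acc,
                 error = 1 - acc, f1 = f1),
            class = "metrics_report")
}

#' Render a metrics report as truncated percentages
#'
#' Percentages are truncated (not rounded) to `digits` decimals, the
#' convention used in published comparison tables (94.29995 -> 94.299).
#'
#' @param m A `metrics_report` (or any named list of proportions).
#' @param digits Decimals kept (default 3).
#' @return Named numeric vector of percentages.
#' @export
metrics_percent <- function(m, digits = 3) {
  vapply(unclass(m), function(v) pct_truncate(100 * v, digits), numeric(1))
}

#' @export
print.metrics_report <- function(x, ...) {
  print(round(metrics_percent(x), 3))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals its members across the folds with a
#' running offset, so fold sizes differ by at most one overall and each
#' class is spread within one instance across folds.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per instance.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- droplevels(factor(labels))
  if (any(table(labels) < k)) {
    stop("every class needs at least ", k, " instances for ", k, " folds")
  }
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (cl in levels(labels)) {
      members <- sample(which(labels == cl))
      fold[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
      offset <- offset + length(members)
    }
  })
  fold
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold protocol. Per fold, the entire training pipeline runs
#' with no test-fold leakage: min-max normalization is fitted on the
#' training fold and applied to both folds, information-gain feature
#' selection and CORT outlier rejection operate on the training fold only,
#' the ensemble is trained on the cleaned training fold, and the held-out
#' fold is predicted.
#'
#' @param table A [labeled_table()].
#' @param config A [pipeline_config()].
#' @return An object of class `cv_report`: `folds` (per-fold confusion
#'   counts, metrics, selected features, rejection counts),
#'   `mean_metrics` (arithmetic mean over folds), `fold_assignment`,
#'   `seed`, `config`.
#' @export
cross_validate <- function(table, config = pipeline_config()) {
  check_two_classes(table)
  k <- config$cv_folds
  fold <- stratified_folds(table$labels, k, config$seed)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- subset_instances(table, fold != f)
    test <- subset_instances(table, fold == f)
    if (config$normalize) {
      mm <- fit_minmax(train)
      train <- apply_minmax(mm, train)
      test <- apply_minmax(mm, test)
    }
    rank <- select_features(train, policy = config$ig$policy,
                            top_k = config$ig$top_k, bins = config$ig$bins)
    train <- subset_features(train, sort(rank$selected))
    test <- subset_features(test, sort(rank$selected))
    cres <- cort_reject(train, config, seed = config$seed + f)
    clean <- subset_instances(train, cres$kept)
    model <- train_ecm(clean, knn_k = config$ecm$knn_k,
                       svm_kernel = config$ecm$svm_kernel,
                       svm_cost = config$ecm$svm_cost,
                       tie_order = config$ecm$tie_order)
    pred <- stats::predict(model, test)
    cm <- confusion_matrix(test$labels, pred)
    folds[[f]] <- list(
      fold = f,
      n_train = n_instances(train), n_test = n_instances(test),
      selected_features = train$feature_names[sort(rank$selected)],
      gains = rank$gains,
      cort_counts = cres$counts,
      confusion = cm,
      metrics = classification_metrics(cm))
  }
  metric_names <- c("precision", "recall", "accuracy", "error", "f1")
  mean_metrics <- structure(as.list(colMeans(do.call(
    rbind, lapply(folds, function(fl) unlist(fl$metrics[metric_names]))))),
    class = "metrics_report")
  structure(list(folds = folds, mean_metrics = mean_metrics,
                 fold_assignment = fold, seed = config$seed,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  pc <- metrics_percent(x$mean_metrics)
  cat("<cv_report> ", length(x$folds), "-fold cross-validation\n", sep = "")
  cat(sprintf("  accuracy %.3f%%  precision %.3f%%  recall %.3f%%  error %.3f%%  F1 %.3f%%\n",
              pc["accuracy"], pc["precision"], pc["recall"],
              pc["error"], pc["f1"]))
  invisible(x)
}
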