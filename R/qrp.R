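#' Fit per-class mean / standard-deviation profiles
#'
#' For every observed class, computes the feature-wise mean vector and
#' sample standard deviation (denominator `d - 1`). Standard-deviation
#' components below `sd_epsilon` are floored at `sd_epsilon`, and
#' single-member classes get `sd_epsilon` throughout, so downstream
#' standardized deviations are always finite.
#'
#' @param train A [labeled_table()]; every observed class needs at least
#'   one member.
#' @param sd_epsilon Small positive floor for standard deviations.
#' @return An object of class `class_profiles`: a named list with one
#'   profile per class, each holding `label`, `mu`, `sigma`, `d`.
#' @export
fit_class_profiles <- function(train, sd_epsilon = 1e-8) {
  if (sd_epsilon <= 0) stop("sd_epsilon must be positive")
  labs <- droplevels(train$labels)
  profiles <- lapply(levels(labs), function(cl) {
    rows <- train$values[labs == cl, , drop = FALSE]
    d <- nrow(rows)
    if (d == 0L) stop("class '", cl, "' has no members")
    mu <- colMeans(rows)
    sigma <- if (d == 1L) rep(sd_epsilon, ncol(rows))
             else pmax(apply(rows, 2L, stats::sd), sd_epsilon)
    list(label = cl, mu = mu, sigma = sigma, d = d)
  })
  names(profiles) <- levels(labs)
  structure(profiles, class = "class_profiles", sd_epsilon = sd_epsilon)
}

#' Class-conditional deviation score of an instance
#'
#' The per-feature absolute deviations of the instance from the class mean,
#' divided by the class standard deviation (`standardized`, the default) or
#' left raw (`literal`), aggregated to one scalar by the mean over
#' features. An instance equal to the class mean scores 0.
#'
#' @param instance Numeric feature vector.
#' @param profile One element of [fit_class_profiles()].
#' @param mode `"standardized"` or `"literal"`.
#' @return Non-negative scalar score.
#' @export
deviation_score <- function(instance, profile,
                            mode = c("standardized", "literal")) {
  mode <- match.arg(mode)
  if (length(instance) != length(profile$mu)) {
    stop("instance length must equal the profile's feature count")
  }
  dev <- abs(instance - profile$mu)
  if (mode == "standardized") dev <- dev / profile$sigma
  mean(dev)
}

#' Global rejection threshold
#'
#' Each class contributes the mean (over its members) of the
#' feature-aggregated absolute deviation from the class mean --
#' sigma-standardized in `standardized` mode (default, dimensionally
#' consistent with the instance scores) or raw in `literal` mode. The
#' global threshold is the sum of the per-class contributions over all
#' classes, so it grows with the number of classes.
#'
#' @param train A [labeled_table()].
#' @param profiles [fit_class_profiles()] covering all observed classes.
#' @param mode `"standardized"` or `"literal"`.
#' @return Non-negative scalar threshold `trd`.
#' @export
rejection_threshold <- function(train, profiles,
                                mode = c("standardized", "literal")) {
  mode <- match.arg(mode)
  labs <- droplevels(train$labels)
  stopifnot(all(levels(labs) %in% names(profiles)))
  per_class <- vapply(levels(labs), function(cl) {
    rows <- which(labs == cl)
    mean(vapply(rows, function(i)
      deviation_score(train$values[i, ], profiles[[cl]], mode), numeric(1)))
  }, numeric(1))
  sum(per_class)
}

#' Quick rejection phase: standard-deviation outlier filter
#'
#' Scores every training instance against its own class profile
#' (standardized absolute deviation, averaged over features) and rejects
#' instances whose score strictly exceeds the global threshold `trd`;
#' ties are kept. In `literal` threshold mode the threshold side uses raw
#' (unstandardized) mean deviations while scores remain standardized. If a
#' class would lose all members, its lowest-scoring instance is retained
#' with a warning.
#'
#' @param train A [labeled_table()] with at least 2 instances per class.
#' @param sd_epsilon Floor for per-feature standard deviations.
#' @param threshold_mode `"standardized"` (default) or `"literal"`.
#' @return An object of class `qrp_result`: `scores`, `trd`, `kept`,
#'   `rejected` (index vectors into `train`), `profiles`, `threshold_mode`.
#' @examples
#' lt <- labeled_table(matrix(c(0, 0.1, -0.1, 5)), rep("a", 4))
#' qrp_filter(lt)$rejected # the instance at 5
#' @export
qrp_filter <- function(train, sd_epsilon = 1e-8,
                       threshold_mode = c("standardized", "literal")) {
  threshold_mode <- match.arg(threshold_mode)
  labs <- droplevels(train$labels)
  if (any(table(labs) < 2)) {
    stop("qrp_filter requires at least 2 instances per class")
  }
  profiles <- fit_class_profiles(train, sd_epsilon)
  n <- n_instances(train)
  scores <- vapply(seq_len(n), function(i)
    deviation_score(train$values[i, ], profiles[[as.character(labs[i])]]),
    numeric(1))
  trd <- rejection_threshold(train, profiles, threshold_mode)
  rejected <- which(scores > trd)
  for (cl in levels(labs)) {
    members <- which(labs == cl)
    if (all(members %in% rejected)) {
      keep_back <- members[which.min(scores[members])]
      warning("qrp_filter would reject every instance of class '", cl,
              "'; retaining its lowest-scoring instance")
      rejected <- setdiff(rejected, keep_back)
    }
  }
  structure(list(scores = scores, trd = trd,
                 kept = setdiff(seq_len(n), rejected), rejected = rejected,
                 profiles = profiles, threshold_mode = threshold_mode),
            class = "qrp_result")
}

#' @export
print.qrp_result <- function(x, ...) {
  cat("<qrp_result> trd=", signif(x$trd, 5), "; rejected ",
      length(x$rejected), "/", length(x$scores), " instances\n", sep = "")
  invisible(x)
}
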