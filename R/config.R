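#' Pipeline configuration
#'
#' One declarative object holding every tunable of the pipeline. Partial
#' lists are merged over the defaults, so
#' `pipeline_config(bhho = list(it_max = 100))` changes only that field.
#'
#' Sections:
#' * `normalize` — fit min-max scaling on the training fold and apply it to
#'   both folds (default `TRUE`).
#' * `ig` — feature-selection policy: `policy` one of `"above_mean"`
#'   (keep features whose information gain strictly exceeds the mean gain)
#'   or `"top_k"` (keep the `top_k` best); `bins` equal-width bins used to
#'   discretize continuous features.
#' * `qrp` — quick rejection phase: `threshold_mode` `"standardized"`
#'   (sigma-weighted threshold, default) or `"literal"` (raw mean absolute
#'   deviation threshold); `sd_epsilon` floor for zero-variance features.
#' * `bhho` — optimizer: `pop_size`, `it_max`, continuous bounds
#'   `lb`/`ub`, Levy exponent `levy_beta`, fitness weights `alpha`/`delta`
#'   (must sum to 1), `fitness_knn_k` for the leave-one-out evaluator and
#'   `subset_penalty` (see [fitness_spec()]).
#' * `ecm` — ensemble: `knn_k`, `svm_kernel`, `svm_cost`, optional
#'   `tie_order` of class labels for vote ties.
#' * `cv_folds`, `seed` — evaluation protocol.
#'
#' @param normalize Logical flag.
#' @param ig,qrp,bhho,ecm Named lists overriding section defaults.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(bhho = list(it_max = 20), cv_folds = 3)
#' cfg$bhho$it_max
#' @export
pipeline_config <- function(normalize = TRUE,
                            ig = list(),
                            qrp = list(),
                            bhho = list(),
                            ecm = list(),
                            cv_folds = 5,
                            seed = 42) {
  defaults <- list(
    ig = list(policy = "above_mean", top_k = NULL, bins = 10),
    qrp = list(threshold_mode = "standardized", sd_epsilon = 1e-8),
    bhho = list(pop_size = 10, it_max = 50, lb = -4, ub = 4,
                levy_beta = 1.5, alpha = 0.99, delta = 0.01,
                fitness_knn_k = 5, subset_penalty = "rejected_fraction"),
    ecm = list(knn_k = 5, svm_kernel = "radial", svm_cost = 1,
               tie_order = NULL)
  )
  cfg <- list(
    normalize = isTRUE(normalize),
    ig = utils::modifyList(defaults$ig, as.list(ig), keep.null = TRUE),
    qrp = utils::modifyList(defaults$qrp, as.list(qrp)),
    bhho = utils::modifyList(defaults$bhho, as.list(bhho)),
    ecm = utils::modifyList(defaults$ecm, as.list(ecm), keep.null = TRUE),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (bhho$pop_size < 2) stop("bhho$pop_size must be >= 2")
    if (bhho$it_max < 1) stop("bhho$it_max must be >= 1")
    if (bhho$lb >= bhho$ub) stop("bhho bounds require lb < ub")
    if (bhho$levy_beta <= 0) stop("bhho$levy_beta must be > 0")
    if (bhho$alpha < 0 || bhho$alpha > 1) stop("bhho$alpha must be in [0,1]")
    if (abs(bhho$alpha + bhho$delta - 1) > 1e-9) {
      stop("bhho alpha + delta must equal 1")
    }
    if (bhho$fitness_knn_k < 1) stop("bhho$fitness_knn_k must be >= 1")
    if (cv_folds < 2) stop("cv_folds must be >= 2")
    if (qrp$sd_epsilon <= 0) stop("qrp$sd_epsilon must be positive")
    if (!qrp$threshold_mode %in% c("standardized", "literal")) {
      stop("qrp$threshold_mode must be 'standardized' or 'literal'")
    }
    if (!ig$policy %in% c("above_mean", "top_k")) {
      stop("ig$policy must be 'above_mean' or 'top_k'")
    }
    if (ig$policy == "top_k" && is.null(ig$top_k)) {
      stop("ig$top_k required when policy is 'top_k'")
    }
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may contain any subset of the [pipeline_config()] arguments;
#' missing values take the defaults and the result is validated.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}
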