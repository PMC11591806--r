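#' Fitness weighting for the accurate rejection phase
#'
#' The subset fitness is `alpha * gamma + delta * penalty`, where `gamma`
#' is the leave-one-out error of a k-nearest-neighbour evaluator on the
#' selected instances R out of N candidates. `alpha` weights classification
#' error and `delta = 1 - alpha` weights the subset-size penalty; the
#' defaults (0.99 / 0.01) put almost all pressure on consistency of the
#' kept set.
#'
#' Two penalty directions are offered. The default,
#' `"rejected_fraction"` (`penalty = (|N| - |R|) / |N|`), is the instance-
#' selection reading: discarding data costs, so among equally consistent
#' subsets the largest wins and only instances that raise the evaluator's
#' error (outliers) are worth rejecting. `"kept_fraction"`
#' (`penalty = |R| / |N|`) is the transliteration of the wrapper
#' feature-selection fitness this weighting originates from; it rewards
#' small subsets and turns the search into prototype selection rather
#' than outlier rejection, so it is not the default.
#'
#' @param alpha Error weight in [0, 1] (default 0.99).
#' @param delta Penalty weight (default `1 - alpha`).
#' @param knn_k Neighbourhood size of the internal evaluator (default 5).
#' @param subset_penalty `"rejected_fraction"` (default) or
#'   `"kept_fraction"`; see Details.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha = 0.99, delta = 1 - alpha, knn_k = 5,
                         subset_penalty = c("rejected_fraction",
                                            "kept_fraction")) {
  subset_penalty <- match.arg(subset_penalty)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (abs(alpha + delta - 1) > 1e-9) stop("alpha + delta must equal 1")
  if (knn_k < 1) stop("knn_k must be >= 1")
  structure(list(alpha = alpha, delta = delta, knn_k = as.integer(knn_k),
                 subset_penalty = subset_penalty),
            class = "fitness_spec")
}

#' Instance-subset fitness (lower is better)
#'
#' Evaluates a binary keep/drop mask over candidate training instances.
#' `gamma` is the error, over all `N` candidates, of the
#' k-nearest-neighbour classifier induced by the selected set R
#' (Euclidean distance on the current feature set): every candidate is
#' classified by its `knn_k` nearest selected instances, itself excluded
#' when selected, so for `R = N` this is exactly the leave-one-out error
#' of the selection. Scoring all candidates — not only the kept ones —
#' means a mask cannot lower `gamma` simply by discarding
#' hard-to-classify instances; rejection pays only when the removed
#' instance was corrupting its neighbours' classification, which is what
#' distinguishes an outlier from a boundary point. The fitness is
#' `alpha * gamma + delta * penalty` (see [fitness_spec()] for the two
#' penalty directions). Masks that are too small to evaluate
#' (`|R| < knn_k + 1`) or that lose a class entirely are invalid and
#' score `Inf`.
#'
#' @param mask Integer/logical 0-1 vector, one bit per candidate
#'   (1 = keep).
#' @param candidates A [labeled_table()] of candidate instances.
#' @param spec A [fitness_spec()].
#' @return Scalar fitness.
#' @examples
#' lt <- generate_synthetic(synthetic_spec(n_per_class = 10,
#'                                         outlier_rate = 0))$table
#' instance_fitness(rep(1, 20), lt)
#' @export
instance_fitness <- function(mask, candidates, spec = fitness_spec()) {
  make_instance_fitness(candidates, spec)(mask)
}

#' @rdname instance_fitness
#' @return `make_instance_fitness` returns a function `mask -> fitness`
#'   with the candidate distance matrix precomputed (the form handed to
#'   the optimizer).
#' @export
make_instance_fitness <- function(candidates, spec = fitness_spec()) {
  stopifnot(inherits(spec, "fitness_spec"))
  D <- as.matrix(stats::dist(candidates$values))
  labels <- droplevels(candidates$labels)
  n_classes <- nlevels(labels)
  n <- length(labels)
  k <- spec$knn_k
  function(mask) {
    if (length(mask) != n) stop("mask length must equal the candidate count")
    sel <- which(as.integer(mask) == 1L)
    if (length(sel) < k + 1L) return(Inf)
    if (length(unique(labels[sel])) < n_classes) return(Inf)
    gamma <- induced_knn_error(D, labels, sel, k)
    kept_frac <- length(sel) / n
    penalty <- if (spec$subset_penalty == "kept_fraction") kept_frac
               else 1 - kept_frac
    spec$alpha * gamma + spec$delta * penalty
  }
}

#' Combined outlier rejection (quick + accurate phases)
#'
#' Runs the full two-phase training-set cleaner. The quick rejection phase
#' ([qrp_filter()]) removes instances whose class-conditional deviation
#' score exceeds the global threshold; the survivors become the candidate
#' set of the accurate rejection phase, where [bhho_optimize()] searches
#' over keep/drop masks (one bit per surviving instance) minimizing
#' [instance_fitness()]. The all-ones mask is seeded into the initial
#' population, so the result is never worse than keeping every survivor.
#'
#' @param train A [labeled_table()] with two or more classes.
#' @param config A [pipeline_config()] (its `qrp` and `bhho` sections are
#'   used).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An object of class `cort_result`: `qrp` ([qrp_filter()]
#'   result), `bhho` ([bhho_optimize()] result), `kept` (final kept row
#'   indices into `train`), `kept_ids`, and `counts` (`tm` training
#'   instances, `out` quick rejections, `rest` candidates, `ins` final
#'   kept).
#' @export
cort_reject <- function(train, config = pipeline_config(),
                        seed = config$seed) {
  check_two_classes(train)
  q <- qrp_filter(train, sd_epsilon = config$qrp$sd_epsilon,
                  threshold_mode = config$qrp$threshold_mode)
  rest_idx <- q$kept
  k <- config$bhho$fitness_knn_k
  if (length(rest_idx) < k + 2L) {
    stop("only ", length(rest_idx), " instances survive the quick phase; ",
         "need at least fitness_knn_k + 2 = ", k + 2L,
         " for the accurate phase")
  }
  cand <- subset_instances(train, rest_idx)
  spec <- fitness_spec(alpha = config$bhho$alpha, delta = config$bhho$delta,
                       knn_k = k,
                       subset_penalty = config$bhho$subset_penalty)
  fit_fn <- make_instance_fitness(cand, spec)
  ctrl <- bhho_control(pop_size = config$bhho$pop_size,
                       it_max = config$bhho$it_max,
                       lb = config$bhho$lb, ub = config$bhho$ub,
                       levy_beta = config$bhho$levy_beta)
  b <- bhho_optimize(fit_fn, dim = length(rest_idx), control = ctrl,
                     seed = seed,
                     init_bits = matrix(1L, 1L, length(rest_idx)))
  kept <- rest_idx[b$best_bits == 1L]
  structure(list(
    qrp = q, bhho = b, kept = kept,
    kept_ids = train$instance_ids[kept],
    counts = list(tm = n_instances(train),
                  out = length(q$rejected),
                  rest = length(rest_idx),
                  ins = length(kept))),
    class = "cort_result")
}

#' @export
print.cort_result <- function(x, ...) {
  with(x$counts, cat("<cort_result> tm=", tm, " -> quick phase rejected ",
                     out, " -> accurate phase kept ", ins, "/", rest,
                     "\n", sep = ""))
  invisible(x)
}
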