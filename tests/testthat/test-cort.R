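test_that("invalid masks are fenced off with infinite fitness", {
  tab <- make_separable_table(n_per_class = 8)
  spec <- fitness_spec(knn_k = 3)
  expect_equal(instance_fitness(rep(0L, 16), tab, spec), Inf)
  expect_equal(instance_fitness(c(rep(1L, 3), rep(0L, 13)), tab, spec), Inf)
  # all kept from one class only
  one_class <- c(rep(1L, 8), rep(0L, 8))
  expect_equal(instance_fitness(one_class, tab, spec), Inf)
  expect_error(instance_fitness(rep(1L, 5), tab, spec), "mask length")
})

test_that("the worked fitness values hold under the printed penalty form", {
  tab <- make_separable_table(n_per_class = 10)
  spec <- fitness_spec(knn_k = 5, subset_penalty = "kept_fraction")
  # separable, all selected: gamma = 0, penalty = |R|/|N| = 1
  expect_equal(instance_fitness(rep(1L, 20), tab, spec), 0.01)
  # and under the default direction the same mask costs nothing
  expect_equal(instance_fitness(rep(1L, 20), tab, fitness_spec(knn_k = 5)), 0)
  # direct arithmetic of the weighting: gamma=0.05, penalty=0.5
  expect_equal(0.99 * 0.05 + 0.01 * 0.5, 0.0545)
})

test_that("the induced-error evaluator agrees with class::knn.cv when all
           candidates are selected", {
  tab <- make_separable_table(n_per_class = 15, gap = 2, sd = 1, seed = 9)
  spec <- fitness_spec(knn_k = 5)
  fit_all <- instance_fitness(rep(1L, 30), tab, spec)
  # with R = N the induced error is the leave-one-out error; continuous
  # features make distance ties a measure-zero event, so knn.cv is exact
  pred <- class::knn.cv(tab$values, tab$labels, k = 5)
  gamma_oracle <- mean(pred != tab$labels)
  expect_equal(fit_all, 0.99 * gamma_oracle, tolerance = 1e-12)
})

test_that("cort removes planted outliers and keeps the bulk of clean data", {
  sim <- generate_synthetic(synthetic_spec(n_per_class = 60, b = 5,
                                           outlier_rate = 0.05, seed = 11))
  res <- cort_reject(sim$table, pipeline_config(), seed = 11)
  planted <- which(sim$truth)
  expect_length(intersect(planted, res$kept), 0L)
  # elitism with the seeded all-ones mask: never worse than keeping all
  cand <- subset_instances(sim$table, res$qrp$kept)
  all_ones <- instance_fitness(rep(1L, res$counts$rest), cand)
  expect_lte(res$bhho$best_fitness, all_ones)
  # bookkeeping identities
  expect_equal(res$counts$rest, res$counts$tm - res$counts$out)
  expect_equal(res$counts$ins, length(res$kept))
  expect_true(all(res$kept %in% res$qrp$kept))
  # reproducibility
  res2 <- cort_reject(sim$table, pipeline_config(), seed = 11)
  expect_identical(res$kept, res2$kept)
  expect_identical(res$bhho$trace, res2$bhho$trace)
})

test_that("on separable outlier-free data the accurate phase keeps everything", {
  tab <- make_separable_table(n_per_class = 12, gap = 10, sd = 0.4, seed = 2)
  res <- cort_reject(tab, fast_config(), seed = 5)
  # the quick phase may trim extreme tail draws; the accurate phase has no
  # reason to reject anything on separable candidates
  expect_equal(res$counts$ins, res$counts$rest)
  # gamma = 0 and nothing rejected beyond the quick phase: fitness exactly 0
  expect_equal(res$bhho$best_fitness, 0)
})

test_that("small-candidate runs reach the exhaustive optimum in most seeds", {
  tab <- make_separable_table(n_per_class = 5, gap = 3, sd = 1.2, seed = 13)
  spec <- fitness_spec(knn_k = 3)
  # the accurate phase searches over quick-phase survivors; brute-force the
  # same candidate set
  cand <- subset_instances(tab, qrp_filter(tab)$kept)
  fit_fn <- make_instance_fitness(cand, spec)
  masks <- as.matrix(expand.grid(rep(list(0:1), n_instances(cand))))
  best <- min(apply(masks, 1, fit_fn))
  cfg <- pipeline_config(bhho = list(it_max = 200, fitness_knn_k = 3))
  hits <- vapply(1:5, function(s) {
    r <- cort_reject(tab, cfg, seed = s)
    abs(r$bhho$best_fitness - best) < 1e-12
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("label-flipped instances are rejected at a higher rate than clean ones", {
  flip_rate <- clean_rate <- numeric(8)
  cfg <- pipeline_config(bhho = list(it_max = 25))
  for (s in 1:8) {
    sim <- generate_synthetic(synthetic_spec(
      n_per_class = 40, b = 5, outlier_rate = 0.1,
      outlier_mode = "label_flip", seed = 100 + s))
    res <- cort_reject(sim$table, cfg, seed = 100 + s)
    flipped <- which(sim$truth)
    clean <- setdiff(seq_len(80), flipped)
    flip_rate[s] <- mean(!flipped %in% res$kept)
    clean_rate[s] <- mean(!clean %in% res$kept)
  }
  expect_gt(mean(flip_rate), mean(clean_rate))
})

test_that("the accurate phase needs enough quick-phase survivors", {
  tiny <- make_separable_table(n_per_class = 3)
  expect_error(cort_reject(tiny, pipeline_config(), seed = 1),
               "fitness_knn_k")
})
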