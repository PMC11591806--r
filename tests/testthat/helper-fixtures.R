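# Shared fixtures, all built in code.

# tiny two-class 2-D table, linearly separable with a wide margin
make_separable_table <- function(n_per_class = 10, gap = 8, sd = 0.5,
                                 seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(2 * n_per_class, mean = 0, sd = sd), ncol = 2),
      matrix(rnorm(2 * n_per_class, mean = gap, sd = sd), ncol = 2))
    labeled_table(x, rep(c("benign", "malignant"), each = n_per_class))
  })
}

# write a small WBCD-dialect file and return its path
write_wbcd_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.data")
  writeLines(lines, path)
  path
}

toy_wbcd_lines <- c(
  "1,1,1,1,1,1,1,1,1,1,2",
  "2,5,5,5,5,5,?,5,5,5,4",
  "3,9,9,9,9,9,9,9,9,9,4")

# a config scaled for fast unit tests
fast_config <- function(...) {
  pipeline_config(bhho = list(it_max = 15, fitness_knn_k = 3),
                  ecm = list(knn_k = 3), ...)
}
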