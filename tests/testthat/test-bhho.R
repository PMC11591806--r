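test_that("escape energy follows the linear envelope", {
  expect_equal(escape_energy(0.7, 100, 100), 0)
  expect_equal(escape_energy(1, 0, 100), 2)
  expect_equal(escape_energy(-0.8, 75, 100), -0.4)
  # envelope bound |G| <= 2|G0|(1 - J/it_max) holds with equality here
  withr::with_seed(1, {
    for (i in 1:50) {
      g0 <- runif(1, -1, 1); j <- sample(0:100, 1)
      expect_lte(abs(escape_energy(g0, j, 100)),
                 2 * abs(g0) * (1 - j / 100) + 1e-12)
    }
  })
})

test_that("mean position is the per-dimension average", {
  same <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  expect_equal(mean_position(same), c(1, 2, 3))
  expect_equal(mean_position(matrix(c(0, 1))), 0.5)
  withr::with_seed(2, {
    X <- matrix(runif(12), 4, 3)
    expect_equal(mean_position(X), apply(X, 2, mean))
  })
})

test_that("exploration step matches the two update branches", {
  d <- function(p, r1 = 0, r2 = 0, r3 = 0, r4 = 0)
    list(p = p, r1 = r1, r2 = r2, r3 = r3, r4 = r4)
  # p >= 0.5 with r1 = 0 lands on the random hawk
  expect_equal(exploration_step(2, 1, 9, 9, -10, 10, d(0.9)), 1)
  # p < 0.5 with r3 = 0 lands on prey minus mean
  expect_equal(exploration_step(2, 1, 5, 3, -10, 10, d(0.1)), 2)
  # hand-traced: x=2, x_rand=1, r1=0.5, r2=0.25 -> 1 - 0.5*|1 - 1| = 1
  expect_equal(exploration_step(2, 1, 9, 9, -10, 10, d(0.9, r1 = 0.5, r2 = 0.25)), 1)
  # clipping
  expect_equal(exploration_step(2, 1, 5, 3, -10, 0.5, d(0.1)), 0.5)
})

test_that("siege steps match direct arithmetic", {
  expect_equal(soft_siege_step(0, 1, 0, 1, -10, 10), 1) # G=0 -> delta X
  expect_equal(soft_siege_step(0, 1, 0.5, 1, -10, 10), 0.5)
  expect_equal(hard_siege_step(3, 3, 0.7, -10, 10), 3) # at the prey
  expect_equal(hard_siege_step(2, 0, 0, -10, 10), 2)   # G=0 -> unchanged
  expect_equal(hard_siege_step(2, 0, 0.4, -10, 10), 1.2)
})

test_that("Levy flight uses the closed-form sigma and scales linearly in u", {
  expect_equal(levy_sigma(1.5), 0.6965745, tolerance = 1e-6)
  lv <- levy_flight(5, 1.5, u = rep(1, 5), v = rep(1, 5))
  expect_length(lv, 5)
  expect_equal(levy_flight(5, 1.5, u = rep(2, 5), v = rep(1, 5)), 2 * lv)
  expect_equal(lv, rep(0.01 * 0.6965745, 5), tolerance = 1e-6)
})

test_that("sigmoid transfer and stochastic binarization obey the threshold rule", {
  expect_equal(sigmoid_transfer(0), 0.5)
  expect_equal(sigmoid_transfer(4), 0.9820138, tolerance = 1e-6)
  x <- c(-3, -0.5, 0, 2, 7)
  expect_equal(sigmoid_transfer(x) + sigmoid_transfer(-x), rep(1, 5))

  expect_identical(binarize(0, draws = 0.3), 1L)
  expect_identical(binarize(0, draws = 0.9), 0L)
  withr::with_seed(6, {
    frac <- mean(replicate(10000, binarize(1)))
  })
  expect_equal(frac, sigmoid_transfer(1), tolerance = 0.02)
})

test_that("dive steps follow the improve-or-stay selection", {
  fit <- function(pos) sum(pos^2) # minimum at the origin
  # Y = prey - G|T prey - x| = 0.5 here, improves on f(2)=4
  expect_equal(
    soft_siege_dive_step(2, 1, 0.5, 1, fit, fit(2), levy_vec = 0, Q = 0,
                         lb = -10, ub = 10), 0.5)
  # make both Y and Z worse: prey far away, x already optimal
  worse <- soft_siege_dive_step(0, 9, 0.9, 1.5, fit, fit(0), levy_vec = 0.1,
                                Q = 1, lb = -10, ub = 10)
  expect_equal(worse, 0)
  # hard variant pivots on the mean position
  expect_equal(
    hard_siege_dive_step(5, 1, 1, 0, 1, fit, fit(5), levy_vec = 0, Q = 0,
                         lb = -10, ub = 10), 1) # G=0 -> Y = prey
})

test_that("phase dispatch is exhaustive and exclusive", {
  phases <- c("exploration", "soft_siege", "hard_siege",
              "soft_siege_dive", "hard_siege_dive")
  withr::with_seed(3, {
    for (i in 1:200) {
      G <- runif(1, -2.2, 2.2); e <- runif(1)
      hits <- c(abs(G) >= 1,
                abs(G) < 1 && abs(G) >= 0.5 && e >= 0.5,
                abs(G) < 0.5 && e >= 0.5,
                abs(G) < 1 && abs(G) >= 0.5 && e < 0.5,
                abs(G) < 0.5 && e < 0.5)
      expect_equal(sum(hits), 1L)
      expect_equal(hho_phase(G, e), phases[which(hits)])
    }
  })
})

test_that("the optimizer solves count-the-zeros and keeps its invariants", {
  res <- bhho_optimize(function(b) sum(b == 0), dim = 6,
                       control = bhho_control(pop_size = 10, it_max = 50),
                       seed = 11)
  expect_equal(res$best_fitness, 0)
  expect_equal(res$best_bits, rep(1L, 6))
  expect_length(res$trace, 50)
  expect_true(all(diff(res$trace) <= 0))
  expect_true(all(res$positions >= -4 & res$positions <= 4))

  res2 <- bhho_optimize(function(b) sum(b == 0), dim = 6,
                        control = bhho_control(pop_size = 10, it_max = 50),
                        seed = 11)
  expect_identical(res, res2) # bit-identical determinism

  for (s in c(1, 7, 19)) {
    r <- bhho_optimize(function(b) sum(abs(b - c(1, 0, 1, 0))), dim = 4,
                       control = bhho_control(pop_size = 6, it_max = 25),
                       seed = s)
    expect_true(all(diff(r$trace) <= 0))
    expect_true(all(r$positions >= -4 & r$positions <= 4))
  }
})

test_that("seeded initial bits bound the returned fitness", {
  # a fitness where the all-ones vector is mediocre but known
  f <- function(b) abs(sum(b) - 2) + 0.5
  seeded <- bhho_optimize(f, dim = 8,
                          control = bhho_control(pop_size = 5, it_max = 5),
                          seed = 4, init_bits = matrix(1L, 1, 8))
  expect_lte(seeded$best_fitness, f(rep(1L, 8)))
})
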