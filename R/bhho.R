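#' Optimizer control parameters
#'
#' @param pop_size Number of hawks (>= 2).
#' @param it_max Iterations of the main loop (>= 1).
#' @param lb,ub Continuous position bounds; with the default `(-4, 4)` the
#'   sigmoid transfer spans roughly (0.018, 0.982), so every bit stays
#'   reachable.
#' @param levy_beta Levy-flight stability exponent (default 1.5).
#' @return An object of class `bhho_control`.
#' @export
bhho_control <- function(pop_size = 10, it_max = 50, lb = -4, ub = 4,
                         levy_beta = 1.5) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (it_max < 1) stop("it_max must be >= 1")
  if (lb >= ub) stop("lb must be < ub")
  if (levy_beta <= 0) stop("levy_beta must be > 0")
  structure(list(pop_size = as.integer(pop_size),
                 it_max = as.integer(it_max),
                 lb = lb, ub = ub, levy_beta = levy_beta),
            class = "bhho_control")
}

#' Escape energy of the prey
#'
#' `G = 2 G0 (1 - J / it_max)`: the envelope decays linearly from `2 G0`
#' at the start of the run to 0 at the final iteration, and its magnitude
#' dispatches exploration (`|G| >= 1`) versus the four siege phases.
#'
#' @param G0 Initial energy, drawn uniformly from `[-1, 1]`.
#' @param J Current iteration (0 <= J <= it_max).
#' @param it_max Maximum iterations.
#' @return Scalar energy.
#' @export
escape_energy <- function(G0, J, it_max) 2 * G0 * (1 - J / it_max)

#' Mean hawk position
#' @param positions Matrix of hawk positions (one row per hawk).
#' @return Per-dimension arithmetic mean.
#' @export
mean_position <- function(positions) colMeans(positions)

#' S-shaped (sigmoid) transfer function
#'
#' Maps a continuous position coordinate to a bit-activation probability.
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, in (0, 1).
#' @export
sigmoid_transfer <- function(x) 1 / (1 + exp(-x))

#' Sample a binary view of a continuous position
#'
#' Bit j is 1 iff `draws[j] < sigmoid_transfer(position[j])`.
#'
#' @param position Continuous position vector.
#' @param draws Uniform(0,1) draws, same length (defaults to fresh draws).
#' @return Integer 0/1 vector.
#' @export
binarize <- function(position, draws = stats::runif(length(position))) {
  if (length(draws) != length(position)) {
    stop("draws must match the position length")
  }
  as.integer(draws < sigmoid_transfer(position))
}

#' Levy-flight step (Mantegna construction)
#'
#' Per dimension, `0.01 * (u * sigma) / |v|^(1/beta)` with `u, v` standard
#' Gaussian draws and `sigma` the closed-form scale
#' `[Gamma(1+b) sin(pi b/2) / (Gamma((1+b)/2) b 2^((b-1)/2))]^(1/b)`
#' (about 0.6966 at `beta = 1.5`).
#'
#' @param dim Number of dimensions.
#' @param beta Stability exponent (> 0).
#' @param u,v Optional Gaussian draw vectors (for reproducible traces).
#' @return Numeric step vector of length `dim`.
#' @export
levy_flight <- function(dim, beta = 1.5, u = stats::rnorm(dim),
                        v = stats::rnorm(dim)) {
  0.01 * u * levy_sigma(beta) / abs(v)^(1 / beta)
}

#' @rdname levy_flight
#' @export
levy_sigma <- function(beta) {
  ((gamma(1 + beta) * sin(pi * beta / 2)) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Exploration update (perch-and-wait)
#'
#' With probability draw `p >= 0.5` the hawk perches relative to a random
#' flock member: `x_rand - r1 |x_rand - 2 r2 x|`; otherwise relative to
#' the prey and the mean position:
#' `(x_prey - x_m) - r3 (lb + r4 (ub - lb))`. The result is clipped to the
#' bounds.
#'
#' @param x Current hawk position.
#' @param x_rand Position of a randomly chosen hawk.
#' @param x_prey Prey (incumbent best) position.
#' @param x_m Mean position of the population.
#' @param lb,ub Bounds.
#' @param draws Named list with uniform draws `p, r1, r2, r3, r4`
#'   (defaults to fresh draws).
#' @return New position vector.
#' @export
exploration_step <- function(x, x_rand, x_prey, x_m, lb, ub,
                             draws = list(p = stats::runif(1),
                                          r1 = stats::runif(1),
                                          r2 = stats::runif(1),
                                          r3 = stats::runif(1),
                                          r4 = stats::runif(1))) {
  new <- if (draws$p >= 0.5) {
    x_rand - draws$r1 * abs(x_rand - 2 * draws$r2 * x)
  } else {
    (x_prey - x_m) - draws$r3 * (lb + draws$r4 * (ub - lb))
  }
  clip(new, lb, ub)
}

#' Soft siege update
#'
#' `x_new = (x_prey - x) - G |T x_prey - x|`, clipped; used when the prey
#' retains energy (`0.5 <= |G| < 1`) but fails to escape. `T = 2 (1 -
#' rand)` is the prey's random jump strength.
#'
#' @param x,x_prey Positions.
#' @param G Escape energy.
#' @param T Jump strength in (0, 2].
#' @param lb,ub Bounds.
#' @return New position vector.
#' @export
soft_siege_step <- function(x, x_prey, G, T, lb, ub) {
  clip((x_prey - x) - G * abs(T * x_prey - x), lb, ub)
}

#' Hard siege update
#'
#' `x_new = x - G |x_prey - x|`, clipped; used when the prey is exhausted
#' (`|G| < 0.5`) and fails to escape.
#'
#' @inheritParams soft_siege_step
#' @return New position vector.
#' @export
hard_siege_step <- function(x, x_prey, G, lb, ub) {
  clip(x - G * abs(x_prey - x), lb, ub)
}

#' Siege updates with progressive dives
#'
#' Used when the prey escapes (`e < 0.5`). A first dive
#' `Y = x_prey - G |T x_prey - x|` (soft variant) or
#' `Y = x_prey - G |T x_prey - x_m|` (hard variant, relative to the mean
#' position) is accepted if it improves on the hawk's current fitness;
#' otherwise a Levy-flight dive `Z = Y + Q * levy` is tried; if neither
#' improves, the hawk stays put.
#'
#' @param x Current hawk position.
#' @param x_prey Prey position.
#' @param x_m Mean population position (hard variant only).
#' @param G Escape energy.
#' @param T Jump strength.
#' @param fitness_fn Function from a continuous position to its fitness
#'   (lower is better); binarization is the caller's concern.
#' @param f_x Fitness of the current position.
#' @param levy_vec Levy step vector (length `dim`).
#' @param Q Uniform(0,1) draw vector (length `dim`).
#' @param lb,ub Bounds.
#' @return New position vector (possibly `x` unchanged).
#' @export
soft_siege_dive_step <- function(x, x_prey, G, T, fitness_fn, f_x,
                                 levy_vec, Q, lb, ub) {
  y <- clip(x_prey - G * abs(T * x_prey - x), lb, ub)
  dive_select(x, y, fitness_fn, f_x, levy_vec, Q, lb, ub)
}

#' @rdname soft_siege_dive_step
#' @export
hard_siege_dive_step <- function(x, x_prey, x_m, G, T, fitness_fn, f_x,
                                 levy_vec, Q, lb, ub) {
  y <- clip(x_prey - G * abs(T * x_prey - x_m), lb, ub)
  dive_select(x, y, fitness_fn, f_x, levy_vec, Q, lb, ub)
}

dive_select <- function(x, y, fitness_fn, f_x, levy_vec, Q, lb, ub) {
  if (fitness_fn(y) < f_x) return(y)
  z <- clip(y + Q * levy_vec, lb, ub)
  if (fitness_fn(z) < f_x) return(z)
  x
}

#' Which update rule applies for a given (energy, escape) pair
#'
#' The dispatch is exhaustive and exclusive: every `(G, e)` pair triggers
#' exactly one of the five update rules.
#'
#' @param G Escape energy.
#' @param e Escape-chance draw in [0, 1].
#' @return One of `"exploration"`, `"soft_siege"`, `"hard_siege"`,
#'   `"soft_siege_dive"`, `"hard_siege_dive"`.
#' @export
hho_phase <- function(G, e) {
  if (abs(G) >= 1) "exploration"
  else if (abs(G) >= 0.5 && e >= 0.5) "soft_siege"
  else if (abs(G) < 0.5 && e >= 0.5) "hard_siege"
  else if (abs(G) >= 0.5) "soft_siege_dive"
  else "hard_siege_dive"
}

#' Binary Harris hawks optimization
#'
#' Minimizes a fitness defined on binary vectors. Hawk positions are
#' binary: every update computes the continuous Harris-hawks rule from the
#' current (0/1) positions, clips it to `[lb, ub]`, and immediately
#' re-binarizes it through the sigmoid transfer ([binarize()]) to obtain
#' the hawk's new position, which is what gets evaluated. The incumbent
#' best ("prey") is updated elitically after every evaluation, so the
#' best-fitness trace is non-increasing. Per hawk and iteration the
#' escape energy `G = 2 G0 (1 - J/it_max)` with `G0 ~ U(-1, 1)` dispatches
#' exploration (`|G| >= 1`) or one of the four siege phases (soft / hard,
#' with or without Levy-flight dives) chosen by `|G|` and a fresh escape
#' draw `e ~ U(0, 1)`.
#'
#' @param fitness_fn Function `integer 0/1 vector -> numeric` (lower is
#'   better; may return `Inf` for invalid vectors).
#' @param dim Number of bits.
#' @param control A [bhho_control()].
#' @param seed Integer seed; results are bit-identical for identical
#'   inputs.
#' @param init_bits Optional 0/1 matrix (rows = candidate vectors) seeded
#'   into the initial population; row `r` becomes hawk `r`'s initial
#'   position and is evaluated as-is, guaranteeing the returned fitness is
#'   at least as good as every seeded candidate.
#' @return An object of class `bhho_result`: `best_bits`, `best_fitness`,
#'   `trace` (per-iteration incumbent fitness, non-increasing),
#'   `iterations`, `n_evals`, `positions` (final binary population),
#'   `seed`, `control`.
#' @examples
#' res <- bhho_optimize(function(b) sum(b == 0), dim = 6,
#'                      control = bhho_control(it_max = 30), seed = 1)
#' res$best_fitness
#' @export
bhho_optimize <- function(fitness_fn, dim, control = bhho_control(),
                          seed = 1, init_bits = NULL) {
  stopifnot(inherits(control, "bhho_control"), dim >= 1)
  pop <- control$pop_size
  lb <- control$lb
  ub <- control$ub
  it_max <- control$it_max

  state <- new.env(parent = emptyenv())
  state$n_evals <- 0L
  state$prey_pos <- NULL
  state$prey_fit <- Inf
  # score a binary position, updating the prey elitically
  eval_bits <- function(bits) {
    f <- fitness_fn(bits)
    state$n_evals <- state$n_evals + 1L
    if (is.null(state$prey_pos) || f < state$prey_fit) {
      state$prey_fit <- f
      state$prey_pos <- as.numeric(bits)
    }
    f
  }

  withr::with_seed(as.integer(seed), {
    # initial binary positions: uniform continuous draws pushed through the
    # transfer (about coin-flip bits); seeded rows are taken verbatim
    X <- matrix(0, pop, dim)
    for (i in seq_len(pop)) X[i, ] <- binarize(stats::runif(dim, lb, ub))
    if (!is.null(init_bits)) {
      init_bits <- matrix(as.integer(init_bits), ncol = dim)
      if (nrow(init_bits) > pop) {
        stop("init_bits cannot contain more rows than pop_size")
      }
      for (r in seq_len(nrow(init_bits))) X[r, ] <- init_bits[r, ]
    }
    fit <- numeric(pop)
    for (i in seq_len(pop)) fit[i] <- eval_bits(X[i, ])

    trace <- numeric(it_max)
    for (j in seq_len(it_max)) {
      for (i in seq_len(pop)) {
        G0 <- stats::runif(1, -1, 1)
        G <- escape_energy(G0, j, it_max)
        e <- stats::runif(1)
        phase <- hho_phase(G, e)
        if (phase %in% c("exploration", "soft_siege", "hard_siege")) {
          cont <- if (phase == "exploration") {
            x_rand <- X[sample.int(pop, 1L), ]
            exploration_step(X[i, ], x_rand, state$prey_pos,
                             mean_position(X), lb, ub)
          } else if (phase == "soft_siege") {
            T <- 2 * (1 - stats::runif(1))
            soft_siege_step(X[i, ], state$prey_pos, G, T, lb, ub)
          } else {
            hard_siege_step(X[i, ], state$prey_pos, G, lb, ub)
          }
          bits <- binarize(cont)
          fit[i] <- eval_bits(bits)
          X[i, ] <- bits
        } else {
          T <- 2 * (1 - stats::runif(1))
          levy_vec <- levy_flight(dim, control$levy_beta)
          Q <- stats::runif(dim)
          # the dive candidates are binarized before evaluation; cache the
          # bits so the accepted candidate's sampled form is stored as-is
          cache <- list()
          fit_num <- function(pos) {
            bits <- binarize(pos)
            f <- eval_bits(bits)
            cache[[length(cache) + 1L]] <<- list(pos = pos, bits = bits,
                                                 fitness = f)
            f
          }
          newx <- if (phase == "soft_siege_dive") {
            soft_siege_dive_step(X[i, ], state$prey_pos, G, T, fit_num,
                                 fit[i], levy_vec, Q, lb, ub)
          } else {
            hard_siege_dive_step(X[i, ], state$prey_pos, mean_position(X),
                                 G, T, fit_num, fit[i], levy_vec, Q, lb, ub)
          }
          hit <- Filter(function(ce) identical(ce$pos, newx), cache)
          if (length(hit)) {
            X[i, ] <- hit[[1L]]$bits
            fit[i] <- hit[[1L]]$fitness
          } # else the hawk kept its position and fitness
        }
      }
      trace[j] <- state$prey_fit
    }

    structure(list(best_bits = as.integer(state$prey_pos),
                   best_fitness = state$prey_fit,
                   trace = trace, iterations = it_max,
                   n_evals = state$n_evals, positions = X,
                   seed = as.integer(seed), control = control),
              class = "bhho_result")
  })
}

#' @export
print.bhho_result <- function(x, ...) {
  cat("<bhho_result> dim=", length(x$best_bits), "; best fitness ",
      signif(x$best_fitness, 6), " after ", x$iterations,
      " iterations (", x$n_evals, " evaluations)\n", sep = "")
  invisible(x)
}
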