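#' Genetic-algorithm configuration for SVR hyperparameter tuning
#'
#' Defaults mirror the tuning protocol used for the published model:
#' search ranges C in [0, 1000] and gamma in [0, 10], 5-fold
#' cross-validation fitness, at most 200 generations, population 20, and
#' epsilon 0.001. The C = 0 boundary is degenerate and is clamped to
#' 1e-6 when candidates are evaluated. Operators (unspecified in the
#' protocol) are real-coded: tournament selection of size 2, blend
#' crossover (BLX-alpha, alpha = 0.5), per-gene Gaussian mutation with
#' standard deviation 5 percent of the range, elitism of 1.
#'
#' @param c_range,gamma_range Search intervals.
#' @param folds Cross-validation folds (m), >= 2.
#' @param generations Maximum generations.
#' @param pop_size Population size (even).
#' @param epsilon SVR tube half-width used during tuning.
#' @param seed Integer seed making the run reproducible.
#' @param crossover_alpha Blend-crossover expansion factor.
#' @param crossover_rate Probability a pair is crossed rather than copied.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sd_frac Mutation standard deviation as a fraction of
#'   the parameter range.
#' @return A \code{"ga_config"} list.
#' @export
ga_config <- function(c_range = c(0, 1000), gamma_range = c(0, 10),
                      folds = 5L, generations = 200L, pop_size = 20L,
                      epsilon = 0.001, seed = 1L,
                      crossover_alpha = 0.5, crossover_rate = 0.9,
                      mutation_rate = 0.2, mutation_sd_frac = 0.05) {
  stopifnot(diff(c_range) > 0, diff(gamma_range) > 0, folds >= 2L,
            pop_size %% 2L == 0L, pop_size >= 4L, generations >= 1L)
  structure(list(c_range = c_range, gamma_range = gamma_range,
                 folds = as.integer(folds),
                 generations = as.integer(generations),
                 pop_size = as.integer(pop_size), epsilon = epsilon,
                 seed = as.integer(seed),
                 crossover_alpha = crossover_alpha,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd_frac = mutation_sd_frac),
            class = "ga_config")
}

# Deterministic fold assignment: permutation of 1..n from the seed, folds
# dealt out cyclically.
.make_folds <- function(n, m, seed) {
  stopifnot(m <= n)
  perm <- .with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(m), n)
  folds
}

# Run code under a local RNG state; the caller's stream is untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mean held-out squared error of an SVR at (C, gamma) over fixed folds.
.cv_mse_svr <- function(x, y, C, gamma, epsilon, folds) {
  x <- as.matrix(x)
  errs <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    hold <- folds == f
    model <- svr_fit(x[!hold, , drop = FALSE], y[!hold], C = C,
                     gamma = gamma, epsilon = epsilon)
    pred <- predict(model, x[hold, , drop = FALSE])
    errs[f] <- mean((y[hold] - pred)^2)
  }
  mean(errs)
}

#' Tune SVR hyperparameters with a real-coded genetic algorithm
#'
#' Minimizes the m-fold cross-validation mean squared error of
#' \code{\link{svr_fit}} over (C, gamma). The fold assignment is fixed for
#' the whole run (drawn once from the seed), so fitness values are
#' comparable across generations; the best-ever candidate is tracked with
#' elitism and the run is fully reproducible from the seed.
#'
#' @param x Training inputs.
#' @param y Training response.
#' @param config A \code{\link{ga_config}}.
#' @return List with \code{C}, \code{gamma}, \code{cv_mse} (best fitness),
#'   \code{history} (data frame of per-generation best fitness) and
#'   \code{evaluated} (matrix of every candidate evaluated, for range
#'   audits).
#' @export
ga_optimize <- function(x, y, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- .make_folds(n, config$folds, config$seed)
  lo <- c(config$c_range[1], config$gamma_range[1])
  hi <- c(config$c_range[2], config$gamma_range[2])
  rng <- hi - lo
  clamp <- function(v) {
    v <- pmin(pmax(v, lo), hi)
    v[1] <- max(v[1], 1e-6)  # C = 0 is degenerate
    v
  }
  fitness <- function(v) .cv_mse_svr(x, y, C = v[1], gamma = v[2],
                                     epsilon = config$epsilon, folds = folds)
  .with_seed(config$seed + 1L, {
    pop <- lapply(seq_len(config$pop_size),
                  function(i) clamp(lo + runif(2) * rng))
    fit <- vapply(pop, fitness, numeric(1))
    evaluated <- do.call(rbind, pop)
    best_idx <- which.min(fit)
    best <- pop[[best_idx]]; best_fit <- fit[best_idx]
    history <- data.frame(generation = 0L, best_fitness = best_fit)
    for (gen in seq_len(config$generations)) {
      next_pop <- list(best)  # elitism of 1
      while (length(next_pop) < config$pop_size) {
        pick <- function() {
          cand <- sample.int(config$pop_size, 2L)
          pop[[cand[which.min(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        if (runif(1) < config$crossover_rate) {
          a <- config$crossover_alpha
          span <- abs(p1 - p2)
          lo_c <- pmin(p1, p2) - a * span
          hi_c <- pmax(p1, p2) + a * span
          c1 <- lo_c + runif(2) * (hi_c - lo_c)
          c2 <- lo_c + runif(2) * (hi_c - lo_c)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          mut <- runif(2) < config$mutation_rate
          child[mut] <- child[mut] +
            rnorm(sum(mut), 0, config$mutation_sd_frac * rng[mut])
          next_pop[[length(next_pop) + 1L]] <- clamp(child)
          if (length(next_pop) >= config$pop_size) break
        }
      }
      pop <- next_pop
      fit <- vapply(pop, fitness, numeric(1))
      evaluated <- rbind(evaluated, do.call(rbind, pop))
      gen_best <- which.min(fit)
      if (fit[gen_best] < best_fit) {
        best_fit <- fit[gen_best]; best <- pop[[gen_best]]
      }
      history <- rbind(history,
                       data.frame(generation = gen, best_fitness = best_fit))
    }
    colnames(evaluated) <- c("C", "gamma")
    list(C = best[1], gamma = best[2], cv_mse = best_fit,
         history = history, evaluated = evaluated)
  })
}
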