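#' Genetic-algorithm configuration for attribute-weight learning
#'
#' Defaults follow the configuration that performed best for the GWHSM_GA
#' baseline: crossover rate 0.75, mutation rate 0.20, 300 generations,
#' roulette-wheel parent selection and elitist carry-over of the top 30%.
#' Population size, the whole-arithmetic crossover, the per-gene Gaussian
#' mutation (sd 0.1) and the `[0, 1]` weight bounds are engine choices for
#' the floating-point chromosome representation.
#'
#' @param population_size Number of chromosomes per generation.
#' @param crossover_rate Probability a child is produced by crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param generations Number of generations (>= 1).
#' @param elitism_fraction Fraction of the population copied unchanged into
#'   the next generation (strictly between 0 and 1).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param weight_bounds `c(low, high)` bounds of every gene, `low >= 0`.
#' @param mutation_sd Standard deviation of the Gaussian mutation.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, crossover_rate = 0.75,
                      mutation_rate = 0.20, generations = 300,
                      elitism_fraction = 0.30, seed = 1,
                      weight_bounds = c(0, 1), mutation_sd = 0.1) {
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stopf("crossover and mutation rates must lie in [0, 1]")
  if (generations < 1) stopf("generations must be >= 1")
  if (elitism_fraction <= 0 || elitism_fraction >= 1)
    stopf("elitism_fraction must lie strictly between 0 and 1")
  if (population_size < 2) stopf("population_size must be >= 2")
  weight_bounds <- as.numeric(weight_bounds)
  if (length(weight_bounds) != 2L || weight_bounds[1] < 0 ||
      weight_bounds[1] >= weight_bounds[2])
    stopf("weight_bounds must be c(low, high) with 0 <= low < high")
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 elitism_fraction = elitism_fraction,
                 seed = as.integer(seed),
                 weight_bounds = weight_bounds,
                 mutation_sd = mutation_sd),
            class = "ga_config")
}

#' Leave-one-out precision fitness of a weight vector
#'
#' Each case is removed in turn, its single most similar neighbour among
#' the remaining cases is retrieved under GWHSM with the given weights, and
#' the retrieved solution is compared with the confirmed one. The fitness
#' is the precision TP / (TP + FP): here every case yields exactly one
#' proposal, so this is the fraction of correctly proposed solutions.
#'
#' @param weights Named non-negative weights (at least one positive).
#' @param cb A [case_base()] with at least two cases.
#' @param decision Decision name whose solution is predicted.
#' @param attrs Attribute names used by the measure (default: all).
#' @return Fitness in `[0, 1]`.
#' @export
loo_precision_fitness <- function(weights, cb, decision,
                                  attrs = names(cb$schema$attributes)) {
  stopifnot(inherits(cb, "case_base"))
  if (nrow(cb$cases) < 2L) stopf("the case-base needs >= 2 cases")
  w <- weight_vector(weights, attrs)
  if (sum(w) <= 0) stopf("degenerate weights: all zero")
  ctx <- measure_ctx(cb)
  arrays <- gwhsm_pair_arrays(cb, attrs, ctx)
  sols <- solution_column(cb, decision)
  fitness_from_arrays(w, arrays, attrs, sols)
}

solution_column <- function(cb, decision) {
  col <- paste0("solution.", decision)
  if (!col %in% names(cb$cases)) stopf("unknown decision '%s'", decision)
  cb$cases[[col]]
}

# 1-NN leave-one-out accuracy from precomputed pairwise arrays. Pairs with
# no informative attribute get dissimilarity 1; argmin ties keep the first
# case in case-base order.
fitness_from_arrays <- function(w, arrays, attrs, sols) {
  n <- length(sols)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (a in attrs) {
    num <- num + w[[a]] * arrays[[a]]$D
    den <- den + w[[a]] * arrays[[a]]$M
  }
  diss <- matrix(1, n, n)
  inf <- den > 0
  diss[inf] <- num[inf] / den[inf]
  diag(diss) <- Inf
  nn <- max.col(-diss, ties.method = "first")
  mean(sols[nn] == sols)
}

#' Learn GWHSM attribute weights with a genetic algorithm
#'
#' Evolves a population of floating-point weight chromosomes against the
#' leave-one-out precision fitness of [loo_precision_fitness()].
#' Roulette-wheel selection picks parents proportionally to fitness
#' (uniformly when the whole population has fitness zero);
#' whole-arithmetic crossover blends two parents with probability
#' `crossover_rate`; each gene then mutates with probability
#' `mutation_rate` by a Gaussian step clipped to the weight bounds; the
#' top `elitism_fraction` of each generation is carried forward unchanged,
#' which makes the best-of-generation fitness non-decreasing.
#'
#' @param cb A [case_base()].
#' @param decision Decision whose solution drives the fitness.
#' @param config A [ga_config()].
#' @param attrs Attribute names to weight (default: all schema attributes).
#' @return An object of class `ga_weights`: `weights` (best chromosome,
#'   named), `fitness` (its fitness), `history` (best fitness per
#'   generation), `config`, `decision`.
#' @export
learn_weights <- function(cb, decision, config = ga_config(),
                          attrs = names(cb$schema$attributes)) {
  stopifnot(inherits(cb, "case_base"), inherits(config, "ga_config"))
  if (nrow(cb$cases) < 2L) stopf("the case-base needs >= 2 cases")
  ctx <- measure_ctx(cb)
  arrays <- gwhsm_pair_arrays(cb, attrs, ctx)
  sols <- solution_column(cb, decision)
  A <- length(attrs)
  P <- config$population_size
  lo <- config$weight_bounds[1]; hi <- config$weight_bounds[2]
  elite_n <- max(1L, ceiling(config$elitism_fraction * P))

  with_seed(config$seed, {
    pop <- matrix(stats::runif(P * A, lo, hi), nrow = P)
    history <- numeric(config$generations)
    best_w <- NULL; best_fit <- -Inf
    for (g in seq_len(config$generations)) {
      fit <- apply(pop, 1L, function(w) {
        w <- stats::setNames(w, attrs)
        if (sum(w) <= 0) return(0)
        fitness_from_arrays(w, arrays, attrs, sols)
      })
      ord <- order(fit, decreasing = TRUE)
      if (fit[ord[1]] > best_fit) {
        best_fit <- fit[ord[1]]
        best_w <- pop[ord[1], ]
      }
      history[g] <- best_fit
      if (g == config$generations) break
      elite <- pop[ord[seq_len(elite_n)], , drop = FALSE]
      probs <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / P, P)
      children <- matrix(NA_real_, nrow = P - elite_n, ncol = A)
      for (i in seq_len(P - elite_n)) {
        p1 <- pop[sample.int(P, 1L, prob = probs), ]
        child <- if (stats::runif(1) < config$crossover_rate) {
          p2 <- pop[sample.int(P, 1L, prob = probs), ]
          alpha <- stats::runif(1)
          alpha * p1 + (1 - alpha) * p2
        } else p1
        mut <- stats::runif(A) < config$mutation_rate
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, config$mutation_sd)
        children[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- rbind(elite, children)
    }
    structure(list(weights = stats::setNames(best_w, attrs),
                   fitness = best_fit, history = history,
                   config = config, decision = decision),
              class = "ga_weights")
  })
}

#' @export
print.ga_weights <- function(x, ...) {
  cat("<ga_weights> decision:", x$decision,
      " best LOO precision:", round(x$fitness, 4), "\n")
  w <- sort(x$weights, decreasing = TRUE)
  for (a in names(w)) cat(sprintf("  %-34s %.3f\n", a, w[[a]]))
  invisible(x)
}
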