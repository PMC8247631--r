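#' Tune post-processing parameters with a genetic algorithm
#'
#' Real-coded genetic algorithm maximising the mean DSB score of the
#' refinement chain over a training set of (prediction, probability map,
#' ground truth) triples. Tournament selection, uniform crossover,
#' Gaussian mutation (sigma = 10% of each parameter's range) and one-elite
#' survival, so the best fitness never decreases across generations. The
#' default parameters and an identity-leaning member (a chain that changes
#' as little as possible) are seeded into the initial population.
#'
#' @param train a list of triples `list(pred =, prob =, gt =)`, or a
#'   tibble with columns `pred`, `prob`, `gt` (list-columns).
#' @param population population size (default 30).
#' @param generations number of generations (default 20).
#' @param seed integer seed; the run is deterministic given it.
#' @param bounds a 2 x 6 matrix of lower/upper parameter bounds
#'   (columns p1..p6); the default caps p2 at 200 px and p4/p5 at 3 px.
#' @param mutation_prob per-gene mutation probability.
#' @param tournament tournament size.
#' @param stages stages passed to [postprocess_chain()].
#' @return a `pp_fit`: list with `params` (a [postprocess_params()] row),
#'   `fitness`, `default_fitness`, `baseline_fitness` (chain off) and
#'   `history` (tibble of per-generation best/mean fitness).
#' @export
optimize_params <- function(train, population = 30, generations = 20, seed,
                            bounds = default_param_bounds(),
                            mutation_prob = 0.2, tournament = 3,
                            stages = c("contained", "surrounded", "small",
                                       "correct", "confidence")) {
  train <- as_triples(train)
  if (!length(train)) stop("empty training set", call. = FALSE)
  stopifnot(population >= 1, generations >= 0)
  withr::local_seed(seed)

  fitness <- function(genome) {
    par <- genome_to_params(genome)
    mean(purrr::map_dbl(train, function(tr) {
      dsb_score(postprocess_chain(tr$pred, tr$prob, par, stages = stages), tr$gt)
    }))
  }

  lo <- bounds[1, ]; hi <- bounds[2, ]
  rng <- hi - lo
  defaults <- as.numeric(postprocess_params()[1, 1:6])
  identityish <- c(1, 0, 0.5, 0, 0, 0)
  pop <- matrix(stats::runif(population * 6, lo, hi),
                nrow = population, byrow = TRUE)
  if (population >= 1) pop[1, ] <- pmin(pmax(defaults, lo), hi)
  if (population >= 2) pop[2, ] <- pmin(pmax(identityish, lo), hi)
  fit <- apply(pop, 1, fitness)

  history <- tibble::tibble(generation = 0L, best = max(fit), mean = mean(fit))
  for (g in seq_len(generations)) {
    elite_i <- which.max(fit)
    new_pop <- matrix(0, population, 6)
    new_pop[1, ] <- pop[elite_i, ]
    for (i in seq_len(population)[-1]) {
      pa <- pop[tournament_pick(fit, tournament), ]
      pb <- pop[tournament_pick(fit, tournament), ]
      child <- ifelse(stats::runif(6) < 0.5, pa, pb)
      mut <- stats::runif(6) < mutation_prob
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1 * rng[mut])
      new_pop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- new_pop
    fit <- c(fit[elite_i], apply(pop[-1, , drop = FALSE], 1, fitness))
    history <- dplyr::bind_rows(
      history,
      tibble::tibble(generation = g, best = max(fit), mean = mean(fit))
    )
  }
  best <- which.max(fit)
  params <- genome_to_params(pop[best, ])
  default_fit <- mean(purrr::map_dbl(train, function(tr) {
    dsb_score(postprocess_chain(tr$pred, tr$prob, postprocess_params(),
                                stages = stages), tr$gt)
  }))
  baseline_fit <- mean(purrr::map_dbl(train, ~ dsb_score(.x$pred, .x$gt)))
  structure(
    list(params = params, fitness = fit[best],
         default_fitness = default_fit, baseline_fitness = baseline_fit,
         history = history, n_train = length(train)),
    class = "pp_fit"
  )
}

#' Default genetic-algorithm parameter bounds
#' @return a 2 x 6 matrix (rows: lower, upper; columns p1..p6).
#' @export
default_param_bounds <- function() {
  rbind(
    lower = c(0, 0, 0, 0, 0, 0),
    upper = c(1, 200, 1, 3, 3, 1)
  )
}

genome_to_params <- function(g) {
  postprocess_params(p1 = g[1], p2 = g[2], p3 = g[3],
                     p4 = round(g[4]), p5 = round(g[5]), p6 = g[6])
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), min(k, length(fit)))
  cand[which.max(fit[cand])]
}

as_triples <- function(train) {
  if (is.data.frame(train)) {
    stopifnot(all(c("pred", "prob", "gt") %in% names(train)))
    train <- purrr::pmap(train[c("pred", "prob", "gt")], list)
  }
  purrr::map(train, function(tr) {
    stopifnot(all(c("pred", "prob", "gt") %in% names(tr)))
    tr
  })
}

#' @export
print.pp_fit <- function(x, ...) {
  cat(sprintf(
    "<pp_fit> tuned on %d image(s): fitness %.4f (defaults %.4f, chain off %.4f)\n",
    x$n_train, x$fitness, x$default_fitness, x$baseline_fitness
  ))
  print(as.data.frame(x$params))
  invisible(x)
}

#' Tuned parameters in long form
#' @param x a `pp_fit`.
#' @param ... unused.
#' @return a tibble with columns `parameter`, `value`.
#' @export
tidy.pp_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$params), value = as.numeric(x$params[1, ]))
}

#' @export
glance.pp_fit <- function(x, ...) {
  tibble::tibble(
    fitness = x$fitness, default_fitness = x$default_fitness,
    baseline_fitness = x$baseline_fitness, n_train = x$n_train,
    generations = max(x$history$generation)
  )
}
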