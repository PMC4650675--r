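# Genetic-algorithm wavelength selection. A chromosome is an explicit
# sorted set of feature indices (not a fixed-length bit mask) so the size
# bounds -- at least one more feature than the number of latent variables,
# at most max_features -- are first-class and enforced everywhere.

#' GA configuration
#'
#' Defaults follow the study settings: population 50, at most 20
#' generations, per-feature mutation probability 0.05 per generation,
#' subset sizes between `n_components + 1` and 75, 26 latent variables,
#' and a fitness that weights calibration and leave-one-out accuracy
#' equally (both as fractions, so perfect classification gives fitness 1,
#' the default stopping value).
#'
#' @param population_size Number of chromosomes per generation.
#' @param max_generations Generation cap.
#' @param mutation_prob Per-feature toggle probability per generation.
#' @param max_features Largest allowed subset size.
#' @param n_components Latent variables used in every fitness evaluation.
#' @param min_features Smallest allowed subset size (default
#'   `n_components + 1`).
#' @param fitness_weights Length-2 nonnegative weights `(w_cal, w_loo)`
#'   summing to 1.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param tournament_size Tournament size for parent selection.
#' @param target_fitness Early-stopping fitness value.
#' @param seed Master seed; all GA randomness derives from it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, max_generations = 20L,
                      mutation_prob = 0.05, max_features = 75L,
                      n_components = 26L, min_features = n_components + 1L,
                      fitness_weights = c(0.5, 0.5), elitism = 1L,
                      tournament_size = 2L, target_fitness = 1.0, seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              mutation_prob = mutation_prob,
              min_features = as.integer(min_features),
              max_features = as.integer(max_features),
              n_components = as.integer(n_components),
              fitness_weights = as.numeric(fitness_weights),
              elitism = as.integer(elitism),
              tournament_size = as.integer(tournament_size),
              target_fitness = target_fitness, seed = as.integer(seed))
  with(cfg, {
    if (population_size < 2L || max_generations < 1L || tournament_size < 1L)
      stopf("population, generations and tournament size must be positive")
    if (mutation_prob < 0 || mutation_prob > 1) stopf("mutation_prob outside [0, 1]")
    if (min_features <= n_components)
      stopf("subsets need at least n_components + 1 = %d features", n_components + 1L)
    if (max_features < min_features) stopf("max_features < min_features")
    if (length(fitness_weights) != 2L || any(fitness_weights < 0) ||
        abs(sum(fitness_weights) - 1) > 1e-12)
      stopf("fitness_weights must be 2 nonnegative values summing to 1")
  })
  structure(cfg, class = "ga_config")
}

validate_chromosome <- function(subset, cfg, p) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < cfg$min_features)
    stopf("subset size %d below minimum %d (n_components + 1)",
          length(subset), cfg$min_features)
  if (length(subset) > cfg$max_features)
    stopf("subset size %d above maximum %d", length(subset), cfg$max_features)
  if (subset[1L] < 1L || subset[length(subset)] > p)
    stopf("subset indices outside grid [1, %d]", p)
  subset
}

#' GA fitness of a feature subset
#'
#' `fitness = w_cal * r_calibration + w_loo * r_LOO`, where both accuracies
#' are fractions in `[0, 1]` from a PLSDA fit at `cfg$n_components` latent
#' variables on the given subset.
#'
#' @param train A `spectra_set`.
#' @param subset Integer feature indices satisfying the size bounds.
#' @param cfg A `ga_config`.
#' @return List with `fitness`, `r_calibration`, `r_loo`.
#' @export
ga_fitness <- function(train, subset, cfg) {
  subset <- validate_chromosome(subset, cfg, ncol(train$absorbance))
  model <- fit_plsda(train, cfg$n_components, subset)
  r_cal <- overall_accuracy(calibration_confusion(model, train)) / 100
  r_loo <- overall_accuracy(loo_cv(train, cfg$n_components, subset)) / 100
  list(fitness = cfg$fitness_weights[1L] * r_cal + cfg$fitness_weights[2L] * r_loo,
       r_calibration = r_cal, r_loo = r_loo)
}

#' Initialise a GA population
#'
#' Chromosome sizes are uniform on `[min_features, max_features]`; indices
#' are sampled uniformly without replacement from the grid.
#'
#' @param cfg A `ga_config`.
#' @param p Grid size (number of available features).
#' @return List of `population_size` sorted index vectors.
#' @export
ga_init_population <- function(cfg, p) {
  if (p < cfg$min_features)
    stopf("grid size %d smaller than minimum subset size %d", p, cfg$min_features)
  max_sz <- min(cfg$max_features, p)
  lapply(seq_len(cfg$population_size), function(i) {
    sz <- sample(cfg$min_features:max_sz, 1L)
    sort(sample.int(p, sz))
  })
}

#' Recombine two chromosomes
#'
#' The child's features are drawn without replacement from the union of the
#' parents; its size is the size of a randomly chosen parent, clamped to
#' the configured bounds and to the union size.
#'
#' @param parent_a,parent_b Sorted index vectors.
#' @param cfg A `ga_config`.
#' @return A sorted index vector.
#' @export
ga_crossover <- function(parent_a, parent_b, cfg) {
  pool <- union(parent_a, parent_b)
  sz <- length(if (stats::runif(1) < 0.5) parent_a else parent_b)
  sz <- min(max(sz, cfg$min_features), cfg$max_features, length(pool))
  sort(pool[sample.int(length(pool), sz)])
}

#' Mutate a chromosome
#'
#' Every grid feature is toggled independently (added if absent, removed if
#' present) with probability `cfg$mutation_prob`; the result is repaired to
#' the size bounds by random additions or removals.
#'
#' @param subset Sorted index vector.
#' @param cfg A `ga_config`.
#' @param p Grid size.
#' @return A sorted index vector within the size bounds.
#' @export
ga_mutate <- function(subset, cfg, p) {
  if (cfg$mutation_prob > 0) {
    toggled <- which(stats::runif(p) < cfg$mutation_prob)
    subset <- union(setdiff(subset, toggled), setdiff(toggled, subset))
  }
  max_sz <- min(cfg$max_features, p)
  if (length(subset) < cfg$min_features) {
    absent <- setdiff(seq_len(p), subset)
    subset <- c(subset, absent[sample.int(length(absent),
                                          cfg$min_features - length(subset))])
  } else if (length(subset) > max_sz) {
    subset <- subset[-sample.int(length(subset), length(subset) - max_sz)]
  }
  sort(subset)
}

#' Run the genetic algorithm
#'
#' Tournament selection, crossover, per-feature mutation and elitism, with
#' early stopping once the best fitness reaches `cfg$target_fitness`. All
#' randomness derives deterministically from `cfg$seed` via per-generation
#' streams; fitness values are cached so a chromosome is never re-evaluated.
#'
#' @param train A `spectra_set`.
#' @param cfg A `ga_config`.
#' @return An object of class `ga_result`: `best_subset`, `best_fitness`,
#'   `fitness_components` (r_calibration and r_loo of the best),
#'   `trajectory` (per-generation best and mean fitness), `generations_run`.
#' @export
run_ga <- function(train, cfg) {
  p <- ncol(train$absorbance)
  if (nrow(train$absorbance) < cfg$n_components + 2L)
    stopf("training set too small for %d latent variables under LOO", cfg$n_components)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(subset) {
    key <- paste(subset, collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <- ga_fitness(train, subset, cfg)
    cache[[key]]
  }
  seeds <- derive_seeds(cfg$seed, cfg$max_generations + 1L)
  pop <- with_seed(seeds[1L], ga_init_population(cfg, p))
  traj_best <- traj_mean <- numeric(0)
  best <- NULL
  for (gen in seq_len(cfg$max_generations)) {
    for (chrom in pop) validate_chromosome(chrom, cfg, p)
    fits <- vapply(pop, function(ch) evaluate(ch)$fitness, numeric(1))
    if (is.null(best) || max(fits) > best$fitness)
      best <- list(subset = pop[[which.max(fits)]], fitness = max(fits))
    traj_best <- c(traj_best, best$fitness)
    traj_mean <- c(traj_mean, mean(fits))
    if (best$fitness >= cfg$target_fitness || gen == cfg$max_generations) break
    pop <- with_seed(seeds[gen + 1L], {
      elite <- pop[order(fits, decreasing = TRUE)[seq_len(min(cfg$elitism,
                                                              length(pop)))]]
      pick <- function() {
        cand <- sample.int(length(pop), cfg$tournament_size, replace = TRUE)
        pop[[cand[which.max(fits[cand])]]]
      }
      children <- lapply(seq_len(cfg$population_size - length(elite)), function(i)
        ga_mutate(ga_crossover(pick(), pick(), cfg), cfg, p))
      c(elite, children)
    })
  }
  comp <- evaluate(best$subset)
  structure(list(best_subset = best$subset, best_fitness = best$fitness,
                 fitness_components = c(r_calibration = comp$r_calibration,
                                        r_loo = comp$r_loo),
                 trajectory = data.frame(generation = seq_along(traj_best),
                                         best = traj_best, mean = traj_mean),
                 generations_run = length(traj_best), config = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d features selected, fitness %.4f (r_cal %.3f, r_loo %.3f) after %d generations\n",
              length(x$best_subset), x$best_fitness,
              x$fitness_components[["r_calibration"]],
              x$fitness_components[["r_loo"]], x$generations_run))
  invisible(x)
}
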