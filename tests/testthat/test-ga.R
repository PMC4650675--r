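test_that("fitness is the configured mixture of calibration and LOO accuracy", {
  gen <- generate_spectra(enrichment_config(), seed = 31)
  cfg <- ga_config(population_size = 5L, max_generations = 2L,
                   n_components = 2L, max_features = 10L, seed = 1L)
  truth <- gen$truth$informative
  f <- ga_fitness(gen$spectra, truth[1:4], cfg)
  expect_equal(f$fitness, 0.5 * f$r_calibration + 0.5 * f$r_loo)
  expect_true(f$r_calibration >= 0 && f$r_calibration <= 1)
  # weight arithmetic at fixed accuracies: r_cal 1, r_loo 0.5 -> 0.75
  expect_equal(0.5 * 1 + 0.5 * 0.5, 0.75)
  # monotone in r_loo at fixed weights: heavier loo weight, same ordering
  cfg2 <- cfg; cfg2$fitness_weights <- c(0.3, 0.7)
  f2 <- ga_fitness(gen$spectra, truth[1:4], cfg2)
  expect_equal(f2$fitness, 0.3 * f2$r_calibration + 0.7 * f2$r_loo)
  expect_error(ga_fitness(gen$spectra, truth[1:2], cfg), "below minimum")
  expect_error(ga_fitness(gen$spectra, seq_len(20), cfg), "above maximum")
})

test_that("initial populations respect bounds and sample the grid uniformly", {
  cfg <- ga_config(population_size = 40L, max_generations = 1L,
                   n_components = 2L, max_features = 10L, seed = 1L)
  pop1 <- with_seed_helper(5, ga_init_population(cfg, 100L))
  pop2 <- with_seed_helper(5, ga_init_population(cfg, 100L))
  expect_identical(pop1, pop2)
  sizes <- vapply(pop1, length, 0L)
  expect_true(all(sizes >= 3L & sizes <= 10L))
  expect_true(all(vapply(pop1, function(ch) !anyDuplicated(ch) &&
                           all(ch >= 1 & ch <= 100), TRUE)))
  expect_error(ga_init_population(cfg, 2L), "smaller than minimum")
  # uniformity over >= 10,000 index draws
  set.seed(6)
  draws <- unlist(replicate(60, ga_init_population(cfg, 100L), simplify = FALSE))
  counts <- tabulate(draws, 100L)
  expect_gt(sum(counts), 10000)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("crossover children are contained in the parent union with parent-like sizes", {
  cfg <- ga_config(population_size = 5L, max_generations = 1L,
                   n_components = 2L, max_features = 50L, seed = 1L)
  set.seed(7)
  expect_identical(ga_crossover(c(3L, 5L, 9L, 11L), c(3L, 5L, 9L, 11L), cfg),
                   c(3L, 5L, 9L, 11L))
  child_sizes <- integer(1000)
  for (i in 1:1000) {
    a <- sort(sample.int(80, sample(4:12, 1)))
    b <- sort(sample.int(80, sample(4:12, 1)))
    child <- ga_crossover(a, b, cfg)
    expect_true(all(child %in% union(a, b)))
    expect_true(length(child) %in% c(length(a), length(b)))
    child_sizes[i] <- length(child)
  }
  expect_true(all(child_sizes >= 3L))
})

test_that("mutation toggles at the configured per-feature rate and repairs bounds", {
  cfg <- ga_config(population_size = 5L, max_generations = 1L,
                   n_components = 1L, max_features = 50L,
                   mutation_prob = 0.05, seed = 1L)
  base <- sort(sample.int(50L, 25L))
  cfg0 <- cfg; cfg0$mutation_prob <- 0
  expect_identical(ga_mutate(base, cfg0, 50L), base)
  set.seed(8)
  toggles <- 0L
  n_trials <- 10000L
  for (i in seq_len(n_trials)) {
    out <- ga_mutate(base, cfg, 50L)
    toggles <- toggles + length(setdiff(out, base)) + length(setdiff(base, out))
    expect_true(length(out) >= 2L && length(out) <= 50L)
  }
  # exact binomial 99% interval around 0.05 over n_trials * 50 feature draws
  n_draws <- n_trials * 50L
  ci <- qbinom(c(0.005, 0.995), n_draws, 0.05)
  expect_gte(toggles, ci[1])
  expect_lte(toggles, ci[2])
  # repair pulls undersized results back above the minimum
  tiny <- ga_mutate(c(5L, 6L), cfg0, 50L)
  expect_gte(length(tiny), 2L)
})

test_that("the GA run is deterministic, elitist-monotone, and bound-safe", {
  gen <- generate_spectra(enrichment_config(), seed = 31)
  cfg <- ga_config(population_size = 10L, max_generations = 5L,
                   n_components = 2L, max_features = 10L, seed = 99L)
  r1 <- run_ga(gen$spectra, cfg)
  r2 <- run_ga(gen$spectra, cfg)
  expect_identical(r1$best_subset, r2$best_subset)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(diff(r1$trajectory$best) >= 0))
  expect_lte(r1$generations_run, 5L)
  expect_true(length(r1$best_subset) >= 3L && length(r1$best_subset) <= 10L)
  expect_equal(r1$best_fitness,
               0.5 * r1$fitness_components[["r_calibration"]] +
               0.5 * r1$fitness_components[["r_loo"]])
})

test_that("GA selection enriches informative bands against the hypergeometric null", {
  # 30 samples, 200-point grid, ~12 informative indices; 50 independent
  # reduced runs (population 20, 10 generations)
  gen <- generate_spectra(enrichment_config(), seed = 77)
  m <- length(gen$truth$informative)
  cfg0 <- ga_config(population_size = 20L, max_generations = 10L,
                    n_components = 2L, max_features = 10L)
  seeds <- 1000 + seq_len(50)
  hits <- draws <- integer(50)
  for (r in seq_along(seeds)) {
    cfg <- cfg0; cfg$seed <- seeds[r]
    res <- run_ga(gen$spectra, cfg)
    hits[r] <- length(intersect(res$best_subset, gen$truth$informative))
    draws[r] <- length(res$best_subset)
  }
  p_val <- hyper_sum_upper_p(sum(hits), draws, m, 200L)
  expect_lt(p_val, 0.01)
})
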