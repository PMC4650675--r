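# Robustness experiment: repeatedly re-split the data 2:1 and refit three
# model variants -- all-feature PLSDA (baseline), a fixed GA-selected
# subset reused across replicates (scheme 1), and a fresh GA selection per
# replicate (scheme 2) -- then summarise each scheme's accuracies by the
# median with a bootstrap confidence interval.

#' Run the resampling model comparison
#'
#' @param set A `spectra_set` (the full data; each replicate draws its own
#'   stratified 2:1 train/test split).
#' @param schemes Character subset of `c("baseline", "scheme1", "scheme2")`.
#' @param n_replicates Number of re-splits (>= 2). 50 is a practical desk
#'   scale; the study design uses 1000.
#' @param fixed_subset Feature indices reused in every replicate; required
#'   when `"scheme1"` is run.
#' @param cfg `ga_config` used by scheme 2's per-replicate selection (and
#'   for subset-size validation of `fixed_subset`).
#' @param n_components Latent variables for every fitted model (default 26).
#' @param seed Master seed; replicate splits and GA runs derive from it.
#' @return An object of class `resample_result`: data frame `records` with
#'   one row per replicate x scheme (`calibration`, `loo`, `external` in
#'   percent) plus the run metadata.
#' @export
run_comparison <- function(set, schemes = c("baseline", "scheme1", "scheme2"),
                           n_replicates = 50L, fixed_subset = NULL,
                           cfg = ga_config(population_size = 20L,
                                           max_generations = 10L,
                                           n_components = n_components),
                           n_components = 26L, seed = 1L) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (n_replicates < 2L) stopf("need n_replicates >= 2")
  if ("scheme1" %in% schemes && is.null(fixed_subset))
    stopf("scheme1 requires a fixed_subset of GA-selected features")
  if (!is.null(fixed_subset))
    fixed_subset <- validate_chromosome(fixed_subset, cfg, ncol(set$absorbance))
  seeds <- derive_seeds(seed, 2L * n_replicates)
  rows <- vector("list", n_replicates * length(schemes))
  k <- 0L
  for (r in seq_len(n_replicates)) {
    parts <- stratified_split(set, seed = seeds[r])
    for (scheme in schemes) {
      subset <- switch(scheme,
        baseline = NULL,
        scheme1 = fixed_subset,
        scheme2 = {
          cfg_r <- cfg; cfg_r$seed <- seeds[n_replicates + r]
          run_ga(parts$train, cfg_r)$best_subset
        })
      model <- fit_plsda(parts$train, n_components, subset)
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = r, scheme = scheme,
        n_features = length(subset %||% set$wavenumbers),
        calibration = overall_accuracy(calibration_confusion(model, parts$train)),
        loo = overall_accuracy(loo_cv(parts$train, n_components, subset)),
        external = overall_accuracy(confusion_matrix(
          parts$test$labels, predict(model, parts$test), set$class_order)))
    }
  }
  structure(list(records = do.call(rbind, rows), n_replicates = n_replicates,
                 n_components = n_components, schemes = schemes, seed = seed),
            class = "resample_result")
}

# Percentile bootstrap CI of the median of x.
median_boot_ci <- function(x, n_boot, level = 0.95) {
  meds <- vapply(seq_len(n_boot),
                 function(b) stats::median(sample(x, replace = TRUE)),
                 numeric(1))
  stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

#' Summarise a resampling comparison
#'
#' Per scheme and accuracy metric: the median over replicates and a
#' seeded percentile-bootstrap 95% confidence interval of that median.
#'
#' @param result A `resample_result`.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame with columns `scheme`, `metric`, `median`, `ci_lower`,
#'   `ci_upper` (percentages).
#' @export
summarize_comparison <- function(result, n_boot = 1000L, seed = 1L) {
  rec <- result$records
  grid <- expand.grid(scheme = unique(rec$scheme),
                      metric = c("calibration", "loo", "external"),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(grid)), function(i) {
      x <- rec[rec$scheme == grid$scheme[i], grid$metric[i]]
      ci <- median_boot_ci(x, n_boot)
      data.frame(scheme = grid$scheme[i], metric = grid$metric[i],
                 median = stats::median(x), ci_lower = ci[1L], ci_upper = ci[2L])
    })
    do.call(rbind, out)
  })
}
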