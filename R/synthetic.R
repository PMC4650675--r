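# Synthetic NIR soil spectra with known ground truth. Each spectrum is an
# affine baseline (mimicking scatter offsets, since no scatter correction
# is applied downstream) plus Gaussian absorption bands with per-sample
# amplitude draws truncated at zero, plus white noise. Band positions
# follow the diagnostic regions of the five soil classes: structural and
# adsorbed-water -OH overtones shared by all soils, organic-matter
# combination bands, a carbonate band near 4287 cm-1 (calcareous
# Chernozems and Eutric Cambisols) and illite bands near 4094/4050/4046
# cm-1 (the mica-derived mineralogy of Albic Luvisols).

band <- function(center, width, amplitude, amplitude_sd) {
  data.frame(center = center, width = width, amplitude = amplitude,
             amplitude_sd = amplitude_sd)
}

#' Synthetic spectra configuration
#'
#' @param class_names Ordered class names.
#' @param n_per_class Integer sample counts per class (each >= 2).
#' @param grid_points Number of wavenumbers (default 1816).
#' @param grid_range Wavenumber range, high to low (default 7500 to 4000).
#' @param shared_bands Data frame of bands (columns `center`, `width`,
#'   `amplitude`, `amplitude_sd`; cm-1 for the first two) common to all
#'   classes.
#' @param class_bands Named list (one per class) of class-discriminating
#'   band data frames in the same format.
#' @param baseline_intercept Named numeric vector: per-class mean baseline
#'   absorbance offset.
#' @param baseline_intercept_sd,baseline_slope,baseline_slope_sd Per-sample
#'   baseline variation: the intercept and the slope (per unit of
#'   normalised wavenumber position) are drawn independently per sample.
#' @param noise_sd Additive white-noise standard deviation.
#' @param seed Default seed used by [generate_spectra()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(class_names, n_per_class, grid_points = 1816L,
                             grid_range = c(7500, 4000), shared_bands,
                             class_bands, baseline_intercept,
                             baseline_intercept_sd = 0.03,
                             baseline_slope = 0.05, baseline_slope_sd = 0.02,
                             noise_sd = 0.005, seed = 1L) {
  cfg <- list(class_names = as.character(class_names),
              n_per_class = as.integer(n_per_class),
              grid_points = as.integer(grid_points),
              grid_range = as.numeric(grid_range),
              shared_bands = shared_bands, class_bands = class_bands,
              baseline_intercept = baseline_intercept,
              baseline_intercept_sd = baseline_intercept_sd,
              baseline_slope = baseline_slope,
              baseline_slope_sd = baseline_slope_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (length(cfg$n_per_class) != length(cfg$class_names) || any(cfg$n_per_class < 2L))
    stopf("n_per_class must give >= 2 samples for each class")
  if (cfg$grid_range[1L] <= cfg$grid_range[2L])
    stopf("grid_range must run from high to low wavenumber")
  if (!setequal(names(cfg$class_bands), cfg$class_names))
    stopf("class_bands must be named by the class names")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  all_bands <- rbind(cfg$shared_bands, do.call(rbind, unname(cfg$class_bands)))
  if (any(all_bands$center > cfg$grid_range[1L] | all_bands$center < cfg$grid_range[2L]))
    stopf("band centers must lie inside the grid range")
  if (any(all_bands$width <= 0)) stopf("band widths must be > 0")
  structure(cfg, class = "synthetic_config")
}

#' Default five-soil-class configuration
#'
#' Emulates the study conditions: the five FAO classes with their observed
#' sample counts (36, 72, 29, 45, 48; total 230) on the 1816-point
#' 7500-4000 cm-1 grid. Shared high-amplitude -OH bands sit near 7065,
#' 5222 and 4527 cm-1; class-discriminating bands follow the diagnostic
#' assignments (illite for Albic Luvisols, carbonate for Chernozems and
#' Eutric Cambisols, organics for Chernozems and Phaeozems, -OH shoulders
#' for the Luvisols). Baseline offsets order the mean spectra with
#' Chernozems highest and Albic Luvisols lowest.
#'
#' @param n_per_class Optional override of the per-class sample counts.
#' @param seed Default generation seed.
#' @return A `synthetic_config`.
#' @export
default_soil_config <- function(n_per_class = c(36L, 72L, 29L, 45L, 48L),
                                seed = 1L) {
  classes <- soil_classes()
  shared <- rbind(band(7065, 80, 0.12, 0.015),
                  band(5222, 45, 0.15, 0.015),
                  band(4527, 35, 0.10, 0.012))
  class_bands <- list(
    "Albic Luvisols"   = rbind(band(4094, 25, 0.09, 0.02),   # illite
                               band(4050, 20, 0.08, 0.02),
                               band(4046, 20, 0.05, 0.015),
                               band(7463, 60, 0.05, 0.015)), # -OH shoulder
    "Haplic Luvisols"  = rbind(band(7037, 55, 0.07, 0.02),   # -OH
                               band(4505, 25, 0.08, 0.02)),
    "Chernozems"       = rbind(band(4287, 30, 0.10, 0.02),   # carbonate
                               band(5292, 35, 0.07, 0.02)),  # organics
    "Eutric Cambisols" = rbind(band(4287, 30, 0.06, 0.015),  # carbonate
                               band(4503, 22, 0.07, 0.02),
                               band(5263, 30, 0.05, 0.015)), # -OH
    "Phaeozems"        = rbind(band(4320, 25, 0.08, 0.02),   # organics
                               band(4316, 25, 0.05, 0.015),
                               band(5263, 30, 0.06, 0.015))) # -OH
  synthetic_config(
    class_names = classes, n_per_class = n_per_class,
    shared_bands = shared, class_bands = class_bands,
    baseline_intercept = c("Albic Luvisols" = 0.25, "Haplic Luvisols" = 0.35,
                           "Chernozems" = 0.45, "Eutric Cambisols" = 0.40,
                           "Phaeozems" = 0.42),
    seed = seed)
}

#' Generate a synthetic spectra set with ground truth
#'
#' Deterministic for a fixed seed. The ground truth marks, per class, the
#' grid indices lying within one band width of any of that class's
#' discriminating band centers; the global informative set is their union.
#'
#' @param config A `synthetic_config`.
#' @param seed Seed (default `config$seed`).
#' @return List with `spectra` (a `spectra_set`) and `truth` (list with
#'   `per_class` index lists, `informative` global indices, and the echoed
#'   `config`).
#' @export
generate_spectra <- function(config, seed = config$seed) {
  wn <- seq(config$grid_range[1L], config$grid_range[2L],
            length.out = config$grid_points)
  xnorm <- (config$grid_range[1L] - wn) /
    (config$grid_range[1L] - config$grid_range[2L])      # 0 at high, 1 at low
  n <- sum(config$n_per_class)
  labels <- rep(config$class_names, config$n_per_class)
  gauss <- function(center, width) exp(-0.5 * ((wn - center) / width)^2)
  X <- matrix(0, n, config$grid_points)
  with_seed(seed, {
    for (i in seq_len(n)) {
      cls <- labels[i]
      spec <- stats::rnorm(1, config$baseline_intercept[[cls]],
                           config$baseline_intercept_sd) +
        stats::rnorm(1, config$baseline_slope, config$baseline_slope_sd) * xnorm
      bands <- rbind(config$shared_bands, config$class_bands[[cls]])
      for (b in seq_len(nrow(bands))) {
        amp <- max(0, stats::rnorm(1, bands$amplitude[b], bands$amplitude_sd[b]))
        spec <- spec + amp * gauss(bands$center[b], bands$width[b])
      }
      X[i, ] <- spec + stats::rnorm(config$grid_points, 0, config$noise_sd)
    }
  })
  per_class <- lapply(config$class_names, function(cls) {
    bands <- config$class_bands[[cls]]
    sort(unique(unlist(lapply(seq_len(nrow(bands)), function(b)
      which(abs(wn - bands$center[b]) <= bands$width[b])))))
  })
  names(per_class) <- config$class_names
  ids <- sprintf("s%03d_%s", seq_len(n), abbreviate(gsub(" ", "", labels), 6))
  list(spectra = spectra_set(wn, X, ids, labels, config$class_names),
       truth = list(per_class = per_class,
                    informative = sort(unique(unlist(per_class))),
                    config = config))
}

#' Write a synthetic configuration to a YAML file
#'
#' @param config A `synthetic_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  obj <- unclass(config)
  obj$shared_bands <- lapply(seq_len(nrow(obj$shared_bands)),
                             function(i) as.list(obj$shared_bands[i, ]))
  obj$class_bands <- lapply(obj$class_bands, function(df)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])))
  obj$baseline_intercept <- as.list(obj$baseline_intercept)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a synthetic configuration from a YAML file
#'
#' @param path Path to a file written by [write_synthetic_config()].
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  as_band_df <- function(rows) do.call(rbind, lapply(rows, as.data.frame))
  synthetic_config(
    class_names = obj$class_names, n_per_class = obj$n_per_class,
    grid_points = obj$grid_points, grid_range = obj$grid_range,
    shared_bands = as_band_df(obj$shared_bands),
    class_bands = lapply(obj$class_bands, as_band_df),
    baseline_intercept = unlist(obj$baseline_intercept),
    baseline_intercept_sd = obj$baseline_intercept_sd,
    baseline_slope = obj$baseline_slope,
    baseline_slope_sd = obj$baseline_slope_sd,
    noise_sd = obj$noise_sd, seed = obj$seed)
}
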