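---
title: "Methods: PLS discriminant analysis of soil NIR spectra with GA wavelength selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS discriminant analysis of soil NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilplsda)
```

# The problem

Near-infrared diffuse reflectance spectra of soils (7500–4000 cm⁻¹,
1816 points on the instrument grid this package assumes) integrate
overtone and combination bands of -OH, organic matter, carbonates and
clay minerals. Different soil classes — here the five FAO classes Albic
Luvisols, Haplic Luvisols, Chernozems, Eutric Cambisols and Phaeozems —
differ systematically in these constituents, so a spectrum carries enough
information to recognise the class. The statistical obstacles are that
the feature count (p = 1816) far exceeds the sample count, and that
neighbouring wavenumbers are almost perfectly collinear. PLS regression
is the standard chemometric answer to both.

# The discriminant model

## PLS2 on an indicator response

Labels are encoded as an n × K binary indicator matrix with one column
per class (`encode_indicator()`); the class order is fixed (the order of
`soil_classes()`) and defines indicator columns and all tie-breaking.
`fit_pls2()` regresses the indicator matrix on the spectra with the PLS2
algorithm, which calibrates all K response columns simultaneously through
shared latent variables.

Both blocks are mean-centered and **not** variance-scaled: absorbance
features share a common magnitude scale, so scaling would only inflate
noise wavenumbers. Centering is considered part of the regression, not a
pretreatment; no derivative, SNV or scatter correction is applied
anywhere in the pipeline.

Components are extracted NIPALS-style with X-deflation only. For each
component the NIPALS inner loop's fixed point — **w** ∝ X'Y**q**,
**q** ∝ Y'X**w** — is computed by power iteration on the K × K matrix
(Y'X)(X'Y) (implemented in compiled code, `src/pls.cpp`), which converges
to the same weight vector as the textbook sample-space loop at a fraction
of the cost for small K. The test suite verifies equivalence against an
independently coded textbook NIPALS loop on random small instances, and
against multiresponse least squares at full rank.

Numerical choices:

* inner-loop tolerance 1e-10 (relative change of the unit q-vector),
  maximum 500 iterations;
* per-component sign fixed by making the largest-magnitude weight entry
  positive — predictions, coefficients and VIP are sign-invariant, but a
  convention keeps stored decompositions reproducible bit-for-bit;
* rank exhaustion (weight or score norm numerically zero) is an error
  naming the offending component rather than a silent truncation;
* a constant (zero-variance) response matrix is rejected; single constant
  columns are tolerated and simply receive zero loadings.

## Class assignment

`assign_class()` implements the maximum-predicted-value rule: a sample
goes to the class whose predicted indicator value is largest. Exact ties
go to the earliest class in the declared order — a deterministic and
documented convention (ties have measure zero on continuous data but do
occur in degenerate tests). Accuracy bookkeeping (`confusion_matrix()`,
`overall_accuracy()`, `per_class_accuracy()`) follows the conventional
table layout: true-class rows, predicted-class columns, per-class
accuracy = 100·diagonal/row-sum. A class absent from the data yields an
undefined (NA) per-class accuracy, never 0, so means stay honest.

## Validation

* **Calibration**: accuracy of the fitted model on its training samples.
* **LOO cross-validation** (`loo_cv()`): each sample is predicted by a
  model refitted on the other n − 1 samples with fresh centering, so no
  information from the held-out spectrum leaks into the fold. Re-centering
  per fold is the statistically correct reading and is the implemented
  behaviour.
* **External validation**: a stratified 2:1 train/test split
  (`stratified_split()`). Per class the training count is
  round(2n_c/3), rounding to nearest — the rule that reproduces the
  allocation 36/72/29/45/48 → 24/48/19/30/32 exactly, including the
  non-divisible 29 → 19. Rounding half-cases cannot occur at the 2:1
  ratio (2n/3 is never a half-integer).

`accuracy_curve()` tabulates all three accuracies for a = 1..30
components with no smoothing; the LOO column reuses one refit per
held-out sample (fitted at the maximum a) since truncating a PLS model to
fewer components is exact.

# Variable importance

`vip_scores()` computes per-class VIP at a chosen component count a:

VIP²ⱼₖ = p · Σ_{c≤a} SSYₖc (wⱼc/‖w_c‖)² / Σ_{c≤a} SSYₖc, with
SSYₖc = q²ₖc·t'_c t_c.

The per-class SSY weighting is chosen deliberately: each soil class
weighs components by how much of *its own* indicator variance they
explain, which is what makes per-class importance sets differ. The
normalization Σⱼ VIP²ⱼₖ = p holds per class and is asserted in the
tests. The component count at which VIP is evaluated is an explicit
argument (defaulting to the fitted model's count) since importance is
only defined relative to a model size. `high_vip_features()` applies the
conventional VIP ≥ 1 rule per class and intersects across classes.

# GA wavelength selection

A chromosome is an explicit sorted index set, not a fixed-length bit
mask, so the size bounds — at least A + 1 features (one more than the
latent-variable count, keeping every candidate model identifiable) and at
most 75 — are first-class and re-validated every generation.

The fitness of a subset is fitness = w_cal·r_calibration + w_LOO·r_LOO,
with both accuracies as fractions and default weights ½/½. The two named
components are exposed separately in every result. The default target
fitness of 1.0 (perfect calibration and LOO) together with the generation
cap gives the standard two-part stopping rule. The equal-weight linear
combination is a design choice: the two accuracy components are on the
same scale and neither is privileged a priori; the weights (and thus any
other convex combination) are configurable in `ga_config()`. A
size-penalty term was considered and rejected for the default because the
hard 75-feature cap already bounds complexity.

Operators:

* **selection** — tournament of 2 (rank-robust, standard when only
  "highest fitness recombines" is specified);
* **crossover** — the child draws its features without replacement from
  the parents' union; its size is the size of a randomly chosen parent,
  clamped to the bounds (identical parents therefore reproduce exactly);
* **mutation** — every grid feature toggles independently with
  probability 0.05 per generation, followed by random repair back into
  the size bounds; the pre-repair toggle rate is verified against the
  exact binomial interval in the tests;
* **elitism** — the best chromosome survives unchanged (making the best
  fitness trajectory non-decreasing, which the tests assert).

Defaults: population 50, at most 20 generations, 26 latent variables
inside the GA (the final model's count; applied to selection as well
since no separate value is specified), one master seed from which
per-generation streams derive deterministically. Fitness values are
cached per chromosome, so elitism and converged populations cost nothing
to re-evaluate. LOO inside the fitness is exact (not k-fold): the
compiled core makes the full refit loop affordable even at study scale.
A single GA run yields a single subset; no cross-run aggregation is
performed.

# The robustness comparison

`run_comparison()` re-splits the data per replicate (a full new
stratified 2:1 split — training *and* test re-drawn, the natural reading
of re-sampled training sets under a fixed ratio) and fits up to three
variants at 26 components: all features (baseline), a fixed GA subset
(scheme 1), and a per-replicate GA re-selection (scheme 2).
`summarize_comparison()` reports, per scheme and metric, the median over
replicates with a percentile-bootstrap 95% CI **of the median** (1000
seeded draws). A median CI — rather than a replicate-distribution
interval — is chosen because the quantity of interest is the location of
the accuracy distribution, and its uncertainty shrinks with the number of
replicates. The default desk scale is 50 replicates with a reduced GA
(population 20, 10 generations) for scheme 2; 1000 replicates and the
full GA reproduce the original experimental scale via arguments.

# The synthetic generator

`generate_spectra()` builds each spectrum as

absorbance = intercept + slope·x + Σ_bands amp·exp(−(ν−center)²/2σ²) + ε,

where x is the normalised grid position, per-sample intercept and slope
are Gaussian (affine baselines mimic scatter offsets, which matter here
precisely because no scatter correction is applied downstream), band
amplitudes are Gaussian draws truncated at zero (absorbance stays
physically nonnegative), and ε is white noise.

`default_soil_config()` encodes the study conditions: five classes with
sample counts 36/72/29/45/48 (230 total) on the 1816-point 7500–4000 cm⁻¹
grid; shared high-amplitude -OH bands near 7065, 5222 and 4527 cm⁻¹;
class-discriminating bands at the diagnostic positions — illite
4094/4050/4046 cm⁻¹ for Albic Luvisols, carbonate 4287 cm⁻¹ amplified for
Chernozems and Eutric Cambisols, organics 5292/4320/4316 cm⁻¹ split
between Chernozems and Phaeozems, -OH shoulders 7463/7037/5263/4505/4503
cm⁻¹ distributed over the Luvisols and Cambisols — and baseline offsets
ordering mean absorbance with Chernozems highest and Albic Luvisols
lowest. Where the emulated conditions fix no value (band widths,
amplitudes, baseline and noise scales), values were chosen once to give a
clearly class-structured but noisy spectrum family: widths 20–80 cm⁻¹,
class-band amplitudes 0.05–0.10 absorbance units against baselines of
0.25–0.45, noise SD 0.005. The grid follows the stated point count
(1816 over 3500 cm⁻¹ ≈ 1.93 cm⁻¹ spacing), not the nominal 4 cm⁻¹
optical resolution.

Gaussian band shapes (rather than Lorentzian/Voigt) are a modelling
convenience adequate for testing classification structure — not a
spectroscopy claim. The generator also does **not** emulate instrument
line-shape effects, non-linear baseline curvature, particle-size scatter
correlations between neighbouring classes, or the long-range spatial
correlation of field sampling. Consequently the synthetic task is
*easier* than the real one: with the default configuration the
class-discriminating bands are strong, and accuracies near 100% are
expected. Passing tests therefore demonstrate correctness of the
machinery (the estimators, the cross-validation accounting, the GA's
selection pressure toward truly informative wavenumbers), not the
field-data accuracy levels, which cannot be reproduced without the
original soil spectra.

Ground truth lists, per class, the grid indices within one band width of
a class-discriminating band center; the GA enrichment test measures
selection of exactly these indices against the exact hypergeometric null.

# Problem sizes in the shipped tests

The suite exercises every component at sizes chosen to keep a full run
in the minutes range while preserving the properties under test: oracle
equivalence on n, p ≤ 12; GA behaviour and scheme comparisons on a
two-class 200-point fixture (30 samples, ~12 informative indices, GA
population 20 × 10 generations, 50 enrichment runs, 20 replicates × 5
experiment seeds); and one deterministic end-to-end pipeline at full
study shape (230 × 1816, 26 components, all three schemes × 20
replicates). The acceptance script repeats the study-shaped pipeline and
additionally recomputes every accuracy of the two shipped reference
confusion tables from their raw counts. One of those printed table cells
(the GA-model testing mean) is internally inconsistent with its own
counts, which give 93.51%; the package reports the value computed from
the counts.

# Known limitations

* The discriminant rule is the maximum predicted indicator value;
  centroid or Mahalanobis distances and probabilistic posteriors are out
  of scope.
* No spectral pretreatment (derivatives, SNV, OSC) and no resampling
  between wavenumber grids: inputs must share the training grid.
* The GA is a stochastic local search; different seeds select different
  (overlapping) subsets of comparable fitness. Single-run semantics are
  deliberate.
* Bootstrap CIs of the median are percentile intervals; no BCa
  correction.
* `read_spectra_csv()` reads the package's wide CSV dialect only — no
  SPC/JCAMP-DX instrument formats.
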