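---
title: "Methods: predicting sample origin from microbial abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting sample origin from microbial abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

geomicrobe asks a forensic question of a taxa-by-sample count table:
*where was this sample collected?* It provides two complementary answers
— a regression that predicts latitude and longitude directly, and a
classifier that assigns one of the trained cities — plus an open-set
detector that flags samples whose true origin was probably never
sampled at all. This vignette documents the statistical choices behind
each stage, what the synthetic data generator does and does not
emulate, and the numerical conventions the implementation fixes.

## Normalization and features

Shotgun libraries differ in depth by orders of magnitude, and a
handful of dominant taxa can carry most of the reads. Total-sum
(relative abundance) scaling lets those dominant taxa set the
denominator for everyone. Cumulative sum scaling (CSS) instead divides
each sample by the summed counts of its *lower-abundance* taxa: for
sample $j$, the cutoff $q_j$ is the 50th percentile of the sample's
positive counts, the scaling factor is
$s_j = \sum_{i:\,c_{ij} \le q_j} c_{ij}$, and the normalized abundance
is $c_{ij} / s_j \times 1000$.

Conventions the implementation fixes, because the CSS idea leaves them
open:

* the percentile is taken over **positive** counts only, with the
  linear-interpolation (type 7) quantile;
* counts **equal** to the cutoff are included in the scaling sum;
* the post-scaling constant is 1000 — any positive constant only
  shifts the log2 intercept of every feature, so nothing downstream
  depends on it;
* samples with no reads at all are an error, not a silent `NaN`.

Before normalization, sparse taxa are removed: a taxon is kept only if
**strictly more than** `min_samples_exceed` samples give it at least
`min_reads` (default 100) reads. The strict inequality matters at the
boundary — a taxon reaching 100 reads in exactly two samples survives
the default filter, one doing so in a single sample does not.

Model features are `log2(normalized + 1)` — the pseudocount of 1 keeps
zeros at zero before standardization — z-scored per taxon with means
and standard deviations estimated **on training data only**. The fitted
scaler travels with the model; test folds and mystery samples are
always transformed with the training statistics, which is the
no-leakage contract the cross-validation tests assert by recomputation.
Zero-variance features are dropped at scaler-fitting time and never at
prediction time. Standardization is performed explicitly before the
penalized fits (with glmnet's internal standardization disabled); doing
it inside the fit would give the same paths up to a re-scaling of
lambda.

## The two origin models

**Coordinate regression.** Latitude and longitude are modeled jointly
by a multi-task Lasso (glmnet's `mgaussian` family): each taxon's
coefficient pair $(\beta_{lat}, \beta_{lon})$ is penalized by its
Euclidean norm, so a taxon enters or leaves *both* responses together.
This matches the biology being exploited — a taxon whose abundance
tracks location is informative about the place, not about one
coordinate — and gives cleaner feature selection than two independent
Lassos (which remain available via `multi_task = FALSE`). Coordinates
are treated as plain Euclidean responses; there is no longitude
wrap-around and no geodesic loss, which is a known limitation near the
date line.

**City classification.** An L1-penalized multinomial logistic
regression with per-sample weights $w_i = 1 - n_{c(i)}/N$, so
heavily sampled cities do not dominate the weighted deviance. Weights
are used exactly as given (not renormalized to sum to $n$; that choice
only rescales the effective lambda and is documented here so the
numbers are reproducible). The penalty is ungrouped across classes —
a taxon may discriminate one city and be irrelevant elsewhere — with
`grouped = TRUE` available. Argmax ties are broken toward the first
city in sorted order, a deterministic convention.

Both models select lambda by internal 10-fold cross-validation with
the **one-standard-error rule**: the largest lambda whose CV error is
within one SE of the minimum. The CV error for the regression is the
summed MSE over both coordinates (sum and mean select the same lambda,
being a monotone rescaling). Internal folds are stratified by city and
all fold assignments derive from a caller-supplied seed. The lambda
path uses 100 log-spaced values down to $10^{-3}\lambda_{max}$.

A down-sampled random forest (`fit_rf_downsampled`) is included as the
nonlinear baseline: every tree's bootstrap is down-sampled to the
minority-class size per class, and out-of-bag predictions are kept.

To compare a classifier with the regression on one scale, predicted
cities are *bridged* to coordinates: a sample assigned to a city is
scored at that city's latitude and longitude. The classifier therefore
competes on mean squared error in squared degrees, like the regression.

## Two cross-validation designs, two questions

Nested 10-fold CV answers: *how well do we place samples from cities
we have already sampled?* Outer folds are stratified by city, so every
training portion contains every city; the scaler and the model's
internal lambda search are refit within each outer fold.

Leave-one-city-out (L1CO) CV answers the forensically harder question:
*what happens when the true origin was never sampled?* All samples of
one city are held out together. For the classifier the confusion
diagonal is then structurally zero — the true label is not a class.
For both models the L1CO error is expected to exceed, usually several
times over, the nested 10-fold error; the test suite asserts this
ordering across seeds.

Model scoring reports MSE per coordinate (squared degrees), their sum,
and $r^2$ defined as the **squared Pearson correlation** between
predicted and true values — the quantity a prediction scatterplot is
annotated with. This differs from $1 - SS_{res}/SS_{tot}$ for biased
predictors, which is why the definition is pinned here. A constant
predictor has no defined correlation; it is reported as $r^2 = 0$ with
a warning. Per-city model comparisons use one-sided Wilcoxon rank-sum
tests on total squared errors (exact p-values below 50 observations),
Benjamini-Hochberg adjusted across cities.

## Novelty detection from prediction ambiguity

A classifier cannot name a never-sampled city, but it can *hesitate*.
The Simpson index of a sample's class-probability vector,
$1 - \sum_k p_k^2$ (the Gini impurity), is 0 for a confident one-hot
prediction and approaches $1 - 1/K$ for maximal ambiguity. The
detector is trained on each sample's held-out probabilities from the
two CV designs: nested 10-fold probabilities mimic a *pre-trained*
origin, L1CO probabilities mimic a *new* origin — giving $2N$ labeled
ambiguity values for $N$ samples.

A Bayes classifier with one Gaussian kernel density per setting learns
the two distributions. Bandwidths follow Silverman's rule (`bw.nrd0`)
per class, with a fixed fallback of $10^{-3}$ for degenerate
zero-variance groups; priors default to the empirical class
frequencies (equal by construction when every sample contributes one
record per setting; `priors = "equal"` is available); the decision
threshold is a posterior of 0.5, and the ROC over all thresholds is
exposed. No boundary reflection is applied to the densities near 0 and
$1 - 1/K$ — a documented simplification that slightly smears mass
outside the support. Leave-one-out evaluation refits both densities
(including bandwidths) without the held-out value. The posterior is
computed by explicit kernel sums and is tested against an independent
brute-force implementation at $10^{-10}$.

## What the synthetic generator emulates

`generate_world` + `synthetic_truth` + `generate_counts` build a
city-structured world with a known, recoverable geographic signal:

* **Geography.** Cities are uniform over latitude $[-55, 65]$ and
  longitude $[-170, 170]$ (the inhabited band); continents are six
  longitude/latitude blocks, enough for continent-level assessment
  without geographic data files.
* **Taxonomy.** 200 species nest into 60 genera and 25 families by a
  random mapping under the seed; coarser tables are exact column sums,
  an identity the tests assert.
* **Geographic signal.** 10 informative species change expected log2
  abundance by ±0.05 per degree latitude and ±0.02 per degree
  longitude — the latitudinal-gradient magnitude that makes a taxon
  span about six log2 units across the globe. The two coordinates get
  orthogonal sign patterns (period 2 vs period 4) so their effects are
  identifiable rather than confounded, and informative taxa are given
  a fixed mid-abundance baseline: a gradient of six log2 units is only
  observable if the taxon stays above the detection floor at its low
  end.
* **City signatures.** Every (taxon, city) pair receives a log2 effect
  drawn N(0, 1), seeded from the city id so a city keeps its signature
  across panels while distinct cities — including train vs mystery —
  never share one. The default of 1 log2 unit puts the nested
  classification accuracy in the mid-0.9s, the regime urban microbiome
  classifiers actually reach; much weaker signatures make even
  pre-trained predictions diffuse and the ambiguity contrast
  disappears.
* **Counts.** Expected abundances are closed to proportions, scaled to
  a library size uniform in [50k, 200k], thinned by structural zeros
  (probability 0.05 per taxon-sample), and drawn from a negative
  binomial with dispersion 0.5 — overdispersed shotgun-like counts
  without fitting any real dataset.
* **Protocol batch.** A single-end 125 bp city receives a +6 log2
  shift on a fixed random half of all taxa. The artifact is drawn
  before any panel-dependent randomness, so a single-end training city
  and a single-end mystery city share the same artifact — the
  situation in which mixing protocols visibly corrupts mystery
  predictions. The magnitude is deliberately far above the city
  signatures: a protocol change dominates biological differences,
  which is exactly what makes it dangerous as training data, and at
  this size the batch city separates on the first principal
  coordinate.

The generator deliberately omits several properties of real urban
microbiome data: no phylogenetic covariance between taxa, no
seasonality, surface type, or transport-network structure, no
correlation between library size and city, and no real taxon names.
Passing tests on this generator therefore demonstrate that the
pipeline recovers planted, linearly coded geographic structure under
compositional closure, CSS, overdispersion and zero inflation — not
that real cities are this well behaved.

A "noiseless signal" condition used by the recovery tests sets city
signatures and zero inflation to zero while keeping the count model;
under it the nested-CV latitude $r^2$ of the regression exceeds 0.9,
so the ceiling of the method on clean data is visible in the suite.

## Numerical and design conventions

* All generators and fits are bit-reproducible under a caller seed;
  per-city RNG streams derive from a small polynomial hash of the city
  id.
* Simpson values are validated to be probability vectors within
  $10^{-6}$; probabilities for classes a fold's model never saw are
  `NA` and excluded from the index.
* `pcoa_cailliez` adds the smallest constant removing negative
  eigenvalues (via ape) and returns it; 0 means the input was already
  Euclidean.
* Bray-Curtis between two all-zero samples is undefined and raised as
  an error rather than returned as `NaN`.
* Taxon overlap percentages are rounded to whole percents; the
  denominator ("perspective") is explicit.

## Problem sizes in the test suite

The full study configuration — 15 training cities of 18 samples, 8
mystery cities, 200 species — runs end to end in a few minutes and is
what `scripts/acceptance.R` executes. Property checks that repeat over
20 seeds use reduced worlds (6–8 cities, 8–10 samples per city,
100–120 species) chosen as the smallest sizes at which the asserted
contrasts — L1CO error above nested error, higher ambiguity for new
origins, artifact-inflated mystery error — are stable across seeds.

## Known limitations

* Euclidean coordinate loss: longitudes −179 and 179 are treated as
  far apart; errors near the date line are overstated.
* The classifier can only ever place a new origin at its nearest
  trained city; the ambiguity flag mitigates but does not remove this.
* The $r^2$-by-correlation convention can flatter biased predictors;
  MSE is the primary metric.
* KDE densities are unbounded-support approximations to distributions
  living on $[0, 1 - 1/K]$.
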