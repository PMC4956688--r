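---
title: "Methods and design of mvpamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mvpamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpamap)
```

# The dataset model

All analyses in mvpamap operate on one structure, built by
`mvpa_dataset()`: a numeric `samples` matrix (observations in rows,
measurement locations in columns), a per-sample attribute table `sa`, a
per-feature attribute table `fa`, and general attributes `a`. Two `sa`
columns are reserved: `targets` holds integer condition labels and
`chunks` marks groups of samples that can be treated as statistically
independent — acquisition runs for fMRI, trials for M/EEG. Everything
that respects chunk boundaries (partitioning, label permutation,
split-half assignment) keys off this column, which is what licenses the
exchangeability assumptions of the permutation machinery below.

Multi-dimensional feature spaces are described declaratively:
`a$fdim$labels` names the dimensions in order, `a$fdim$values` lists the
coordinate values of each, and for every label an `fa` column stores
1-based positions into that value list. The same mechanism applies to
the sample axis (`a$sdim`), which is how dissimilarity matrices and
time-generalization grids are represented. Indices are 1-based
everywhere, including inside the volumetric affine `a$vol$mat`, which
maps 1-based voxel indices to world millimetres; conversion to the
0-based convention of NIfTI files is a unit index shift applied
symmetrically on read and write so that round trips are exact.

`flatten_dataset()` enumerates a dense dimension grid with the *first*
listed dimension varying fastest (column-major over the listed order);
`unflatten_dataset()` inverts this, writing `fill` (default `NaN`) into
grid cells absent from the dataset. `dim_transpose()` moves dimensions
between the axes; it requires the dataset to be dense in the moved
dimensions — every combination of a moved position with a remaining
position must occur exactly once — and orders the new elements with the
original elements varying fastest. NaN values are propagated, never
silently dropped; `validate_dataset()` reports every broken invariant
rather than stopping at the first.

# Classifiers

`classify_lda()` fits class means and the pooled within-class
covariance with `n - C` degrees of freedom, regularized as
$\Sigma_r = \Sigma + \lambda\,\frac{\mathrm{tr}(\Sigma)}{p} I$ with
$\lambda = 0.01$. Scaling the ridge by the mean diagonal keeps
$\Sigma_r$ well conditioned when features outnumber training samples,
the normal situation inside a searchlight; when the pooled estimate is
undefined (one sample per class) the ridge is all that remains and the
rule degrades gracefully to nearest class mean. Class priors are equal —
balanced designs are the norm in this field — and prediction ties go to
the smallest class label so results are reproducible across platforms.
`classify_naive_bayes()` uses per-class, per-feature Gaussians with a
variance floor of 1e-12 (constant features must not break a searchlight
column) and *empirical* priors, the conventional choice for that model.
Both choices are design decisions of this package: they are documented,
tested against independent brute-force reimplementations of the same
discriminants, and not claimed to be bit-identical to any other
implementation.

# Measures

Measures share the signature `measure(ds, opt)` and return a dataset
with a single samples column, which is what lets the searchlight treat
them interchangeably.

*Cross-validation* (`crossvalidation_measure`) trains and predicts per
fold and reports pooled accuracy — total correct over total predictions
— rather than a mean of per-fold accuracies, so unequal fold sizes are
weighted correctly. Optional normalization (`demean`/`zscore`, the
latter with the n−1 denominator) estimates its parameters on the
training samples only and applies them to the test samples; features
whose training variance is zero are dropped for that fold. With
`output = "predictions"` each sample keeps the prediction from the last
fold that tested it; all shipped partition schemes test each sample at
most once per scheme.

*Split-half correlation* (`correlation_measure`) averages per-target
patterns within each half (the two chunk values if there are exactly
two, else a round-robin `chunkize` into two groups), correlates the
half-1 and half-2 patterns target-by-target, Fisher-transforms, and
contrasts the diagonal against the off-diagonal with weights $1/C$ and
$-1/(C(C-1))$ — mean within-condition minus mean between-condition
correlation, averaged over both half orderings. Correlations at
$|r| = 1$, which noiseless toy data produces, are clamped to
$1 - 10^{-15}$ with a warning before `atanh`.

*Representational similarity* (`target_dsm_corr_measure`) computes the
neural dissimilarity matrix (default one minus Pearson correlation
between condition patterns) and correlates its upper triangle with the
target's, Pearson by default, Spearman optionally. The upper triangle
is vectorized in row-major pair order (1,2), (1,3), …, (2,3), …
throughout the package, and `dissimilarity_matrix_measure` emits
exactly that ordering with the pair indices in `sa` and a sample
dimension descriptor, so unflattening along samples reproduces the
square matrix.

*Time generalization* (`dim_generalization_measure`) requires the
generalization dimension on the sample axis (via `dim_transpose`) and
chunks 1/2 marking train/test data. For each pair of positions it
gathers a window of `radius` positions around the train and test
centers, turns window positions into extra features, and applies the
inner measure with a single train-to-test fold. Near the sequence
boundaries the window offsets are restricted to those valid for *both*
centers of the pair — this keeps the train and test feature spaces
aligned at all `n^2` pairs, at the cost of slightly narrower windows at
the edges; the alternative (dropping boundary centers) would silently
change the output grid, which we considered worse.

# Neighborhoods and the searchlight

A neighborhood maps each center of an *output* feature space to a list
of *input* feature indices. Spherical neighborhoods measure Euclidean
distance in world millimetres through the volume affine and include
features at exactly the radius (closed ball); in fixed-count mode
candidates are ordered by (distance, feature index), a deterministic
tie-break. Interval neighborhoods select all features within an integer
bin radius of the center position, across all other dimensions.
Channel neighborhoods measure 2-D distance between sensor locations in
layout units; with `chantype = "combined_from_planar"` the centers are
per-location combined gradiometers while the selected features are both
planar gradiometers of every chosen location, so maps have one value
per sensor site without averaging the underlying pair.
`cross_neighborhood` forms the Cartesian product of center sets (first
part fastest) and intersects neighbor lists; crossed centers with empty
intersections are kept, and the searchlight writes NaN for them with a
warning rather than silently renumbering the output space.

The searchlight itself is deliberately trivial: slice, apply, stack,
attach the neighborhood's feature attributes. Centers are independent,
so the map is identical for any worker count; results are always
assembled in center order.

# Cluster-level inference

`montecarlo_cluster_stat` computes a feature-wise one-sample *t*
against `h0_mean` (zero-variance features are mapped to t = 0 when
their mean equals the null and to a capped ±100 otherwise, keeping the
enhancement loop finite), transforms the map with TFCE
($E = 0.5$, $H = 2$, $dh = 0.1$, the standard parameterization), and
compares each observed feature score against the Monte-Carlo
distribution of the *maximum* score across features, which controls
family-wise error. Sign-flipping multiplies each participant's centered
map by an independent ±1 per iteration; the slower null-map-sampling
mode draws one pre-computed first-level null map per participant with
replacement, a simplified variant of full null-map pipelines that skips
their additional feature-wise FDR stages — a scope decision, documented
here. Corrected p-values are $(1 + \#\{\max \ge \text{obs}\})/(n_{iter}+1)$,
clamped to $[1/(n_{iter}+1),\; n_{iter}/(n_{iter}+1)]$ so z-scores stay
finite; features with an observed score of exactly zero report z = 0.
By default the test is one-tailed when `h0_mean` is nonzero (accuracy
against chance) and two-tailed otherwise; an explicit `tails` always
wins. The automatic adjacency (`feature_adjacency`) uses
26-connectivity for voxel dimensions, ±1 bin for time/frequency, and
sensor locations within `chan_radius = 1.5` layout units for channels
(8-connectivity on a unit grid), combined by conjunction across
dimension groups.

TFCE and connected-component labeling are implemented in C++ (the
permutation loops evaluate tens of thousands of enhancement passes); an
independent per-threshold R loop reproduces them exactly in the test
suite. The threshold ladder uses integer stepping (`h = k·dh`) — a
floating accumulator was observed to drop the top level.

# Synthetic data: what it does and does not emulate

The generators produce the structural layout of real designs, not their
physics. `make_toy_meeg` builds 18 planar gradiometers (9 locations on
a 3×3 unit grid) by 5 time bins of 0.1 s starting at stimulus onset,
with per-condition mean patterns injected on 8 channels from the second
bin onward; `make_toy_fmri` builds an isotropic 3 mm grid with a 3×3×3
signal block at positions 4–6 and, by default, a block design of 2
conditions × 4 runs × 4 repetitions (32 samples), the sample size of a
typical per-block GLM output; `make_group_maps` adds Gaussian noise to
a fixed effect vector, one map per participant. Noise is i.i.d.
Gaussian everywhere: there is no hemodynamic or evoked-response
temporal structure, no spatial autocorrelation, no inter-subject
variability in effect location. Passing tests therefore demonstrate the
correctness and calibration of the *algorithms* under their stated
assumptions, not performance on real recordings — in real data,
smoothness makes cluster inference more, not less, conservative under
the max-statistic, while autocorrelated noise can degrade decoding.

Effect size is the standard deviation of the per-feature condition
pattern in noise-SD units; 1 is a moderate multivariate effect (single
features are weak, the pattern across ~30 features decodes well), which
is the regime searchlight analyses are designed for.

A note on peak localization: a searchlight map is blurred by the
searchlight aperture, so an effect confined to a region produces peak
centers up to one radius outside it. The recovery checks in the test
suite and acceptance script therefore count a peak as recovering the
region when the peak center's searchlight contains planted voxels;
requiring the peak voxel itself to lie inside the block fails for a
third of otherwise perfect maps purely through this blur.

# Problem sizes and determinism

The test suite and `scripts/acceptance.R` use deliberately small
problems — the 90-feature M/EEG toy, 1000-voxel volumes, 100-feature
group maps with 100–200 permutation iterations, 20–200 simulation
repeats — sizes at which the statistical calibration checks (binomial
confidence intervals around chance accuracy and the nominal 5%
family-wise error) are already tight while a full run stays within a
coffee break on one CPU. Every stochastic component takes an explicit
seed, restores the caller's RNG state, and is a pure function of its
inputs, so all reported numbers are exactly reproducible.

# Known limitations

Surface-based (cortical-sheet) neighborhoods, native AFNI, BrainVoyager,
GIFTI, SPM, FieldTrip and EEGLAB formats, MEG source reconstruction,
multivariate regression and nested meta-parameter search are out of
scope; the portable `.plds` container and NIfTI are the interchange
formats. Group-level inference is the one-sample t design; factorial
(ANOVA) second levels are not provided. String targets must be mapped
to integers at the I/O boundary.
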