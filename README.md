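# mvpamap

Multivariate pattern analysis (MVPA) and searchlight information mapping
for volumetric fMRI and M/EEG channel/time data, with threshold-free
cluster enhancement (TFCE) and Monte-Carlo permutation testing for
multiple-comparison correction.

The package is aimed at cognitive-neuroscience researchers who want to
run decoding, pattern-correlation and representational similarity
analyses over arbitrary feature spaces — voxels, sensors, time bins,
frequency bins, and combinations of these — with a small set of
composable building blocks:

- **Dataset**: every analysis operates on one structure, a
  samples-by-features matrix with per-sample attributes (`targets` =
  condition labels, `chunks` = independence groups such as runs),
  per-feature attributes (dimension indices), and dimension descriptors
  that let the 2-D matrix be unflattened into voxel grids or
  channel-by-time arrays.
- **Measures**: functions `measure(ds, opt)` returning a single-column
  dataset — cross-validated classification accuracy, split-half
  correlation contrasts, representational similarity to a model
  dissimilarity matrix, pairwise dissimilarity matrices, and
  time-generalization matrices.
- **Neighborhoods**: per-center lists of input features — spherical
  (radius or fixed voxel count), interval (time/frequency windows),
  channel (sensor-layout proximity, including planar-pair to combined
  gradiometer mapping) — and their Cartesian products.
- **Searchlight**: applies any measure at every neighborhood center and
  assembles the per-center results into an information map over the
  neighborhood's output space.
- **Cluster statistics**: feature-wise group-level *t* statistics
  enhanced with TFCE,
  `TFCE(f) = Σ_h e(f,h)^E · h^H · dh` (extent `e`, height `h`, defaults
  `E = 0.5`, `H = 2`), and family-wise error corrected via the
  permutation distribution of the maximum statistic, using sign-flipping
  or sampling of per-participant null maps.

Classifiers (regularized LDA, Gaussian naive Bayes, optional SVM
adapter) share one signature, partitioning schemes (leave-one-chunk-out,
odd/even, take-k-out, cross-group decoding) generate train/test folds
from the chunk structure, and deterministic synthetic-data generators
produce all example and test inputs.

## Worked example

A time-resolved decoding analysis on a small synthetic M/EEG dataset
(18 planar gradiometers × 5 time bins, 3 conditions, 4 chunks):

```r
library(mvpamap)

ds <- make_toy_meeg(seed = 1)          # 12 samples x 90 features
nb <- interval_neighborhood(ds, "time", radius = 1)
map <- searchlight(ds, nb, crossvalidation_measure,
                   opt = list(classifier = classify_lda,
                              partitions = make_partitions(ds, "nfold")))
round(map$samples, 3)
#>       [,1] [,2] [,3]  [,4] [,5]
#> [1,] 0.833    1    1 0.917    1
```

One accuracy per time bin, each computed from all channels in a
three-bin window around that bin with leave-one-chunk-out
cross-validation; chance is 1/3, so every bin decodes far above chance
(the generator plants condition patterns from the second bin on).
Crossing the time neighborhood with a sensor neighborhood instead yields
a channel-by-time accuracy map; replacing the measure runs a
correlation or representational-similarity searchlight with the same
two lines.

Group-level inference on a stack of per-participant maps:

```r
gm  <- make_group_maps(n_participants = 20, n_features = 100,
                       true_effect = rep(c(0, 1, 0), c(45, 10, 45)),
                       seed = 2)
adj <- feature_adjacency(gm)
res <- montecarlo_cluster_stat(gm, adj,
                               list(niter = 200, h0_mean = 0,
                                    tails = 1, seed = 3))
res
#> mvpa_clusterstat: 100 features, 200 iterations (sign_flip, tfce, 1-tailed)
#>   max z = 2.578; 10 feature(s) with z > 1.96
which(res$z$samples[1, ] > 1.96)
#>  [1] 46 47 48 49 50 51 52 53 54 55
```

The ten features carrying the planted effect are exactly the ones
exceeding the corrected z threshold.

Command-line wrappers around the same functions are installed under
`inst/cli/` (`mvpa_searchlight`, `mvpa_clusterstat`); see their
`--help`-style usage text.

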