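Package: mvpamap
Title: Multivariate Pattern Analysis and Searchlight Information Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A uniform dataset structure for volumetric fMRI and M/EEG
    channel/time/frequency data, composable multivariate pattern analysis
    measures (cross-validated classification, split-half correlation,
    representational similarity analysis, time generalization), generalized
    neighborhoods over voxels, channels, time and frequency bins, a
    searchlight engine that applies any measure at every neighborhood
    center, and threshold-free cluster enhancement with Monte-Carlo
    permutation testing for multiple-comparison correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
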