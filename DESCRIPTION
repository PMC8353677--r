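Package: voxelSemantics
Title: Voxel-Wise Semantic Encoding Models for Natural-Speech fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a voxel-wise encoding-model pipeline for fMRI recorded
    during continuous natural speech. Timed, lemmatized word tokens are mapped
    through a word-embedding table to a feature-word similarity (markup) matrix,
    low-pass resampled onto the scanner TR grid with a Lanczos kernel, and
    delay-embedded to approximate the haemodynamic response. Voxel time series
    are predicted by ridge regression with cross-validated regularization; the
    resulting weight maps are reduced by PCA and clustered with k-means into
    semantic categories which are localized back to voxels. An individual-level
    analysis locates the cluster nearest to a set of threat-related seed words.
    A synthetic-data generator with planted ground truth makes every stage
    testable without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    RNifti
Suggests:
    withr,
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Neuroimaging, Regression, Clustering
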