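Package: chemolink
Title: Linking Ambient Chemical Mixtures to Transcriptomic Bioactivity
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for correlating environmental chemical-mixture
    fingerprints with whole-organism transcriptomic responses. Provides
    preprocessing for censored chemical concentration tables (detection
    filtering, k-nearest-neighbour imputation, standardization, PCA) and
    RNA-seq count matrices (count filtering, quantile-based
    normalization), bootstrap-ensemble gene coexpression network
    construction with scale-free topology thresholding and map-equation
    (Infomap) module detection, sparse generalized canonical correlation
    analysis (SGCCA) producing low-dimension representations and
    squared-weight contribution scores, module enrichment via
    Mann-Whitney U tests, pathway overrepresentation via chi-square
    tests, and a synthetic two-block data generator with planted latent
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    limma,
    mclust,
    mixOmics,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
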