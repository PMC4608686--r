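Package: txeq
Title: Transcriptome Equivalence Testing for Single-Channel Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical comparability analysis of gene expression responses
    measured on single-channel microarrays, built for biosimilar/generic
    equivalence studies. Raw foreground/background spot intensities are
    background-corrected with a normal-plus-exponential convolution model
    fitted per array, offset, log2-transformed, quantile-normalized and
    replicate-probe averaged. Treatment groups are then compared with a
    univariate battery (per-probe Student t-tests under uncorrected,
    Bonferroni and Storey q-value control, plus a permutation test on the
    count of nominally significant probes) and with a dissimilarity-based
    multivariate statistic (mvt) assessed against a permutation null,
    complemented by classical multidimensional scaling, standardized
    principal components and Ward hierarchical clustering. A synthetic-data
    generator with planted group effects, latent-factor coexpression and a
    partially shared "nonequivalent" effect profile makes the whole pipeline
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
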