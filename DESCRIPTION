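Package: lpecount
Title: Local-Pooled-Error Differential Expression Tests for RNA-Seq with
    Few or No Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential expression testing for RNA-seq count data when
    very few -- or no -- biological replicates are available. Implements a
    local-pooled-error (LPE) approach on log2-transformed relative
    abundances: per-gene error variance is borrowed from intensity
    neighbours by binning genes on mean log2 intensity, pooling the
    variance of between-replicate differences within each bin, and
    smoothing the bin variances with a cubic smoothing spline. For designs
    with a single sample per class, the two cross-class samples are
    treated as pseudo-replicates and apparent outliers (candidate
    differential transcripts) are removed before the variance curve is
    fitted. Includes a per-transcript negative binomial (mean/dispersion)
    maximum-likelihood estimator, a zero-inflated-Poisson plus negative
    binomial two-class count simulator, and a Monte-Carlo benchmark
    harness reporting false discovery and true positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
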