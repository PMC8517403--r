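Package: ebscan
Title: Two-Stage Multi-Locus Association Mapping with Score-Test
    Screening and Empirical Bayes Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast two-stage multi-locus genome-wide association mapping
    for quantitative traits. Stage one scans every marker with a linear
    mixed model score test under kinship-based polygenic control, solving
    the null covariance systems by preconditioned conjugate gradients,
    and screens candidates with a lenient p-value cutoff. Stage two fits
    all screened markers jointly by empirical-Bayes expectation
    maximisation with a scaled inverse chi-square (Jeffreys) prior on
    per-marker effect variances, and calls quantitative trait nucleotides
    by a likelihood-ratio/LOD criterion. Includes genotype input in PLINK
    binary or plain tab-separated form, a synthetic genotype/phenotype
    simulator with heritability bookkeeping, and power/FDR/MSE
    benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
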