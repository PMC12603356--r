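Package: scprecision
Title: Precision, Accuracy, and Reproducibility Assessment for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative quality assessment of single-cell and single-nucleus
    RNA-seq gene expression. Builds pseudo-bulk profiles and randomized
    pseudo-bulk technical replicates, measures per-gene expression precision
    as the coefficient of variation across replicates (with cell-number
    downsampling curves and covariate regressions), evaluates expression
    accuracy against matched bulk references via per-gene Pearson correlation
    and a through-origin regression slope test, performs negative-binomial
    likelihood-ratio differential expression on pseudo-bulks, scores gene
    reproducibility by true-positive rate and signal-to-noise ratio, and
    estimates the expected true-positive rate of a planned design by
    Monte-Carlo simulation. Includes a gamma-Poisson two-condition simulator
    with known differential-expression ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
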