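Package: nbseqpower
Title: Power and Sample Size for RNA-Seq Differential Expression via the
    Negative Binomial Exact Test
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact power and minimal per-group sample size for two-group
    RNA-seq differential expression based on the negative binomial exact
    test. Supports single-gene designs at a fixed significance level and
    multi-gene designs that control the false discovery rate through a
    target number of true rejections, with a conservative least-favourable
    parameter reduction. Design parameters (per-gene mean, fold change,
    dispersion, normalization-factor ratio) can be estimated from pilot
    count data, and a Monte Carlo validation harness simulates full count
    matrices, tests every gene and reports achieved true rejections under
    Storey q-value FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
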