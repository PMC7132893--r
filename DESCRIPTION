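Package: georif
Title: Regulatory Impact Factor Scoring with Geometric Co-Expression Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate key regulators (transcription factors,
    epigenetic factors, long non-coding RNAs) of a two-condition gene
    expression contrast from RNA-seq counts. Counts are normalized by
    trimmed-mean-of-M-values factors, differentially expressed genes are
    called with a simplified negative-binomial exact test under
    Benjamini-Hochberg false-discovery-rate control, and regulators are
    scored by the Regulatory Impact Factor statistics RIF1 and RIF2 under
    four interchangeable co-expression measures: Pearson, Spearman, the
    Fisher information metric on the probability simplex, and a Sobolev
    metric. Top-ranked regulators are assembled into an interaction
    network filtered by the Partial Correlation and Information Theory
    (PCIT) algorithm. A synthetic negative-binomial data generator with
    planted differential wiring supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
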