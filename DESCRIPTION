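Package: midparent
Title: Mid-Parent-Value Inheritance Classification for Hybrid RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of hybrid-vigor (heterosis) transcriptomes from
    gene-level count matrices: median-of-ratios library-size
    normalization with FPKM/TPM conversion, per-gene negative-binomial
    likelihood-ratio differential expression with Benjamini-Hochberg
    FDR, classification of differentially expressed genes into twelve
    additive/non-additive inheritance patterns relative to the
    mid-parent expression value (expression-level dominance and
    transgressive expression), hypergeometric gene-set
    over-representation against GMT collections, and companion
    growth/assay statistics (specific growth rate, survival, enzyme
    specific activity, histomorphometry indices, 2^-ddCt, one-way
    ANOVA with Tukey HSD and compact letter display). Seeded
    negative-binomial simulators with planted inheritance modes make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
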