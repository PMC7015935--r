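Package: icbscore
Title: Stroma and Proliferation Gene-Signature Scoring for Immune
    Checkpoint Blockade Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives cancer-associated-fibroblast (stroma) and cell-cycle
    (proliferation) gene signatures from two-group bulk RNA-seq differential
    expression, scores samples by geometric means of cohort-mean-normalized
    expression, and classifies anti-PD-1 response with a combination score.
    Includes supporting computations for expression matrices (FPKM, low-count
    filtering, median-of-ratios size factors, a negative-binomial Wald test,
    Benjamini-Hochberg correction), classifier and group-difference evaluation
    (confusion metrics, rank tests, Kaplan-Meier and log-rank utilities),
    missense neo-antigen candidate enumeration, and a synthetic cohort
    generator with planted signature effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
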