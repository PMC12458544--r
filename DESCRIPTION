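Package: tcrbench
Title: Benchmarking Peptide-TCR Binder Predictors by Classification and
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation harness for predictors of peptide to T-cell
    receptor (TCR) binding. Stratifies peptides into majority, few-shot
    and zero-shot tasks by binder count, constructs negative pairs under
    background-drawing and reshuffling strategies, assembles balanced
    multi-fold classification evaluations, and runs repertoire-scale
    virtual screening with early-enrichment metrics (BEDROC, enrichment
    curves, hit rates, success rates). Predictors plug in through a
    scorer contract or pre-computed score tables; a synthetic data and
    scorer generator makes the whole pipeline testable without trained
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
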