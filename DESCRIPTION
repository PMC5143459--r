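Package: trnacca
Title: Sprinzl 3'-End Annotation and CCA-Templating Analysis of Prokaryotic tRNA Genes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to re-annotate the 3' ends of prokaryotic tRNA gene
    records. A semi-global dynamic programming aligner pairs the reversed
    5' acceptor-stem heptamer against the annotated 3' end plus trailer to
    assign Sprinzl coordinates 66-76, from which genes are called as
    templating the 3' CCA end or not. CAU-anticodon genes (initiator
    tRNA-fMet, elongator tRNA-Met and lysidinylated tRNA-Ile) are
    classified with position-specific log-odds profile models. Structural
    features (1:72 acceptor pair, 11:24 D-stem pair, anticodon-stem
    triplets) are tabulated into contingency tables, CCA-templating
    frequencies are aggregated per functional class and taxonomic clade,
    and clade-level phyletic patterns are called. A synthetic-data
    generator with full ground-truth bookkeeping supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
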