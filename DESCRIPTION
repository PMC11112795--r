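Package: methylscreen
Title: Whole-Genome Bisulfite Methylome Summaries, DMR Calling, and
    Methylation-Expression Integration for Small Tumor/Normal Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for small-replicate (e.g. 3 tumor vs 3 normal)
    whole-genome bisulfite sequencing studies: parsing per-cytosine
    methylation call tables, read-level quality flagging, per-context
    methylome summaries, differentially methylated region (DMR) calling
    under a CpG-count/fold-change/significance criterion with an
    adjacent-region merge rule, a threshold-based differential expression
    screen, the hyper-DMR x down-DEG crossover that nominates
    methylation-silenced candidate tumor suppressors, a Spearman
    co-expression screen, 2x2 clinical association tests, and
    quantification of per-CpG-unit demethylation response after 5-Aza
    treatment. Includes a seeded synthetic-data generator (beta-binomial
    cytosine counts with planted DMRs, coupled negative-binomial
    expression with planted DEGs) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
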