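Package: qgrscan
Title: G-Quadruplex Screening and Partner Nomination for Dysregulated lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico pipeline for discovering putative G-quadruplex-forming
    sequences (PQS) in long non-coding RNA transcripts and nominating their
    protein partners. Implements a QGRS-style G-scoring scanner with
    non-overlapping hit selection, gene-level transcript clustering with PQS
    summaries, dual-evidence lncRNA-protein partner integration with
    subcellular colocalization convergence, a cytoplasmic/nuclear relative
    concentration index, and desk-scale analytics for the biophysical assays
    (circular dichroism topology classification, thioflavin T fold
    enhancement, reverse-transcriptase stop quantification) used to validate
    predicted quadruplexes. Seeded synthetic-fixture generators provide every
    input format the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
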