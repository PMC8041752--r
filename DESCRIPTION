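Package: cyclereg
Title: Droplet scRNA-seq QC, Cell-Cycle Phase Scoring and Regulon Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control calculators for droplet single-cell RNA-seq
    (double-Poisson loading expectations, barnyard species assignment and
    doublet/contamination summaries, barcode-rank knee estimation of captured
    cells, UMI-vs-reads capture-efficiency slopes, cell/UMI barcode
    correction), five-phase cell-cycle scoring and ordering of single cells,
    transcription-factor regulon activity inference with phase correlation,
    multi-network single-cell enrichment with average-score integration, and
    CRISPR depletion-screen scoring with common-essential classification.
    Seeded synthetic-data generators with known ground truth accompany every
    analysis for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
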