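Package: annocurate
Title: Evidence-Based Gene Annotation Curation and Cross-Species Expression Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for improving and evaluating genome annotations
    with transcriptional evidence. Gene models are classified into four
    confidence levels from the evidence classes that support them (cDNA, EST,
    multi-tissue RNA-seq assemblies, protein alignments, reference
    annotations), then curated by a deterministic rule engine that adjusts
    terminal exons, adds or deletes exons, replaces structures and merges
    isoforms according to documented guidelines. Annotation quality is scored
    by base-level sensitivity, specificity and congruency against evidence at
    gene and exon level, with cumulative-congruence curves for comparing
    annotation versions. Additional modules select a transcript-assembly
    stringency parameter from exon detection sensitivity/precision sweeps, and
    compare multi-tissue expression across two species (RPKM, quantile
    normalization, transcriptome-complexity curves, correlation clustering and
    Wilcoxon/fold-change differential genes). Seeded generators provide
    synthetic annotations, evidence tracks and expression matrices for testing
    every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    withr,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
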