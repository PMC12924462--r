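Package: epieditr
Title: Profiling On- and Off-Target Effects of dCas9 DNA Methylation Editors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for CRISPR/dCas9 epigenome-editing experiments
    that deposit DNA methylation. Calls differentially methylated regions
    (DMRs) from CpG beta-value matrices with an effect-size run rule
    (consecutive same-direction CpGs with |delta-beta| > 0.1 within 2 kb),
    quantifies on-target and predicted off-target editing from targeted
    methyl-seq panels with coverage masking, measures temporal persistence
    and pairwise sharedness of DMR sets, screens differential expression on
    TMM-normalized counts-per-million, and integrates methylome and
    transcriptome via CpG-gene correlation, DMR-DEG intersection,
    chromatin-state enrichment, overrepresentation analysis and sequence
    preference profiling. Includes a synthetic methylome + transcriptome
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
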