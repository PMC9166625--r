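Package: crisprAudit
Title: Multi-Assay Audit of CRISPR Gene-Correction Outcomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies sequencing reads from CRISPR gene-correction
    experiments into editing outcomes across three complementary assays:
    amplicon sequencing (WT/NHEJ/HDR quantification, indel rates, in-silico
    RFLP), tag-junction libraries (GUIDE-seq dsODN and AAV-seq ITR
    integration-site calling with off-target annotation under a 5000-bp
    window rule), and LAM-HTGTS (classification of primer-anchored reads
    against in-silico expected-outcome amplicons, including deletions,
    inversions, AAV integrations and translocations). Includes design
    validation for paired-nickase ("spacer-nick") guide arrangements
    (PAM-out pairs at 200-350 bp, homology arms of at least 800 bp) and a
    synthetic read simulator with per-read ground truth that emulates the
    four library structures on a mini-genome with planted off-target sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
biocViews: CRISPR, SequenceMatching, Alignment, Sequencing, GeneTarget
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
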