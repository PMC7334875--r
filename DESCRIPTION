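Package: cropmap
Title: Expression CROP-seq Screen Design, Simulation and eSNP Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for expression CROP-seq, a pooled single-cell
    CRISPR screening strategy for fine-mapping regulatory variants within eQTL
    credible intervals.  Provides SNP-targeted sgRNA design (NGG PAM scanning,
    GC-content and uniqueness filters, cut-site distance selection),
    construction of the guide-detection extended reference (one artificial
    chromosome per gRNA, FASTA + GTF), a synthetic screen generator with
    ground-truth editing outcomes and injected cis-regulatory effects,
    guide-to-cell assignment from UMI counts with MOI estimation, cell and
    gene quality control with library-size log2 normalization, per-eSNP
    univariate regression testing with locus-wise Bonferroni control and
    replicate concordance, and screen-level statistics: guide representation
    and dropout testing, eQTL effect-size/variance-explained conversion,
    two-group power, 2^-ddCt arithmetic, and chromatin-accessibility peak
    overlap annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
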