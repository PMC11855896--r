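Package: cypstab
Title: Genomic and Physicochemical Discrimination of Stable and Labile
    Insect Cytochrome P450s
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative profiling of insect cytochrome P450 (CYP) genes
    split into evolutionarily "stable" (at most three paralogs in their
    ortholog group) and "labile" (four or more paralogs) classes. Computes
    gene-structure features from GFF3 gene models (gene/exon/intron lengths,
    exon and transcript counts, GC content), Pepstats-style protein
    physicochemistry (molecular weight, charge, isoelectric point, residue
    and category composition, Kyte-Doolittle hydrophobicity), pairwise
    identity based redundancy culling, P450 signature-motif scanning with
    position-frequency-matrix conservation profiling, nonparametric
    two-group comparison with family-wise Bonferroni control, chi-squared
    frequency tests, and annotation-term over-representation summaries.
    Includes a seeded synthetic cohort generator that emits FASTA/GFF3/TSV
    bundles with configurable class contrasts so the full pipeline is
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
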