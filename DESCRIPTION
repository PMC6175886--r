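Package: polyswitch
Title: Suppressor-Screen Mapping and Dosage Genetics of a Nematode
    Polyphenism Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify and characterise a dosage-dependent
    polyphenism switch gene in Pristionchus nematodes. Implements the
    two-allele suppressor-screen mapping cascade (variant loading,
    quality filtering, shared-background subtraction, coding-impact
    classification, and cross-allele candidate intersection), a Mendelian
    cross engine for X-linked and autosomal loci under XX/XO sex
    determination including an interspecies gene duplication,
    complementation-group partitioning, morph-ratio statistics
    (exact binomial confidence intervals, pairwise chi-square and Z
    tests, Benjamini-Hochberg adjustment, binomial logit GLMs),
    delta-delta-Ct relative expression quantification with
    reference-gene normalisation and titration-based efficiency, and
    pairwise dN/dS by the Nei-Gojobori (1986) counting method with
    Jukes-Cantor correction. A synthetic-data module generates every
    input the pipeline consumes (genome, annotation, per-strain variant
    tables with planted causal lesions, dosage-driven morph counts, Ct
    tables, and evolved codon pairs) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
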