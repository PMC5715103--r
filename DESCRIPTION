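Package: strseek
Title: Discovery and Association Analysis of Expressed Polymorphic Short
    Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering expressed polymorphic
    microsatellites (short tandem repeats, STRs) and testing their
    association with disease. Parses RepeatMasker annotation output into an
    STR catalogue with divergence-based filters, cross-references the
    catalogue against external polymorphic-STR call sets by coordinate
    overlap and motif equivalence (reverse / reverse-complement), converts
    RNA-seq STR caller output (lobSTR-style ALLREADS fields) into filtered,
    normalized per-locus expression, classifies loci against gene models,
    ranks tumor versus adjacent-normal candidates with a fold-change-times-
    prevalence metric, and runs the genetic-epidemiology stage: allele and
    genotype tabulation, crude and logistic odds ratios, Hardy-Weinberg
    tests, stratified bootstrap, Gleason-score dichotomization,
    Kaplan-Meier/log-rank survival and genotype-expression comparisons.
    Includes seeded generators for every input format so all stages run at
    desk scale with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
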