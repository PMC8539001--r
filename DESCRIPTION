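Package: heatcross
Title: Multi-Trait Selection of Heat-Tolerant Tomato Hybrids with In-Silico Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for hybrid-breeding programmes that select
    heat-tolerant tomato F1 hybrids by combining phenotypic scores with
    marker-assisted screening of disease-resistance genes. Implements the
    arbitrary-scale selection index for reproductive and yield traits,
    mid-parent heterosis, a three-score hybrid index (heat tolerance, fruit
    quality, resistance-gene fraction) with mean-threshold elite
    classification, titratable-acidity computation, identity-by-state
    allele-sharing matrices, genotype-matrix filtering with missingness and
    depth thresholds, resistance-gene variant scans and impact tallies, and
    an in-silico CAPS/dCAPS/SCAR marker-design engine with virtual (nested)
    PCR and IUPAC restriction-digest simulation. Seeded generators produce
    trait tables with planted heterosis, genotype matrices with controlled
    pairwise similarity, and allele template sequences with planted
    diagnostic SNPs and restriction sites, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
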