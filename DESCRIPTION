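Package: mutmapr
Title: Bulked-Segregant MutMap Analysis of an EMS-Induced Recessive Mutant
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a MutMap-style bulked-segregant analysis for mapping
    a recessive EMS-induced mutation from two-pool sequencing data:
    per-pool SNP indices and the delta SNP index, a windowed genome scan
    with Monte-Carlo confidence thresholds, Mendelian segregation testing,
    candidate-SNP filtering, and strand-aware variant-effect annotation.
    Ships a synthetic F2 pooled-sequencing data generator (reference FASTA,
    GFF3 gene models, two-sample allele-depth VCF, truth table) so every
    stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    rtracklayer,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
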