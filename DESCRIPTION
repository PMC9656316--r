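Package: scubr
Title: Genome-Wide Synonymous Codon Usage Bias with Exon and Intron Stratification
Version: 0.1.0
Authors@R:
    person("scubr", "developers", email = "scubr@example.org", role = c("aut", "cre"))
Description: Extracts and filters coding sequences from genome FASTA plus GFF3
    annotation, assigns codons to coding exons with phase-aware splitting
    rules, and computes synonymous codon usage bias (SCUB) statistics: per-
    codon frequencies, per-amino-acid C/G- versus A/T-ending ratios, RSCU,
    CAI, CBI and Wright's effective number of codons. Statistics can be
    stratified by chromosome, by intron number and by exon position, and the
    package computes CpG-deamination sequence-context ratios (NXA/NXG and
    NT|X/NC|X) that proxy 5mC-to-T conversion. Downstream comparisons include
    chi-square cross-table tests, Welch t-tests, coefficients of variation,
    average-linkage correlation-distance clustering and PCA. A seed-
    deterministic synthetic genome generator with known codon-usage structure
    supports offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
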