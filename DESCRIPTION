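Package: tdsdquant
Title: Tile-Based Small RNA Quantification and Target-Directed Small RNA
    Degradation Kinetics for Programmed DNA Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for studying scan RNA (scnRNA) dynamics
    during programmed DNA elimination in ciliates. Provides a synthetic-data
    generator with known ground truth (germline/somatic genome pairs with
    internal eliminated sequences, 26-32 nt small RNA pools with
    genotype-specific target-directed degradation, per-cell FISH intensity
    tables, and label-free proteomics tables); k-mer mappability masks and
    MDS/IES genomic tiling; unique-match read counting with RPKM
    normalization and Wilcoxon rank-sum tile comparisons; first-order decay
    fitting of scnRNA time courses; the calibrated IES retention index with
    Welch tests; and a SUMO-proteomics candidate filter. A single
    orchestrator runs the whole pipeline reproducibly from one seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
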