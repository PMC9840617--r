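Package: cptrna
Title: Chloroplast tRNA Census, Anomaly Detection and Sequence Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale analysis of transfer RNA genes in plastid
    genomes. Parses tRNAscan-SE, GFF3 and GenBank annotations into a common
    record model and merges multi-annotator calls; builds pooled anticodon
    census tables with rarity, absence and special-isotype (fMet, Ile2, Sec,
    Pyl, suppressor) classification; detects duplet and quadruplet anticodon
    anomalies and attributes quadruplets to parent triplets; locates putative
    spacer tRNAs between the 16S and 23S rRNA genes; classifies tRNA-derived
    fragments (tRFs and tiRNAs) against mature references and extracts
    conserved motifs; builds per-isotype group I intron wildcard consensuses
    and clusters them; and provides count-based transition/transversion
    statistics, Kimura two-parameter distances and neighbor-joining trees
    with bootstrap support. A seeded synthetic plastome generator with full
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stats,
    utils,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
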