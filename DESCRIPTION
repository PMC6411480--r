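Package: pdzsurvey
Title: Comparative Survey of PDZ Domain-Containing Proteins in Microbial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a comparative-genomics survey of PDZ domain-containing
    proteins across prokaryotic and fungal proteomes. Ingests HMMER3 per-domain
    hit tables and Superfamily-style assignment tables, applies e-value
    inclusion thresholds, resolves overlapping hits into ordered domain
    architectures with tandem-PDZ counts, classifies proteins into twelve
    architecture-defined families (protease and non-protease) with motif
    corroboration, extracts codirectional gene neighborhoods from NCBI PTT
    annotation tables, summarizes per-genome counts and subcellular
    localization, and compares phyletic counts between phenotype groups with
    one-sided Wilcoxon rank-sum tests. A seeded synthetic-cohort generator
    plants known family architectures, gene clusters, and group effects so the
    whole pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
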