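Package: rmcensus
Title: Census, Classification and Persistence of Restriction-Modification
    Systems in Archaeal Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying restriction-modification (RM) systems across
    completely sequenced prokaryotic genomes: completeness filtering of strain
    manifests, greedy centroid clustering of RM-gene protein sequences at a
    fractional-identity threshold, profile-based functional classification of
    gene clusters into the 13 standard RM functional categories with
    methylation-type assignment (m6A, m4C, m5C), per-taxon census tables of
    genes and observed methylome motifs with gene/motif reconciliation,
    detection of "persistent" methyltransferase families conserved within
    taxa (the >=75% incidence in >=5 genomes rule) with neighbor-joining
    refinement of homologous groups, and m5C motif discovery from
    RIMS-seq-style paired-read C>T deamination counts. Includes a synthetic
    community generator (taxonomies, gene families, methylomes, deamination
    tables) with known ground truth so every stage is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
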