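#!/usr/bin/env Rscript

# Two censuses. First, per-taxon means for the synthetic community: genes
# per genome in each of the 13 functional categories, then MTase genes and
# observed motifs split by methylated base, with gene/motif reconciliation
# flags (motifs exceeding genes point at misclassified activities or
# missing replicons). Second, the same aggregation arithmetic applied to
# the shipped survey tables for the 519 complete archaeal genomes,
# reproducing the published totals and the canonical m6A:m4C:m5C gene
# ratio of roughly 4:2:1.

suppressPackageStartupMessages(library(rmcensus))
calls <- utils::read.delim("results/functional_calls.tsv")
manifest <- utils::read.delim("results/manifest_kept.tsv")
methylome <- utils::read.delim("results/world/methylome.tsv")
methylome <- methylome[methylome$strain_id %in% manifest$strain_id, ]

for (rank in c("phylum", "class")) {
  cen <- census_by_taxon(calls, manifest, rank)
  write_tsv(cen, sprintf("results/census_%s.tsv", rank))
}
cls <- utils::read.delim("results/census_class.tsv")
message("class-level census (mean genes per genome):")
print(cls[, c("taxon", "n_genomes", "IM", "IIM", "IIG", "IIIM", "IV")],
      digits = 3)

mc <- meth_census(calls, methylome, manifest, "class")
write_tsv(mc$genes, "results/meth_census_genes.tsv")
write_tsv(mc$motifs, "results/meth_census_motifs.tsv")
write_tsv(mc$flags, "results/meth_census_flags.tsv")
message(nrow(mc$flags), " taxon/type cells where motifs exceed genes")

total <- mc$genes[mc$genes$taxon == "TOTAL", ]
ratio <- meth_ratio(total)
message(sprintf("synthetic-world MTase gene ratio m6A:m4C:m5C = %s",
                format_ratio(ratio)))

# published survey: weighted aggregation of the printed phylum rows
t2 <- read_survey_table("meth_census")
phyla <- t2[t2$rank == "phylum", ]
tot <- census_total(data.frame(n_genomes = phyla$n_genomes,
                               m6A = phyla$genes_m6A, m4C = phyla$genes_m4C,
                               m5C = phyla$genes_m5C))
message(sprintf(
  "published archaeal totals: m6A %.3f, m4C %.3f, m5C %.3f per genome -> %s",
  tot$m6A, tot$m4C, tot$m5C, format_ratio(meth_ratio(tot))))
write_tsv(cbind(taxon = "TOTAL", tot), "results/survey_totals.tsv")
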