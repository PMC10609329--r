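#!/usr/bin/env Rscript

# Deamination-based m5C motif discovery, emulating the heterologous-host
# validation of an m5C MTase: a clone methylates CCWGG sites on a 200 kb
# host chromosome, partial enzymatic deamination elevates read1 C>T at
# methylated cytosines, and the caller works back from per-position counts
# to sites and from sites to the recognition motif.

suppressPackageStartupMessages(library(rmcensus))
dir.create("results", showWarnings = FALSE)
seed <- 20260907L

sim <- emit_rims_counts(genome_length = 200000, motif = "CCWGG",
                        methylated_offset = 1, methylation_fraction = 1,
                        background_rate = 0.005, m5c_rate = 0.1,
                        coverage = 100, seed = seed)
writeLines(c(">host_chromosome", sim$genome), "results/rims_genome.fa")
write_tsv(sim$table[, c("pos", "strand", "r1_c", "r1_t", "r2_c", "r2_t")],
          "results/rims_counts.tsv")

sites <- call_m5c_sites(sim$table, min_coverage = 10, fdr = 0.05)
truth <- paste(sim$table$pos, sim$table$strand)[sim$table$methylated]
message(sprintf(
  "%d m5C sites called; sensitivity %.3f; %d false positives",
  nrow(sites), mean(truth %in% paste(sites$pos, sites$strand)),
  sum(!paste(sites$pos, sites$strand) %in% truth)))
# BED: 0-based half-open, name=q-value
bed <- data.frame(chrom = "host_chromosome", start = sites$pos - 1L,
                  end = sites$pos, name = signif(sites$q, 3), score = 0L,
                  strand = sites$strand)
utils::write.table(bed, "results/rims_sites.bed", sep = "\t", quote = FALSE,
                   row.names = FALSE, col.names = FALSE)

motifs <- find_motifs(sites, sim$genome, k_range = 3:8, fdr = 0.05)
message("motif report (top-ranked first):")
print(motifs, digits = 3)
write_tsv(motifs, "results/rims_motifs.tsv")
message(sprintf("top motif: %s with methylated C at offset %d",
                motifs$motif[1], motifs$offset[1]))
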