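#!/usr/bin/env Rscript

# Apply the completeness filter to the simulated strain manifest after
# perturbing a tail of records the way public repositories look in
# practice: some whole-genome shotgun assemblies, some short draft
# sequences, some unfinished projects. Records flagged complete_genome are
# always retained; the rest must survive the wgs / length / status rules.

suppressPackageStartupMessages(library(rmcensus))
manifest <- utils::read.delim("results/world/manifest.tsv")

set.seed(20260902)
n <- nrow(manifest)
perturb <- sample(n, ceiling(0.15 * n))
third <- split(perturb, rep(1:3, length.out = length(perturb)))
manifest$definition_flag[third[[1]]] <- "wgs"
manifest$definition_flag[third[[2]]] <- "other"
manifest$longest_bp[third[[2]]] <- sample(2e5:4.9e5, length(third[[2]]))
manifest$definition_flag[third[[3]]] <- "other"
manifest$project_status[third[[3]]] <- "incomplete"

sel <- filter_complete(manifest)
message(nrow(sel$kept), " of ", n, " genomes kept; dropped by reason:")
print(table(sel$dropped$reason))

dir.create("results", showWarnings = FALSE)
write_tsv(sel$kept, "results/manifest_kept.tsv")
write_tsv(sel$dropped, "results/manifest_rejects.tsv")
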