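#!/usr/bin/env Rscript

# Functional classification of the gene clusters: build a profile model
# from each family's training alignment, calibrate the bit-score call
# threshold on a random-sequence null (99.9th percentile of best-hit
# scores), score each cluster centroid against the whole library and
# propagate the top hit's functional category and methylation type to the
# cluster members.

suppressPackageStartupMessages(library(rmcensus))
lib_manifest <- utils::read.delim("results/world/library_manifest.tsv")
lib <- lapply(seq_len(nrow(lib_manifest)), function(i) {
  msa <- Biostrings::readAAStringSet(lib_manifest$msa_path[i])
  build_profile(msa, lib_manifest$name[i], lib_manifest$category[i],
                lib_manifest$meth_type[i])
})
names(lib) <- lib_manifest$name
message("profile library: ", length(lib), " models")

threshold <- calibrate_threshold(lib, n = 1000, seed = 20260904)
message(sprintf("bit-score threshold (99.9th null percentile): %.2f",
                threshold))

seqs <- Biostrings::readAAStringSet("results/world/genes.faa")
clusters <- utils::read.delim("results/clusters.tsv")
seqs <- seqs[clusters$gene_id]
calls <- classify_genes(seqs, lib, threshold = threshold, clusters = clusters)

genes <- utils::read.delim("results/world/gene_table.tsv")
truth_cat <- genes$category[match(calls$gene_id, genes$gene_id)]
acc <- mean(calls$category == truth_cat)
message(sprintf("category accuracy vs ground truth: %.3f (%d genes)",
                acc, nrow(calls)))
truth_type <- genes$meth_type[match(calls$gene_id, genes$gene_id)]
message(sprintf("methylation-type accuracy: %.3f",
                mean(calls$meth_type == truth_type)))

calls$strain_id <- genes$strain_id[match(calls$gene_id, genes$gene_id)]
write_tsv(calls, "results/functional_calls.tsv")
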