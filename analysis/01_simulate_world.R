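#!/usr/bin/env Rscript

# Build the synthetic archaeal community that the rest of the workflow
# analyses: an unevenly sampled ranked taxonomy (a few heavily sequenced
# classes next to many small ones, mirroring how complete genomes cluster
# in public databases), RM gene families planted with known ground truth —
# persistent MTase families conserved within home taxa, sporadic families
# scattered by horizontal transfer — protein sequences for every gene, and
# an observed methylome with realistic gene silencing and poor m5C
# detection.

suppressPackageStartupMessages(library(rmcensus))
dir.create("results/world/train", recursive = TRUE, showWarnings = FALSE)
seed <- 20260901L

ts <- taxonomy_spec(
  ranks = c("phylum", "class", "order"),
  sizes = list(phylum = 2L, class = c(3L, 3L), order = 2L),
  # six classes of very different sampling depth (strains per order)
  strains_per_leaf = c(20L, 20L, 13L, 12L, 10L, 10L, 8L, 7L, 6L, 6L, 4L, 4L),
  seed = seed, methylome_fraction = 0.10)
manifest <- generate_taxonomy(ts)
message(nrow(manifest), " strains in ", length(unique(manifest$class)),
        " classes; ", sum(manifest$has_methylome), " with methylome data")

classes <- unique(manifest$class)
specs <- list(
  # persistent MTases, one per home class, echoing the archetypes seen in
  # archaea: a near-universal m5C CCWGG family, Dam-like GATC, AGCT/CTAG
  # m4C orphans, a nonpalindromic CATTC family and one Type I system
  family_spec("hgA", "persistent", home_taxon = classes[1],
              presence_rate = 0.95, category = "IIM", meth_type = "m5C",
              motif = "CCWGG", divergence = 0.15),
  family_spec("hgB", "persistent", home_taxon = classes[2],
              presence_rate = 0.9, category = "IIM", meth_type = "m6A",
              motif = "GATC", divergence = 0.15),
  family_spec("hgC", "persistent", home_taxon = classes[3],
              presence_rate = 0.9, category = "IIM", meth_type = "m4C",
              motif = "AGCT", divergence = 0.15),
  family_spec("hgD", "persistent", home_taxon = classes[4],
              presence_rate = 0.85, category = "IIM", meth_type = "m4C",
              motif = "CTAG", divergence = 0.15),
  family_spec("hgE", "persistent", home_taxon = classes[2],
              presence_rate = 0.8, category = "IIM", meth_type = "m6A",
              motif = "CATTC", divergence = 0.15),
  family_spec("hgF", "persistent", home_taxon = classes[5],
              presence_rate = 0.9, category = "IM", meth_type = "m6A",
              motif = "GCANNNNNNTGC", divergence = 0.15)
)
sporadic_cats <- rep(c("IIM", "IIR", "IIG", "IM", "IIIM", "IV", "V", "M"),
                     length.out = 18L)
sporadic_types <- ifelse(sporadic_cats %in% c("IIM", "IIG", "IIIM", "IM", "M"),
                         rep(c("m6A", "m4C", "m5C"), length.out = 18L), "none")
for (i in seq_along(sporadic_cats)) {
  specs[[length(specs) + 1L]] <- family_spec(
    sprintf("spo%02d", i), "sporadic", presence_rate = 0.12,
    category = sporadic_cats[i],
    meth_type = sporadic_types[i],
    motif = if (sporadic_types[i] == "none") NA_character_ else "GANTC",
    divergence = 0.2)
}

world <- plant_families(manifest, specs, seed = seed + 1L)
message(nrow(world$gene_table), " genes planted across ",
        length(unique(world$gene_table$family_id)), " families")

seqs <- emit_world_sequences(world$gene_table, specs, seed = seed + 2L)
methylome <- emit_methylome(world$gene_table, world$truth,
                            silencing_rate = 0.1, m5c_detection_rate = 0.3,
                            seed = seed + 3L)
methylome <- methylome[methylome$strain_id %in%
                         manifest$strain_id[manifest$has_methylome], ]
message(nrow(methylome), " observed motifs on methylome strains")

# training alignments for the classifier: a held-out draw from each family
# ancestor (same family seeds as emit_world_sequences, so the ancestors
# match), 8 sequences each
lib_manifest <- list()
for (sp in specs) {
  fam_seed <- rmcensus:::.family_seed(seed + 2L, sp$family_id)
  n_world <- sum(world$gene_table$family_id == sp$family_id)
  draw <- emit_family_sequences(sp, n_world + 8L, seed = fam_seed)
  train <- draw$aligned[seq(n_world + 1L, n_world + 8L)]
  path <- file.path("results/world/train", paste0(sp$family_id, ".afa"))
  Biostrings::writeXStringSet(train, path)
  lib_manifest[[sp$family_id]] <- data.frame(
    name = sp$family_id, category = sp$category, meth_type = sp$meth_type,
    msa_path = path)
}

write_tsv(manifest, "results/world/manifest.tsv")
write_tsv(world$gene_table, "results/world/gene_table.tsv")
write_tsv(methylome, "results/world/methylome.tsv")
write_tsv(do.call(rbind, lib_manifest), "results/world/library_manifest.tsv")
Biostrings::writeXStringSet(seqs, "results/world/genes.faa")
truth_motifs <- do.call(rbind, lapply(names(world$truth), function(f)
  data.frame(family_id = f, category = world$truth[[f]]$category,
             meth_type = world$truth[[f]]$meth_type,
             motif = world$truth[[f]]$motif,
             n_strains = length(world$truth[[f]]$strains))))
write_tsv(truth_motifs, "results/world/family_truth.tsv")
message("world written under results/world/")
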