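test_that("taxonomy generation expands clade sizes and is deterministic", {
  ts <- taxonomy_spec(ranks = c("phylum", "class"),
                      sizes = list(phylum = 1L, class = 1L),
                      strains_per_leaf = 5L, seed = 7)
  m <- generate_taxonomy(ts)
  expect_equal(nrow(m), 5L)
  expect_equal(length(unique(m$class)), 1L)
  expect_identical(m, generate_taxonomy(ts))
  expect_true(all(m$project_status == "complete"))
  expect_true(all(m$definition_flag == "complete_genome"))
  # rank paths are complete: one taxon per rank per strain
  expect_false(any(is.na(m$phylum) | is.na(m$class)))
})

test_that("an uneven manifest mirroring six dominant classes totals 519", {
  # six heavily sequenced classes (100, 61, 181, 65, 44, 29 strains) plus
  # 39 strains spread over 13 small classes
  ts <- taxonomy_spec(ranks = c("phylum", "class"),
                      sizes = list(phylum = 1L, class = 19L),
                      strains_per_leaf = c(100L, 61L, 181L, 65L, 44L, 29L,
                                           rep(3L, 13L)),
                      seed = 1)
  m <- generate_taxonomy(ts)
  expect_equal(nrow(m), 519L)
  sizes <- sort(as.integer(table(m$class)), decreasing = TRUE)
  expect_equal(sum(sizes[1:6]), 480L)
  expect_equal(round(100 * sum(sizes[1:6]) / nrow(m), 1), 92.5)
})

test_that("invalid taxonomy specs are rejected", {
  expect_error(taxonomy_spec(sizes = list(phylum = 0L, class = 2L, order = 2L)),
               "positive")
  expect_error(taxonomy_spec(ranks = "phylum", sizes = list(class = 2L)),
               "named list")
})

test_that("family planting respects mode, rate and home taxon", {
  w <- build_test_world(seed = 11)
  manifest <- w$manifest
  home <- unique(manifest$class)[1]
  certain <- plant_families(manifest, family_spec(
    "f1", "persistent", home_taxon = home, presence_rate = 1), seed = 1)
  home_strains <- manifest$strain_id[manifest$class == home]
  expect_setequal(certain$truth$f1$strains, home_strains)
  never <- plant_families(manifest, family_spec(
    "f2", "sporadic", presence_rate = 0), seed = 1)
  expect_length(never$truth$f2$strains, 0)
  expect_error(plant_families(manifest, family_spec(
    "f3", "persistent", home_taxon = "no-such-taxon")), "no-such-taxon")
  # conservation: every planted gene appears in exactly one strain
  expect_equal(anyDuplicated(w$gene_table$gene_id), 0L)
  expect_equal(nrow(w$gene_table),
               sum(lengths(lapply(w$truth, `[[`, "gene_ids"))))
})

test_that("planted presence fraction converges to the specified rate", {
  ts <- taxonomy_spec(ranks = c("phylum", "class"),
                      sizes = list(phylum = 1L, class = 1L),
                      strains_per_leaf = 100L, seed = 5)
  manifest <- generate_taxonomy(ts)
  spec <- family_spec("f", "persistent", home_taxon = manifest$class[1],
                      presence_rate = 0.9)
  fracs <- vapply(1:500, function(s)
    length(plant_families(manifest, spec, seed = s)$truth$f$strains) / 100,
    0)
  se <- sqrt(0.9 * 0.1 / 100) / sqrt(500)
  expect_lt(abs(mean(fracs) - 0.9), 3 * se)
})

test_that("family sequences follow the substitution model", {
  spec0 <- family_spec("f", "sporadic", divergence = 0, ancestor_length = 50L)
  out <- emit_family_sequences(spec0, 4, seed = 3)
  expect_true(all(as.character(out$seqs) == out$ancestor))
  one <- emit_family_sequences(spec0, 1, seed = 3)
  expect_length(one$seqs, 1)
  expect_identical(as.character(one$aligned), as.character(one$seqs))
  # expected pairwise identity at divergence d is (1-d)^2 + d^2/19 under
  # uniform replacement over the 19 alternative residues
  d <- 0.2
  spec <- family_spec("f", "sporadic", divergence = d, ancestor_length = 300L)
  ids <- vapply(1:200, function(s) {
    pair <- as.character(emit_family_sequences(spec, 2, seed = 1000 + s)$seqs)
    a <- strsplit(pair[1], "")[[1]]; b <- strsplit(pair[2], "")[[1]]
    mean(a == b)
  }, 0)
  expected <- (1 - d)^2 + d^2 / 19
  p <- expected
  se <- sqrt(p * (1 - p) / 300) / sqrt(200)
  expect_lt(abs(mean(ids) - expected), 3 * se)
})

test_that("methylome emission tracks active genes and detection rates", {
  w <- build_test_world(seed = 21)
  full <- emit_methylome(w$gene_table, w$truth, silencing_rate = 0,
                         m5c_detection_rate = 1, seed = 1)
  n_mtase <- sum(w$gene_table$meth_type %in% c("m6A", "m4C", "m5C"))
  expect_equal(nrow(full), n_mtase)
  per_strain_genes <- table(w$gene_table$strain_id[
    w$gene_table$meth_type %in% c("m6A", "m4C", "m5C")])
  per_strain_motifs <- table(full$strain_id)
  expect_equal(as.integer(per_strain_motifs[names(per_strain_genes)]),
               as.integer(per_strain_genes))
  no_m5c <- emit_methylome(w$gene_table, w$truth, silencing_rate = 0,
                           m5c_detection_rate = 0, seed = 1)
  expect_equal(sum(no_m5c$type == "m5C"), 0L)
  silenced <- emit_methylome(w$gene_table, w$truth, silencing_rate = 1,
                             seed = 1)
  expect_equal(nrow(silenced), 0L)
})

test_that("identical seeds reproduce identical synthetic outputs", {
  w1 <- build_test_world(seed = 33)
  w2 <- build_test_world(seed = 33)
  expect_identical(w1$gene_table, w2$gene_table)
  s1 <- emit_world_sequences(w1$gene_table, w1$specs, seed = 2)
  s2 <- emit_world_sequences(w2$gene_table, w2$specs, seed = 2)
  expect_identical(as.character(s1), as.character(s2))
  r1 <- emit_rims_counts(5000, "CCWGG", 1, seed = 4)
  r2 <- emit_rims_counts(5000, "CCWGG", 1, seed = 4)
  expect_identical(r1, r2)
})

test_that("deamination counts are elevated only at planted motif cytosines", {
  sim <- emit_rims_counts(genome_length = 30000, motif = "CCWGG",
                          methylated_offset = 1, methylation_fraction = 1,
                          background_rate = 0.005, m5c_rate = 0.2,
                          coverage = 200, seed = 9)
  tab <- sim$table
  # ground-truth methylated positions sit at the second C of a CCAGG or
  # CCTGG instance on their own strand
  meth_plus <- tab$pos[tab$methylated & tab$strand == "+"]
  ctx <- substring(sim$genome, meth_plus - 1, meth_plus + 3)
  expect_true(all(ctx %in% c("CCAGG", "CCTGG")))
  # and read1 rates reflect the planted difference
  r1 <- tab$r1_t / (tab$r1_t + tab$r1_c)
  expect_gt(mean(r1[tab$methylated]), 0.15)
  expect_lt(mean(r1[!tab$methylated]), 0.01)
  # read2 never sees methylation
  r2 <- tab$r2_t / (tab$r2_t + tab$r2_c)
  expect_lt(abs(mean(r2[tab$methylated]) - mean(r2[!tab$methylated])), 0.005)
})

test_that("degenerate deamination inputs behave as specified", {
  zero <- emit_rims_counts(genome_length = 2000, motif = "GATC",
                           methylated_offset = 3, coverage = 0, seed = 2)
  expect_true(all(zero$table[, c("r1_c", "r1_t", "r2_c", "r2_t")] == 0))
  expect_equal(nrow(suppressMessages(call_m5c_sites(zero$table))), 0L)
  expect_error(emit_rims_counts(2000, "GATC", methylated_offset = 0, seed = 1),
               "does not address a C")
})
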