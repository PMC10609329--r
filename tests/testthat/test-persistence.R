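test_that("presence matrix counts incidences at every rank", {
  w <- build_test_world(seed = 71)
  m <- w$manifest
  everywhere <- data.frame(gene_id = paste0("e", seq_len(nrow(m))),
                           strain_id = m$strain_id, family_id = "ubiq")
  pm <- presence_matrix(everywhere, m)
  expect_true(all(pm$ubiq == pm$size))
  expect_error(presence_matrix(
    data.frame(gene_id = "x", strain_id = "ghost", family_id = "f"), m),
    "ghost")
})

test_that("parent incidence counts dominate child counts", {
  for (seed in 1:10) {
    ts <- taxonomy_spec(ranks = c("phylum", "class", "order"),
                        sizes = list(phylum = 2L, class = 2L, order = 2L),
                        strains_per_leaf = 4L, seed = seed)
    m <- generate_taxonomy(ts)
    world <- plant_families(m, list(
      family_spec("a", "sporadic", presence_rate = 0.3),
      family_spec("b", "persistent", home_taxon = m$class[1],
                  presence_rate = 0.8)), seed = seed)
    if (!nrow(world$gene_table)) next
    pm <- presence_matrix(world$gene_table, m)
    fams <- attr(pm, "families")
    qid <- paste0(pm$rank, ":", pm$taxon)
    for (i in which(!is.na(pm$parent))) {
      parent_row <- match(pm$parent[i], qid)
      for (f in fams) expect_gte(pm[[f]][parent_row], pm[[f]][i])
    }
  }
})

test_that("the persistence rule applies the 75% / 5-genome thresholds", {
  expect_true(persistent_at(99, 100))
  expect_true(persistent_at(4, 5))        # 0.80 in the smallest evaluable taxon
  expect_false(persistent_at(28, 42))     # 0.667 misses the strict rule
  expect_true(is.na(persistent_at(3, 4))) # too few genomes to evaluate
  expect_equal(persistent_at(c(99, 4, 28, 3), c(100, 5, 42, 4)),
               c(TRUE, TRUE, FALSE, NA))
  expect_error(persistent_at(6, 5), "exceeds")
})

test_that("neighbor joining recovers additive metrics exactly", {
  # two taxa: a single path of the pairwise distance
  t2 <- nj_tree(matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"),
                                                         c("a", "b"))))
  expect_equal(sum(t2$edge.length), 3)
  # three taxa: branch lengths from the three-point formulas
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["a"]], (2 + 3 - 4) / 2)
  expect_equal(bl[["b"]], (2 + 4 - 3) / 2)
  expect_equal(bl[["c"]], (3 + 4 - 2) / 2)
  # additive metrics up to n = 8: path lengths reconstruct the input
  for (n in 4:8) {
    gen <- random_additive_metric(n, seed = 200 + n)
    got <- ape::cophenetic.phylo(nj_tree(gen$d))
    expect_equal(got[rownames(gen$d), colnames(gen$d)], gen$d,
                 tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(nj_tree(matrix(c(1, 1, 1, 1), 2)), "diagonal")
})

test_that("homologous-group refinement reassorts by monophyly", {
  ts <- taxonomy_spec(ranks = c("phylum", "class"),
                      sizes = list(phylum = 1L, class = 2L),
                      strains_per_leaf = 6L, seed = 3)
  m <- generate_taxonomy(ts)
  classes <- unique(m$class)
  sA <- m$strain_id[m$class == classes[1]]
  sB <- m$strain_id[m$class == classes[2]]
  # two related families living in disjoint classes, merged into one cluster
  fa <- emit_family_sequences(family_spec("fa", "sporadic", divergence = 0.05,
                                          ancestor_length = 200L), 5, seed = 1,
                              ids = paste0("fa_", sA[1:5]))$seqs
  fb <- emit_family_sequences(family_spec("fb", "sporadic", divergence = 0.05,
                                          ancestor_length = 200L), 5, seed = 2,
                              ids = paste0("fb_", sB[1:5]))$seqs
  seqs <- c(fa, fb)
  gene_strain <- setNames(sub("^f[ab]_", "", names(seqs)), names(seqs))
  clusters <- data.frame(gene_id = names(seqs), cluster_id = 1L,
                         is_centroid = seq_along(seqs) == 1L)
  hgs <- refine_hgs(clusters, seqs, m, gene_strain, label_rank = "class")
  expect_length(hgs, 1L)
  sub <- hgs[[1]]$subgroups
  expect_length(sub, 2L)
  expect_setequal(vapply(sub, function(s)
    paste(sort(unique(sub("_.*", "", s))), collapse = ","), ""),
    c("fa", "fb"))
  # single small cluster passes through untouched
  tiny <- data.frame(gene_id = names(fa)[1:2], cluster_id = 1L,
                     is_centroid = c(TRUE, FALSE))
  hg1 <- refine_hgs(tiny, fa[1:2], m, gene_strain)
  expect_identical(hg1[[1]]$subgroups[[1]], names(fa)[1:2])
})

test_that("a horizontally transferred migrant lands in the residual group", {
  ts <- taxonomy_spec(ranks = c("phylum", "class"),
                      sizes = list(phylum = 1L, class = 2L),
                      strains_per_leaf = 8L, seed = 13)
  m <- generate_taxonomy(ts)
  classes <- unique(m$class)
  home <- m$strain_id[m$class == classes[1]]
  foreign <- m$strain_id[m$class == classes[2]][1]
  fam <- emit_family_sequences(family_spec("hg", "sporadic", divergence = 0.08,
                                           ancestor_length = 180L),
                               7, seed = 4,
                               ids = paste0("g_", c(home[1:6], foreign)))$seqs
  gene_strain <- setNames(sub("^g_", "", names(fam)), names(fam))
  clusters <- data.frame(gene_id = names(fam), cluster_id = 1L,
                         is_centroid = seq_along(fam) == 1L)
  hgs <- refine_hgs(clusters, fam, m, gene_strain, label_rank = "class")
  sub <- hgs[[1]]$subgroups
  expect_equal(names(sub)[length(sub)], "residual")
  expect_identical(sub$residual, paste0("g_", foreign))
  expect_setequal(sub[[1]], paste0("g_", home[1:6]))
})

test_that("persistence reporting picks the most inclusive passing taxon", {
  ts <- taxonomy_spec(ranks = c("phylum", "class", "order"),
                      sizes = list(phylum = 2L, class = 2L, order = 2L),
                      strains_per_leaf = 5L, seed = 23)
  m <- generate_taxonomy(ts)
  classes <- unique(m$class)
  orders <- unique(m$order)
  # full presence throughout one class: reported once, at the class
  cls_strains <- m$strain_id[m$class == classes[1]]
  gt <- data.frame(gene_id = paste0("g", seq_along(cls_strains)),
                   strain_id = cls_strains, family_id = "cls_fam")
  pm <- presence_matrix(gt, m)
  rep1 <- persistence_report(pm)
  hit <- rep1[rep1$family == "cls_fam", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rank, "class")
  expect_equal(hit$taxon, classes[1])
  expect_equal(hit$tier, "persistent")
  # presence in a single order only: reported at that order
  ord_strains <- m$strain_id[m$order == orders[1]][1:4]
  gt2 <- data.frame(gene_id = paste0("h", 1:4), strain_id = ord_strains,
                    family_id = "ord_fam")
  rep2 <- persistence_report(presence_matrix(gt2, m))
  hit2 <- rep2[rep2$family == "ord_fam", ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$rank, "order")
  expect_equal(hit2$fraction, 0.8)
})

test_that("published persistent-system rows evaluate to the printed summary", {
  t3 <- read_survey_table("persistent_systems")
  ev <- persistence_evaluate(t3)
  expect_equal(sum(!is.na(ev$tier)), 29L)
  expect_equal(sum(ev$tier == "persistent", na.rm = TRUE), 28L)
  # the one near-persistent row is the 28-of-42 Type I system
  near <- ev[!is.na(ev$tier) & ev$tier == "near_persistent", ]
  expect_equal(near$count / near$size, 2 / 3, tolerance = 1e-9)
  bands <- attr(ev, "band_summary")
  expect_equal(as.integer(bands), c(1L, 3L, 7L, 18L))
})
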