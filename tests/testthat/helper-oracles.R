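# Independent oracles and fixture builders shared across the suite.

# Literal replay of the greedy centroid clustering definition, written
# independently of greedy_cluster(): sort by length (desc) then id, scan
# centroids in creation order, join the first at >= threshold identity.
oracle_greedy_cluster <- function(seqs, threshold) {
  seqs <- setNames(as.character(seqs), names(seqs))
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  centroids <- character(0)
  members <- list()
  for (id in ids) {
    home <- NA_integer_
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(seqs[[id]], seqs[[centroids[ci]]]) >= threshold) {
        home <- ci
        break
      }
    }
    if (is.na(home)) {
      centroids <- c(centroids, id)
      members[[length(members) + 1L]] <- id
    } else {
      members[[home]] <- c(members[[home]], id)
    }
  }
  lapply(seq_along(centroids), function(i)
    list(centroid = centroids[i], members = sort(members[[i]])))
}

# clustering result -> comparable canonical form
canonical_clusters <- function(clusters) {
  split_members <- split(clusters$gene_id, clusters$cluster_id)
  cents <- clusters$gene_id[clusters$is_centroid]
  out <- lapply(sort(unique(clusters$cluster_id)), function(cid) {
    m <- sort(split_members[[as.character(cid)]])
    list(centroid = intersect(cents, m), members = m)
  })
  out
}

# brute-force best-window profile score: enumerate every placement
oracle_window_score <- function(emission, seq) {
  s <- strsplit(seq, "")[[1]]
  W <- nrow(emission)
  L <- length(s)
  if (L < W) return(-Inf)
  best <- -Inf
  for (o in 0:(L - W)) {
    sc <- 0
    for (i in seq_len(W)) sc <- sc + emission[i, s[o + i]]
    best <- max(best, sc)
  }
  best
}

# a random protein sequence
random_protein <- function(L) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), L, replace = TRUE), collapse = "")
}

# small world: taxonomy + families with known truth, used by several tests
build_test_world <- function(seed = 1L, methylome_fraction = 1) {
  ts <- taxonomy_spec(ranks = c("phylum", "class", "order"),
                      sizes = list(phylum = 2L, class = 2L, order = 2L),
                      strains_per_leaf = 10L, seed = seed,
                      methylome_fraction = methylome_fraction)
  manifest <- generate_taxonomy(ts)
  classes <- unique(manifest$class)
  specs <- list(
    family_spec("perA", "persistent", home_taxon = classes[1],
                presence_rate = 0.95, category = "IIM", meth_type = "m6A",
                motif = "GATC"),
    family_spec("perB", "persistent", home_taxon = classes[2],
                presence_rate = 0.9, category = "IIM", meth_type = "m5C",
                motif = "CCWGG"),
    family_spec("spoA", "sporadic", presence_rate = 0.15, category = "IIR",
                meth_type = "none"),
    family_spec("spoB", "sporadic", presence_rate = 0.1, category = "IM",
                meth_type = "m6A", motif = "CATTC")
  )
  world <- plant_families(manifest, specs, seed = seed + 1L)
  list(manifest = manifest, specs = specs, gene_table = world$gene_table,
       truth = world$truth)
}

# an additive distance matrix from a random tree, plus the tree itself
random_additive_metric <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

csym_gene_table <- function() {
  # the published two-extremes example: 25 RM loci comprising 17 orphan Type
  # II MTases, one IIM pair, one IIM+Vsr, two complete Type II systems, two
  # IIG genes and two complete Type III systems
  data.frame(
    gene_id = sprintf("g%02d", 1:31),
    strain_id = "CsymA",
    locus_id = c(1:17, 18, 18, 19, 19, 20, 20, 21, 21, 22, 23, 24, 24, 25, 25),
    category = c(rep("IIM", 17), "IIM", "IIM", "IIM", "V", "IIM", "IIR",
                 "IIM", "IIR", "IIG", "IIG", "IIIM", "IIIR", "IIIM", "IIIR"),
    stringsAsFactors = FALSE)
}

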