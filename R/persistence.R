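#' Presence/absence matrix of gene families across the taxonomy
#'
#' For every taxon at every rank of the manifest, counts the member genomes
#' containing at least one gene of each family, together with the taxon
#' size. Taxa are identified by rank-qualified ids (`rank:name`) so that
#' name collisions across ranks cannot merge rows.
#'
#' @param gene_table data.frame with `strain_id` and a family column
#' @param manifest strain manifest
#' @param family_col name of the family column (default `"family_id"`)
#' @return data.frame: `rank`, `taxon`, `parent` (rank-qualified id of the
#'   parent taxon, `NA` at the top rank), `size`, one count column per
#'   family, plus attribute `families`
#' @export
presence_matrix <- function(gene_table, manifest, family_col = "family_id") {
  unknown <- setdiff(unique(gene_table$strain_id), manifest$strain_id)
  if (length(unknown))
    stop("gene(s) reference strain(s) not in the manifest: ",
         paste(head(unknown, 5), collapse = ", "))
  ranks <- manifest_ranks(manifest)
  fams <- sort(unique(gene_table[[family_col]]))
  # strain x family incidence
  inc <- table(factor(gene_table$strain_id, levels = manifest$strain_id),
               factor(gene_table[[family_col]], levels = fams)) > 0
  rows <- list()
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    taxa <- .taxon_at(manifest, r)
    sizes <- table(factor(taxa, levels = unique(taxa)))
    counts <- rowsum(inc + 0L, group = taxa, reorder = FALSE)
    parent <- if (ri == 1L) rep(NA_character_, length(sizes)) else {
      pr <- ranks[ri - 1L]
      paste0(pr, ":", .taxon_at(manifest, pr)[match(names(sizes), taxa)])
    }
    df <- data.frame(rank = r, taxon = names(sizes), parent = parent,
                     size = as.integer(sizes), stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(counts[names(sizes), , drop = FALSE]))
    rows[[r]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "families") <- fams
  out
}

#' Persistence rule for one (taxon, family) cell
#'
#' A family is persistent in a taxon when the taxon has at least
#' `min_genomes` genomes and the family is present in at least `min_frac`
#' of them. Taxa below the genome floor are not evaluable (`NA`).
#'
#' @param count genomes containing the family
#' @param size taxon size in genomes
#' @param min_frac incidence threshold (default 0.75)
#' @param min_genomes minimum evaluable taxon size (default 5)
#' @return logical (`NA` when not evaluable); vectorized
#' @export
persistent_at <- function(count, size, min_frac = 0.75, min_genomes = 5L) {
  if (any(count > size)) stop("count exceeds taxon size")
  if (any(count < 0 | size < 0)) stop("counts must be non-negative")
  ifelse(size < min_genomes, NA, count / size >= min_frac)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) with input
#' validation: the matrix must be symmetric with a zero diagonal and at
#' least two taxa. The two-taxon case, which NJ proper does not handle,
#' returns the unique two-leaf tree whose path length equals the pairwise
#' distance. Exactly recovers topology and branch lengths for additive
#' metrics.
#'
#' @param d symmetric numeric matrix (or `dist`) with zero diagonal
#' @return unrooted binary tree of class `phylo`
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (nrow(d) == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(stats::as.dist(d))
}

# all splits of an unrooted phylo tree as a list of tip-label sets, both
# orientations, sizes 2..(n-2) plus the pendant (n-1)-sets
.tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)  # clades under an arbitrary rooting
  sets <- lapply(parts, function(ix) tree$tip.label[ix])
  sets <- c(sets, lapply(sets, function(s) setdiff(tree$tip.label, s)))
  # add pendant splits (each leaf vs the rest)
  sets <- c(sets, lapply(tree$tip.label, function(l) setdiff(tree$tip.label, l)))
  sets <- sets[vapply(sets, length, 0L) %in% 2:(n - 1L)]
  sets[!duplicated(vapply(sets, function(s) paste(sort(s), collapse = "\r"), ""))]
}

#' Merge related clusters and reassort members by tree monophyly
#'
#' Homologous-group (HG) refinement: clusters judged closely related (same
#' best-hit profile and centroid-to-centroid identity at or above
#' `merge_min_ident`, or listed in `merge_override`) are combined; a
#' neighbor-joining tree is built on p-distances (1 - pairwise identity)
#' over the combined members; and members are reassorted into subgroups —
#' maximal split sides of at least two leaves whose members all carry the
#' same taxon label at `label_rank`. Leaves in no such side (e.g. single
#' horizontally transferred migrants inside a foreign clade) fall into a
#' residual subgroup. Groups of fewer than three members pass through
#' unchanged.
#'
#' @param clusters data.frame from [greedy_cluster()]
#' @param seqs named character vector / `AAStringSet` of member sequences
#' @param manifest strain manifest
#' @param gene_strain named character vector mapping gene id to strain id
#' @param label_rank rank whose taxon labels drive the reassortment
#' @param calls optional classification calls (`gene_id`, `profile`) used
#'   for the shared-best-profile merge rule
#' @param merge_min_ident centroid identity for merging (default 0.20)
#' @param merge_override optional list of character vectors of cluster ids
#'   to force-merge
#' @return list of homologous groups, each with `hg_id`, `source_clusters`,
#'   `members`, `tree` (`phylo` or `NULL`), `subgroups` (list of member id
#'   vectors; the last one named `residual` when non-empty)
#' @export
refine_hgs <- function(clusters, seqs, manifest, gene_strain,
                       label_rank = "class", calls = NULL,
                       merge_min_ident = 0.20, merge_override = NULL) {
  seqs <- setNames(as.character(seqs), names(seqs))
  cent <- clusters[clusters$is_centroid, , drop = FALSE]
  cl_ids <- cent$cluster_id
  # decide which clusters merge: same top profile + centroid identity rule
  group_of <- setNames(seq_along(cl_ids), cl_ids)
  link <- function(a, b) {
    ga <- group_of[[as.character(a)]]; gb <- group_of[[as.character(b)]]
    if (ga != gb) group_of[group_of == gb] <<- ga
  }
  if (!is.null(calls) && nrow(cent) > 1L) {
    prof <- setNames(calls$profile[match(cent$gene_id, calls$gene_id)],
                     cent$cluster_id)
    for (i in seq_len(nrow(cent) - 1L)) for (j in (i + 1L):nrow(cent)) {
      a <- cent$cluster_id[i]; b <- cent$cluster_id[j]
      if (!is.na(prof[[as.character(a)]]) &&
          identical(prof[[as.character(a)]], prof[[as.character(b)]]) &&
          pairwise_identity(seqs[[cent$gene_id[i]]],
                            seqs[[cent$gene_id[j]]]) >= merge_min_ident)
        link(a, b)
    }
  }
  for (ov in merge_override %||% list()) {
    for (b in ov[-1]) link(ov[1], b)
  }
  hgs <- list()
  labels_all <- setNames(.taxon_at(manifest, label_rank), manifest$strain_id)
  for (g in unique(group_of)) {
    src <- as.integer(names(group_of)[group_of == g])
    members <- clusters$gene_id[clusters$cluster_id %in% src]
    hg_id <- sprintf("HG%02d", length(hgs) + 1L)
    if (length(members) < 3L) {
      hgs[[hg_id]] <- list(hg_id = hg_id, source_clusters = src,
                           members = members, tree = NULL,
                           subgroups = list(members))
      next
    }
    m <- length(members)
    d <- matrix(0, m, m, dimnames = list(members, members))
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[[members[i]]],
                                                  seqs[[members[j]]])
    tree <- nj_tree(d)
    labels <- labels_all[gene_strain[members]]
    names(labels) <- members
    cand <- .tree_splits(tree)
    homog <- cand[vapply(cand, function(s)
      length(unique(labels[s])) == 1L, NA)]
    # greedy maximal disjoint homogeneous sides, largest first
    ord <- order(-vapply(homog, length, 0L),
                 vapply(homog, function(s) paste(sort(s), collapse = ","), ""))
    chosen <- list()
    used <- character(0)
    for (s in homog[ord]) {
      if (!length(intersect(s, used))) {
        chosen[[length(chosen) + 1L]] <- sort(s)
        used <- c(used, s)
      }
    }
    residual <- setdiff(members, used)
    subgroups <- chosen
    if (length(residual)) {
      subgroups <- c(subgroups, list(sort(residual)))
      names(subgroups) <- c(rep("", length(chosen)), "residual")
    }
    hgs[[hg_id]] <- list(hg_id = hg_id, source_clusters = src,
                         members = members, tree = tree,
                         subgroups = subgroups)
  }
  hgs
}

# ancestor chain (rank-qualified ids) for each taxon row of a presence matrix
.ancestors <- function(pm) {
  qid <- paste0(pm$rank, ":", pm$taxon)
  parent <- setNames(pm$parent, qid)
  anc <- list()
  for (id in qid) {
    chain <- character(0)
    p <- parent[[id]]
    while (!is.na(p)) {
      chain <- c(chain, p)
      p <- parent[[p]]
    }
    anc[[id]] <- chain
  }
  anc
}

#' Persistence report over a presence matrix
#'
#' Evaluates the persistence rule for every (taxon, family) cell at every
#' rank and reports each hit at the most inclusive taxon where the rule
#' passes, suppressing records at its descendant taxa for the same family.
#' Near misses — incidence within `slack` below the threshold in an
#' evaluable taxon — are reported in a separate `near_persistent` tier,
#' accommodating conserved families with a few incomplete members; the same
#' most-inclusive suppression applies across both tiers.
#'
#' @param pm presence matrix from [presence_matrix()]
#' @param system_class optional named vector mapping family id to a system
#'   class label (e.g. `IIM`, `IM/R/S`, `BREX`, `IV`)
#' @param motifs optional named vector mapping family id to a motif label
#' @param min_frac incidence threshold (default 0.75)
#' @param min_genomes minimum evaluable taxon size (default 5)
#' @param slack absolute incidence slack defining the near-persistent tier
#'   (default 0.10)
#' @return data.frame: `taxon`, `rank`, `size`, `family`, `count`,
#'   `fraction`, `tier` (`persistent` / `near_persistent`), `system_class`,
#'   `motif`, sorted by rank then taxon
#' @export
persistence_report <- function(pm, system_class = NULL, motifs = NULL,
                               min_frac = 0.75, min_genomes = 5L,
                               slack = 0.10) {
  fams <- attr(pm, "families") %||%
    setdiff(names(pm), c("rank", "taxon", "parent", "size"))
  anc <- .ancestors(pm)
  qid <- paste0(pm$rank, ":", pm$taxon)
  recs <- list()
  for (f in fams) {
    frac <- pm[[f]] / pm$size
    strict <- persistent_at(pm[[f]], pm$size, min_frac, min_genomes)
    near <- !is.na(strict) & !strict & frac >= (min_frac - slack)
    hit <- (!is.na(strict) & strict) | near
    if (!any(hit)) next
    hit_ids <- qid[hit]
    # most-inclusive reporting: drop a hit whose ancestor also hits
    keep <- vapply(which(hit), function(i)
      !any(anc[[qid[i]]] %in% hit_ids), NA)
    for (i in which(hit)[keep]) {
      recs[[length(recs) + 1L]] <- data.frame(
        taxon = pm$taxon[i], rank = pm$rank[i], size = pm$size[i],
        family = f, count = pm[[f]][i], fraction = frac[i],
        tier = if (isTRUE(strict[i])) "persistent" else "near_persistent",
        system_class = unname((system_class %||% character())[f] %||% NA_character_),
        motif = unname((motifs %||% character())[f] %||% NA_character_),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(taxon = character(0), rank = character(0), size = integer(0),
               family = character(0), count = integer(0), fraction = numeric(0),
               tier = character(0), system_class = character(0),
               motif = character(0))
  rank_order <- c("phylum", "class", "order", "family", "genus", "species")
  out <- out[order(match(out$rank, rank_order), out$taxon, out$family), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate persistence on pre-tabulated (taxon, family) records
#'
#' For survey-style summary tables that directly list taxon sizes and family
#' member counts (rather than a full manifest), applies the persistence rule
#' to each row and attaches the tier. The rank-band summary groups phylum
#' and class ranks as themselves, order as itself, and everything below
#' order into a family-to-species band.
#'
#' @param records data.frame with `taxon`, `rank`, `size`, `family`,
#'   `count` and optionally `system_class`
#' @param min_frac,min_genomes,slack as in [persistence_report()]
#' @return `records` with added `fraction` and `tier` columns (`NA` tier =
#'   neither persistent nor near-persistent), plus attributes
#'   `band_summary` and `class_summary` counting tiered rows
#' @export
persistence_evaluate <- function(records, min_frac = 0.75, min_genomes = 5L,
                                 slack = 0.10) {
  records$fraction <- records$count / records$size
  strict <- persistent_at(records$count, records$size, min_frac, min_genomes)
  near <- !is.na(strict) & !strict & records$fraction >= (min_frac - slack)
  records$tier <- ifelse(!is.na(strict) & strict, "persistent",
                         ifelse(near, "near_persistent", NA_character_))
  flagged <- records[!is.na(records$tier), , drop = FALSE]
  band <- function(r) ifelse(r %in% c("phylum", "class", "order"), r,
                             "family_to_species")
  attr(records, "band_summary") <-
    table(factor(band(flagged$rank),
                 levels = c("phylum", "class", "order", "family_to_species")))
  if ("system_class" %in% names(flagged))
    attr(records, "class_summary") <- table(flagged$system_class)
  records
}
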