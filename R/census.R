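#' Type RM loci from co-located gene calls
#'
#' Assigns each locus (a group of adjacent genes on the replicon, given by
#' the `locus_id` column) a locus type from the composition of its genes'
#' functional categories, following the canonical arrangements: a lone Type
#' II MTase is an orphan; two co-located IIM genes an MTase pair; IIM with a
#' Vsr nuclease an MTase/Vsr locus; IIM with a Type II REase a complete
#' Type II system; a lone IIG a fused RM gene; co-located Type I subunits
#' (IM/IR/IS, at least two) a Type I system; IIIM alone or with IIIR a Type
#' III system; a lone IV a methyl-directed REase; any M gene a BREX locus.
#' Everything else, including unknown categories, lands in `other`.
#'
#' @param gene_table data.frame with `gene_id`, `strain_id`, `locus_id`,
#'   `category`
#' @return data.frame with one row per locus: `strain_id`, `locus_id`,
#'   `locus_type`, `n_genes`, `categories` (comma-joined, input order)
#' @export
type_loci <- function(gene_table) {
  needed <- c("gene_id", "strain_id", "locus_id", "category")
  if (!all(needed %in% names(gene_table)))
    stop("gene_table needs columns: ", paste(needed, collapse = ", "))
  one <- function(cats) {
    tab <- table(factor(cats, levels = c(RM_CATEGORIES, "unknown")))
    n <- length(cats)
    if (any(cats == "M")) return("BREX")
    if (n == 1L) {
      return(switch(cats,
                    IIM = "orphan_IIM", IIG = "IIG", IV = "IV",
                    IIIM = "III_system", "other"))
    }
    if (n == 2L && tab[["IIM"]] == 2L) return("IIM_pair")
    if (tab[["IIM"]] == 1L && tab[["V"]] == 1L && n == 2L) return("IIM_vsr")
    if (tab[["IIM"]] >= 1L && tab[["IIR"]] >= 1L && n == tab[["IIM"]] + tab[["IIR"]])
      return("II_complete")
    typeI <- tab[["IM"]] + tab[["IR"]] + tab[["IS"]]
    if (typeI == n && typeI >= 2L) return("I_system")
    typeIII <- tab[["IIIM"]] + tab[["IIIR"]]
    if (typeIII == n && tab[["IIIM"]] >= 1L) return("III_system")
    "other"
  }
  split_idx <- split(seq_len(nrow(gene_table)),
                     paste(gene_table$strain_id, gene_table$locus_id, sep = "\r"))
  rows <- lapply(split_idx, function(ix) {
    cats <- gene_table$category[ix]
    data.frame(strain_id = gene_table$strain_id[ix[1]],
               locus_id = gene_table$locus_id[ix[1]],
               locus_type = one(cats),
               n_genes = length(ix),
               categories = paste(cats, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# taxon label of each strain at a rank, honoring explicit missing entries
.taxon_at <- function(manifest, rank) {
  tx <- manifest[[rank]]
  tx[is.na(tx) | tx == ""] <- "unclassified"
  tx
}

#' Per-taxon census of genes by functional category
#'
#' Mean genes per genome for every functional category, per taxon at the
#' requested rank, plus a TOTAL row over all genomes. Means are exact
#' (total genes / genome count); rounding is left to the caller.
#'
#' @param calls data.frame with `gene_id`, `strain_id`, `category`
#' @param manifest strain manifest (one row per genome)
#' @param rank rank column name in the manifest
#' @param categories category columns to report (default the 13 standard)
#' @return data.frame: `taxon`, `n_genomes`, one numeric column per category
#' @export
census_by_taxon <- function(calls, manifest, rank,
                            categories = RM_CATEGORIES) {
  unknown <- setdiff(unique(calls$strain_id), manifest$strain_id)
  if (length(unknown))
    stop("gene(s) reference unknown strain(s): ",
         paste(head(unknown, 5), collapse = ", "))
  if (!rank %in% names(manifest)) stop("manifest has no rank column: ", rank)
  taxa <- .taxon_at(manifest, rank)
  strain_taxon <- setNames(taxa, manifest$strain_id)
  counts <- table(factor(strain_taxon[calls$strain_id], levels = unique(taxa)),
                  factor(calls$category, levels = categories))
  sizes <- table(factor(taxa, levels = unique(taxa)))
  means <- sweep(counts, 1, as.numeric(sizes), `/`)
  out <- data.frame(taxon = rownames(means),
                    n_genomes = as.integer(sizes),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame.matrix(means))
  total <- data.frame(taxon = "TOTAL", n_genomes = nrow(manifest),
                      stringsAsFactors = FALSE)
  for (cc in categories)
    total[[cc]] <- sum(calls$category == cc) / nrow(manifest)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Aggregate printed census rows into a weighted total row
#'
#' Given per-taxon census rows (genome counts plus per-category means),
#' computes the genome-count-weighted mean of every category — the exact
#' relationship that must hold between child rows and their parent or TOTAL
#' row of a census table.
#'
#' @param rows data.frame with `n_genomes` and numeric mean columns
#' @param mean_cols which columns to aggregate (default: all numeric except
#'   `n_genomes`)
#' @return one-row data.frame with `n_genomes` and the weighted means
#' @export
census_total <- function(rows, mean_cols = NULL) {
  if (is.null(mean_cols)) {
    num <- vapply(rows, is.numeric, NA)
    mean_cols <- setdiff(names(rows)[num], "n_genomes")
  }
  out <- data.frame(n_genomes = sum(rows$n_genomes))
  for (cc in mean_cols)
    out[[cc]] <- weighted.mean(rows[[cc]], rows$n_genomes)
  out
}

#' Methylation-type census of genes and observed motifs, with reconciliation
#'
#' Computes, per taxon at the requested rank and per methylated base (m6A,
#' m4C, m5C): mean MTase genes per genome over all genomes; mean MTase genes
#' per genome over the genomes with methylome data; and mean observed motifs
#' per genome over the genomes with methylome data (motif cells are `NA`,
#' not zero, for taxa with no methylome genomes). Since inactive genes and
#' undetected m5C motifs can only reduce motif counts, motifs exceeding
#' genes within the methylome subset flags an anomaly — a misclassified
#' activity, a misassigned motif type, or a genome missing a plasmid.
#'
#' @param calls gene calls (`strain_id`, `category`, `meth_type`)
#' @param methylome data.frame (`strain_id`, `motif`, `type`)
#' @param manifest strain manifest with `has_methylome`
#' @param rank rank column name
#' @return list with `genes` (all genomes), `genes_meth` and `motifs`
#'   (methylome genomes), each a [census_by_taxon()]-shaped data.frame over
#'   the three methylation types, and `flags`: rows where a motif mean
#'   exceeds the matching gene mean
#' @export
meth_census <- function(calls, methylome, manifest, rank) {
  if (nrow(methylome) && !all(methylome$type %in% METH_TYPES))
    stop("motif with unknown methylation type: ",
         paste(unique(setdiff(methylome$type, METH_TYPES)), collapse = ", "))
  mt_calls <- calls[calls$meth_type %in% METH_TYPES, , drop = FALSE]
  mt_calls$category <- mt_calls$meth_type
  genes <- census_by_taxon(mt_calls, manifest, rank, categories = METH_TYPES)
  sub <- manifest[manifest$has_methylome, , drop = FALSE]
  if (nrow(sub)) {
    sub_calls <- mt_calls[mt_calls$strain_id %in% sub$strain_id, , drop = FALSE]
    genes_meth <- census_by_taxon(sub_calls, sub, rank, categories = METH_TYPES)
    mot <- methylome[methylome$strain_id %in% sub$strain_id, , drop = FALSE]
    mot$category <- mot$type
    motifs <- census_by_taxon(mot, sub, rank, categories = METH_TYPES)
  } else {
    genes_meth <- genes[0, , drop = FALSE]
    motifs <- genes[0, , drop = FALSE]
  }
  # re-express the methylome-subset tables on the full taxon list, with NA
  # (blank) motif cells for taxa that have no methylome genomes
  template <- genes[, c("taxon", "n_genomes"), drop = FALSE]
  expand <- function(tab) {
    idx <- match(template$taxon, tab$taxon)
    out <- data.frame(taxon = template$taxon,
                      n_genomes = ifelse(is.na(idx), 0L, tab$n_genomes[idx]))
    for (tt in METH_TYPES) out[[tt]] <- tab[[tt]][idx]
    out
  }
  genes_meth <- expand(genes_meth)
  motifs <- expand(motifs)
  flags <- NULL
  for (tt in METH_TYPES) {
    excess <- !is.na(motifs[[tt]]) & motifs[[tt]] > genes_meth[[tt]]
    if (any(excess))
      flags <- rbind(flags, data.frame(
        taxon = motifs$taxon[excess], meth_type = tt,
        gene_mean = genes_meth[[tt]][excess],
        motif_mean = motifs[[tt]][excess],
        motifs_exceed_genes = TRUE, stringsAsFactors = FALSE))
  }
  if (is.null(flags))
    flags <- data.frame(taxon = character(0), meth_type = character(0),
                        gene_mean = numeric(0), motif_mean = numeric(0),
                        motifs_exceed_genes = logical(0))
  list(genes = genes, genes_meth = genes_meth, motifs = motifs, flags = flags)
}

#' Methylation-type ratio from census means
#'
#' Normalizes the (m6A, m4C, m5C) gene means to m5C = 1, the conventional
#' presentation of per-genome MTase gene ratios. If the m5C mean is zero the
#' ratio is reported against m4C instead, with a warning.
#'
#' @param means numeric vector or one-row data.frame with `m6A`, `m4C`,
#'   `m5C` entries
#' @return named numeric triple normalized to the reference base; attribute
#'   `reference` names the base used
#' @export
meth_ratio <- function(means) {
  if (is.data.frame(means)) means <- unlist(means[1, METH_TYPES])
  means <- means[METH_TYPES]
  ref <- "m5C"
  if (means[["m5C"]] == 0) {
    if (means[["m4C"]] == 0) stop("both m5C and m4C means are zero")
    warning("m5C mean is zero; normalizing to m4C instead")
    ref <- "m4C"
  }
  out <- means / means[[ref]]
  attr(out, "reference") <- ref
  out
}

#' Present a methylation ratio as rounded integers
#' @param ratio output of [meth_ratio()]
#' @return character string like `"4:2:1"`
#' @export
format_ratio <- function(ratio) paste(round(as.numeric(ratio)), collapse = ":")
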