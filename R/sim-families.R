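#' Specify a synthetic RM gene family
#'
#' A family is either `persistent` — vertically conserved, present in most
#' members of one home taxon — or `sporadic` — horizontally scattered across
#' the whole manifest with a patchy distribution. Sequences of the family
#' derive from a common random ancestor by i.i.d. per-position substitution.
#'
#' @param family_id unique family label
#' @param mode `"persistent"` or `"sporadic"`
#' @param home_taxon taxon name (must match a manifest taxonomy cell);
#'   required for persistent families, ignored for sporadic ones
#' @param presence_rate per-strain presence probability in `[0, 1]`
#' @param category one of the 13 RM functional categories
#' @param meth_type `"m6A"`, `"m4C"`, `"m5C"` or `"none"`
#' @param motif recognition motif (IUPAC) contributed to the methylome by
#'   active genes; `NA` for non-MTase families
#' @param ancestor_length ancestor length in residues
#' @param divergence expected fraction of substituted positions in `[0, 1)`
#' @return an object of class `family_spec`
#' @export
family_spec <- function(family_id, mode = c("persistent", "sporadic"),
                        home_taxon = NULL, presence_rate = 0.9,
                        category = "IIM", meth_type = "m6A", motif = NA_character_,
                        ancestor_length = 300L, divergence = 0.1) {
  mode <- match.arg(mode)
  if (mode == "persistent" && is.null(home_taxon))
    stop("persistent mode requires a home_taxon")
  stopifnot_scalar_prob(presence_rate, "presence_rate")
  if (!category %in% RM_CATEGORIES)
    stop("unknown category: ", category)
  if (!meth_type %in% c(METH_TYPES, "none"))
    stop("unknown meth_type: ", meth_type)
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  if (ancestor_length < 1) stop("ancestor_length must be >= 1")
  structure(list(family_id = family_id, mode = mode, home_taxon = home_taxon,
                 presence_rate = presence_rate, category = category,
                 meth_type = meth_type, motif = motif,
                 ancestor_length = as.integer(ancestor_length),
                 divergence = divergence),
            class = "family_spec")
}

#' Plant gene families into a strain manifest
#'
#' Persistent families are planted independently in each strain of their home
#' taxon with probability `presence_rate`; sporadic families in any strain of
#' the manifest with the same independence. This emulates the two incidence
#' patterns seen for RM genes — vertical conservation within a clade versus
#' horizontal scattering — without simulating explicit gain/loss on a tree.
#'
#' @param manifest strain manifest from [generate_taxonomy()]
#' @param specs list of [family_spec()] objects
#' @param seed integer seed
#' @return list with `gene_table` (data.frame: gene_id, strain_id, family_id,
#'   category, meth_type, active) and `truth` (list keyed by family_id with
#'   the planted strains, category, meth_type and motif)
#' @export
plant_families <- function(manifest, specs, seed = 1L) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  ranks <- manifest_ranks(manifest)
  all_taxa <- unique(unlist(manifest[ranks]))
  for (sp in specs) {
    if (sp$mode == "persistent" && !sp$home_taxon %in% all_taxa)
      stop("unknown home taxon: ", sp$home_taxon)
  }
  ids <- vapply(specs, `[[`, "", "family_id")
  if (anyDuplicated(ids)) stop("duplicate family ids")
  with_seed(seed, {
    rows <- list()
    truth <- list()
    k <- 0L
    for (sp in specs) {
      host_pool <- if (sp$mode == "persistent") {
        in_home <- Reduce(`|`, lapply(ranks, function(r) manifest[[r]] == sp$home_taxon))
        manifest$strain_id[in_home]
      } else manifest$strain_id
      present <- host_pool[runif(length(host_pool)) < sp$presence_rate]
      genes <- if (length(present)) {
        data.frame(gene_id = sprintf("%s_g%03d", sp$family_id,
                                     k + seq_along(present)),
                   strain_id = present,
                   family_id = sp$family_id,
                   category = sp$category,
                   meth_type = sp$meth_type,
                   active = TRUE,
                   stringsAsFactors = FALSE)
      } else NULL
      k <- k + length(present)
      rows[[sp$family_id]] <- genes
      truth[[sp$family_id]] <- list(strains = present,
                                    gene_ids = if (is.null(genes)) character(0) else genes$gene_id,
                                    category = sp$category,
                                    meth_type = sp$meth_type,
                                    motif = sp$motif)
    }
    gene_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(gene_table))
      gene_table <- data.frame(gene_id = character(0), strain_id = character(0),
                               family_id = character(0), category = character(0),
                               meth_type = character(0), active = logical(0))
    list(gene_table = gene_table, truth = truth)
  })
}

# deterministic per-family seed: position-weighted character hash so that
# ids with the same character multiset (spo01 vs spo10) get distinct seeds
.family_seed <- function(seed, family_id) {
  h <- sum(utf8ToInt(family_id) * 31^(seq_len(nchar(family_id)) - 1))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# sample a random ancestor and derive n sequences by i.i.d. substitution:
# each position independently replaced with probability `divergence` by one
# of the 19 alternative residues, uniformly. Under this model the expected
# pairwise identity between two descendants is (1-d)^2 + d^2/19.
.derive_sequences <- function(ancestor, n, divergence) {
  L <- length(ancestor)
  vapply(seq_len(n), function(i) {
    s <- ancestor
    hit <- runif(L) < divergence
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(res) {
        sample(setdiff(AA_ALPHABET20, res), 1L)
      }, "")
    }
    paste(s, collapse = "")
  }, "")
}

#' Emit protein sequences for a synthetic family
#'
#' Draws a uniform-random ancestor of the spec's length, then derives `n`
#' descendants by substituting each position independently at the divergence
#' rate (uniform choice among the 19 alternative residues). With no indels
#' the columnwise alignment of the descendants is trivially the sequences
#' themselves, returned as the aligned set.
#'
#' @param spec a [family_spec()]
#' @param n number of sequences (>= 1)
#' @param seed integer seed
#' @param ids optional character vector of sequence names (default
#'   `<family>_g001` ...)
#' @return list with `seqs` and `aligned`, both [Biostrings::AAStringSet]
#'   objects, and `ancestor` (character scalar)
#' @export
emit_family_sequences <- function(spec, n, seed = 1L, ids = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    ancestor <- sample(AA_ALPHABET20, spec$ancestor_length, replace = TRUE)
    seqs <- .derive_sequences(ancestor, n, spec$divergence)
    names(seqs) <- ids %||% sprintf("%s_g%03d", spec$family_id, seq_len(n))
    set <- Biostrings::AAStringSet(seqs)
    list(seqs = set, aligned = set, ancestor = paste(ancestor, collapse = ""))
  })
}

#' Emit sequences for every planted gene of a synthetic world
#'
#' Convenience wrapper: one ancestor per family (seeded from the family id so
#' ancestors are unrelated), one derived sequence per planted gene.
#'
#' @param gene_table gene table from [plant_families()]
#' @param specs the list of [family_spec()]s used to plant it
#' @param seed integer seed
#' @return [Biostrings::AAStringSet] named by gene id
#' @export
emit_world_sequences <- function(gene_table, specs, seed = 1L) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, "", "family_id")
  out <- list()
  for (fid in names(specs)) {
    gids <- gene_table$gene_id[gene_table$family_id == fid]
    if (!length(gids)) next
    fam_seed <- .family_seed(seed, fid)
    out[[fid]] <- emit_family_sequences(specs[[fid]], length(gids),
                                        seed = fam_seed, ids = gids)$seqs
  }
  if (!length(out)) return(Biostrings::AAStringSet())
  do.call(c, unname(out))
}
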