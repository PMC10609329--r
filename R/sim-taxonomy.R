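#' Specify a ranked taxonomy of strains
#'
#' Describes a nested taxonomy from which a strain manifest is generated.
#' Ranks are ordered from most to least inclusive (e.g. phylum down to
#' species). `sizes` gives, for each rank, the number of child taxa under
#' each taxon of the parent rank; `strains_per_leaf` gives the number of
#' strains in each taxon of the last rank. Each of these may be a single
#' integer (applied uniformly) or a vector with one entry per parent taxon,
#' which allows deliberately uneven manifests such as a handful of large,
#' heavily sequenced classes next to many small ones.
#'
#' @param ranks character vector of rank names, most inclusive first
#' @param sizes named list (one entry per rank) of positive integers: number
#'   of taxa at that rank under each parent (scalar = uniform)
#' @param strains_per_leaf positive integer(s): strains per taxon of the last
#'   rank (scalar or one per leaf taxon)
#' @param seed integer seed controlling genome-length sampling
#' @param methylome_fraction fraction of strains flagged as having methylome
#'   data
#' @return an object of class `taxonomy_spec`
#' @export
taxonomy_spec <- function(ranks = c("phylum", "class", "order"),
                          sizes = list(phylum = 2L, class = 2L, order = 2L),
                          strains_per_leaf = 5L,
                          seed = 1L,
                          methylome_fraction = 0) {
  if (!length(ranks)) stop("at least one rank is required")
  if (!identical(sort(names(sizes)), sort(ranks)))
    stop("sizes must be a named list with one entry per rank")
  for (r in ranks) {
    s <- sizes[[r]]
    if (any(s < 1) || any(s != round(s)))
      stop("clade sizes must be positive integers (rank ", r, ")")
  }
  if (any(strains_per_leaf < 1))
    stop("clade sizes must be positive integers (strains_per_leaf)")
  stopifnot_scalar_prob(methylome_fraction, "methylome_fraction")
  structure(list(ranks = ranks, sizes = sizes,
                 strains_per_leaf = as.integer(strains_per_leaf),
                 seed = as.integer(seed),
                 methylome_fraction = methylome_fraction),
            class = "taxonomy_spec")
}

#' Generate a strain manifest from a taxonomy specification
#'
#' Expands the nested clade sizes into one row per strain. Every strain gets
#' a full rank path (taxon names are rank-prefixed, e.g. `"p1.c2"`), a
#' simulated genome length, and completeness fields populated as a finished
#' genome (`definition = "complete_genome"`, `status = "complete"`), so that
#' downstream completeness filtering keeps everything unless the caller
#' perturbs the fields. Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [taxonomy_spec()]
#' @return data.frame with columns `strain_id`, one column per rank,
#'   `definition_flag`, `longest_bp`, `project_status`, `has_methylome`
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "taxonomy_spec"))
  ranks <- spec$ranks
  # expand rank by rank: `paths` holds one row per taxon at the current rank
  paths <- data.frame(.dummy = 1)
  for (i in seq_along(ranks)) {
    n_parent <- nrow(paths)
    sz <- spec$sizes[[ranks[i]]]
    if (length(sz) == 1L) sz <- rep(sz, n_parent)
    if (length(sz) != n_parent)
      stop("sizes for rank ", ranks[i], " must have length 1 or ", n_parent)
    idx <- rep(seq_len(n_parent), sz)
    child <- unlist(lapply(sz, seq_len))
    paths <- paths[idx, , drop = FALSE]
    prefix <- substr(ranks[i], 1, 1)
    parent_name <- if (i == 1L) "" else paste0(paths[[ranks[i - 1L]]], ".")
    paths[[ranks[i]]] <- paste0(parent_name, prefix, child)
    rownames(paths) <- NULL
  }
  paths$.dummy <- NULL
  n_leaf <- nrow(paths)
  spl <- spec$strains_per_leaf
  if (length(spl) == 1L) spl <- rep(spl, n_leaf)
  if (length(spl) != n_leaf)
    stop("strains_per_leaf must have length 1 or ", n_leaf)
  manifest <- paths[rep(seq_len(n_leaf), spl), , drop = FALSE]
  rownames(manifest) <- NULL
  n <- nrow(manifest)
  manifest$strain_id <- sprintf("S%04d", seq_len(n))
  lengths_meth <- with_seed(spec$seed, {
    list(len = as.integer(round(runif(n, 1.5e6, 4e6))),
         meth = runif(n) < spec$methylome_fraction)
  })
  manifest$definition_flag <- "complete_genome"
  manifest$longest_bp <- lengths_meth$len
  manifest$project_status <- "complete"
  manifest$has_methylome <- lengths_meth$meth
  manifest[, c("strain_id", ranks, "definition_flag", "longest_bp",
               "project_status", "has_methylome")]
}

#' Rank names of a manifest
#' @param manifest a strain manifest data.frame
#' @return character vector of rank column names, most inclusive first
#' @export
manifest_ranks <- function(manifest) {
  known <- c("phylum", "class", "order", "family", "genus", "species")
  known[known %in% names(manifest)]
}
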