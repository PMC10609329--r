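#' Fractional identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment under BLOSUM62 with gap open 11 and
#' gap extend 1, the standard protein scoring used by BLAST. Identity is the
#' number of identical aligned residue pairs divided by the total number of
#' alignment columns, gap columns included — a symmetric definition, so
#' `pairwise_identity(a, b) == pairwise_identity(b, a)`.
#'
#' @param a,b protein sequences (character or [Biostrings::AAString])
#' @return fraction in `[0, 1]`
#' @export
pairwise_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Greedy centroid clustering at a fractional-identity threshold
#'
#' Reproduces the semantics of length-sorted greedy centroid clustering (the
#' cluster_fast strategy): sequences are processed in decreasing length
#' order, ties broken by id; each sequence joins the first existing centroid
#' (in centroid creation order) whose identity to it meets the threshold,
#' otherwise it founds a new cluster with itself as centroid. Every member
#' therefore has identity >= threshold to its centroid, and the clusters
#' partition the input. Exact pairwise alignment is used throughout rather
#' than heuristic seeding, so results are deterministic and oracle-checkable.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet] of
#'   protein sequences (names are gene ids)
#' @param threshold identity threshold in `(0, 1]` (default 0.30)
#' @return data.frame with columns `gene_id`, `cluster_id` (integer, in
#'   centroid creation order), `is_centroid`
#' @export
greedy_cluster <- function(seqs, threshold = 0.30) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  seqs <- setNames(as.character(seqs), names(seqs))
  if (!length(seqs))
    return(data.frame(gene_id = character(0), cluster_id = integer(0),
                      is_centroid = logical(0)))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names (gene ids)")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroid_ids <- character(0)
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(centroid_ids)) {
      if (pairwise_identity(seqs[[i]], seqs[[centroid_ids[ci]]]) >= threshold) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_ids <- c(centroid_ids, names(seqs)[i])
      assignment[i] <- length(centroid_ids)
    }
  }
  data.frame(gene_id = names(seqs),
             cluster_id = assignment,
             is_centroid = names(seqs) %in% centroid_ids,
             stringsAsFactors = FALSE)
}

#' Summary statistics for a clustering
#'
#' @param clusters data.frame from [greedy_cluster()] (needs `cluster_id`)
#' @param big minimum size counted as a large cluster (default 10)
#' @return list with `n_clusters`, `max_size`, `n_big` (size >= `big`),
#'   `n_singletons`
#' @export
cluster_stats <- function(clusters, big = 10L) {
  if (!nrow(clusters))
    return(list(n_clusters = 0L, max_size = 0L, n_big = 0L, n_singletons = 0L))
  sizes <- as.integer(table(clusters$cluster_id))
  list(n_clusters = length(sizes),
       max_size = max(sizes),
       n_big = sum(sizes >= big),
       n_singletons = sum(sizes == 1L))
}
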