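#' Build a position-specific profile model from a training alignment
#'
#' Match columns are the alignment columns with at most 50% gap characters.
#' Per-column emission scores are log2 odds of the observed residue
#' frequencies (with a +1 pseudocount over the 20-letter alphabet) against a
#' uniform background, so an uninformative column scores 0 for every
#' residue and a perfectly conserved column scores its residue near
#' log2(n + 1) - log2((n + 20) / 20).
#'
#' @param msa [Biostrings::AAStringSet] (or named character vector) of >= 2
#'   aligned sequences of equal length; `-` and `.` are gap characters
#' @param name profile name
#' @param category one of the 13 RM functional categories
#' @param meth_type `"m6A"`, `"m4C"`, `"m5C"` or `"none"`
#' @param max_gap_frac maximum gap fraction for a match column (default 0.5)
#' @return object of class `profile_model`: emission matrix (`match columns
#'   x 20 residues`, bits), match column indices, background frequencies
#' @export
build_profile <- function(msa, name, category, meth_type = "none",
                          max_gap_frac = 0.5) {
  seqs <- as.character(msa)
  if (length(seqs) < 2L)
    stop("a profile needs >= 2 aligned sequences; align more family members")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequences have unequal column counts")
  if (!category %in% RM_CATEGORIES) stop("unknown category: ", category)
  if (!meth_type %in% c(METH_TYPES, "none")) stop("unknown meth_type: ", meth_type)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  is_gap <- mat == "-" | mat == "."
  match_cols <- which(colMeans(is_gap) <= max_gap_frac)
  if (!length(match_cols)) stop("alignment has no match columns")
  n <- length(seqs)
  bg <- rep(1 / 20, 20)
  emission <- t(vapply(match_cols, function(j) {
    counts <- table(factor(mat[!is_gap[, j], j], levels = AA_ALPHABET20))
    freq <- (as.numeric(counts) + 1) / (sum(counts) + 20)
    log2(freq / bg)
  }, numeric(20)))
  colnames(emission) <- AA_ALPHABET20
  structure(list(name = name, category = category, meth_type = meth_type,
                 emission = emission, match_cols = match_cols,
                 background = setNames(bg, AA_ALPHABET20),
                 length = length(match_cols)),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model>", x$name, "-", x$category,
      if (x$meth_type != "none") paste0("(", x$meth_type, ")") else "",
      "-", x$length, "match columns\n")
  invisible(x)
}

# per-placement window scores of a profile along a sequence: score(o) is the
# sum of emission log-odds of the profile's W match columns aligned ungapped
# to sequence positions o..o+W-1. Full-overlap placements only; a sequence
# shorter than the profile has no valid placement (score -Inf).
profile_window_scores <- function(profile, seq) {
  s <- match(strsplit(toupper(as.character(seq)), "")[[1]], AA_ALPHABET20)
  L <- length(s)
  W <- profile$length
  if (L < 1) stop("sequence must be non-empty")
  if (L < W) return(numeric(0))
  n_off <- L - W + 1L
  # residues outside the 20-letter alphabet (X etc.) emit the background: 0 bits
  idx_pos <- outer(seq_len(W), seq_len(n_off) - 1L, `+`)
  res <- s[idx_pos]
  vals <- profile$emission[cbind(rep(seq_len(W), n_off), res)]
  vals[is.na(vals)] <- 0
  colSums(matrix(vals, nrow = W))
}

#' Score a protein sequence against a profile model
#'
#' Best-window ungapped score: the maximum over all full-overlap placements
#' of the profile's match columns on the sequence of the summed per-column
#' emission log-odds, in bits. `-Inf` if the sequence is shorter than the
#' profile (no valid placement).
#'
#' @param profile a [build_profile()] model
#' @param seq protein sequence
#' @return score in bits
#' @export
score_profile <- function(profile, seq) {
  sc <- profile_window_scores(profile, seq)
  if (!length(sc)) -Inf else max(sc)
}

#' Classify a gene by top profile hit
#'
#' Scores the sequence against every profile in the library and takes the
#' functional category and methylation type of the best hit; exact score
#' ties are broken by profile name (lexicographic). Scores below the bit
#' threshold are called `"Other"` with methylation type `"none"` and the
#' below-threshold flag set.
#'
#' @param seq protein sequence
#' @param library list of [build_profile()] models
#' @param threshold bit-score call threshold (see [calibrate_threshold()])
#' @return one-row data.frame: `profile`, `score`, `category`, `meth_type`,
#'   `margin` (bits over the runner-up), `below_threshold`
#' @export
classify_gene <- function(seq, library, threshold = 20) {
  if (!length(library)) stop("profile library is empty")
  nm <- vapply(library, `[[`, "", "name")
  scores <- vapply(library, score_profile, 0, seq = seq)
  ord <- order(-scores, nm)
  best <- library[[ord[1L]]]
  runner <- if (length(scores) > 1L) scores[ord[2L]] else -Inf
  below <- scores[ord[1L]] < threshold
  data.frame(profile = best$name,
             score = scores[ord[1L]],
             category = if (below) "Other" else best$category,
             meth_type = if (below) "none" else best$meth_type,
             margin = if (is.finite(runner)) scores[ord[1L]] - runner else Inf,
             below_threshold = below,
             stringsAsFactors = FALSE)
}

#' Classify many genes, optionally via cluster centroids
#'
#' When a clustering is supplied, only the centroid of each cluster is
#' scored against the library and the call is propagated to all members —
#' the standard shortcut for homogeneous clusters.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet]
#' @param library list of profile models
#' @param threshold bit-score threshold
#' @param clusters optional data.frame from [greedy_cluster()]
#' @return data.frame with one row per gene: `gene_id` plus the
#'   [classify_gene()] columns
#' @export
classify_genes <- function(seqs, library, threshold = 20, clusters = NULL) {
  seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(clusters)) {
    calls <- lapply(seqs, classify_gene, library = library, threshold = threshold)
    out <- do.call(rbind, calls)
    out <- cbind(gene_id = names(seqs), out)
  } else {
    cent <- clusters[clusters$is_centroid, , drop = FALSE]
    calls <- lapply(cent$gene_id, function(g)
      classify_gene(seqs[[g]], library, threshold))
    cent_calls <- do.call(rbind, calls)
    cent_calls$cluster_id <- cent$cluster_id
    idx <- match(clusters$cluster_id, cent_calls$cluster_id)
    out <- cbind(gene_id = clusters$gene_id,
                 cent_calls[idx, setdiff(names(cent_calls), "cluster_id")])
  }
  rownames(out) <- NULL
  out
}

#' Calibrate the classification bit threshold on a random-sequence null
#'
#' Scores `n` uniform-random protein sequences against the whole library and
#' returns the 99.9th percentile of their best-hit scores, a data-driven
#' floor below which a top hit is indistinguishable from chance.
#'
#' @param library list of profile models
#' @param n number of null sequences (default 1000)
#' @param length_range range of null sequence lengths
#' @param seed integer seed
#' @param quantile null quantile to return (default 0.999)
#' @return bit threshold
#' @export
calibrate_threshold <- function(library, n = 1000L, length_range = c(150L, 400L),
                                seed = 1L, quantile = 0.999) {
  with_seed(seed, {
    best <- vapply(seq_len(n), function(i) {
      L <- sample(length_range[1]:length_range[2], 1L)
      s <- paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
      max(vapply(library, score_profile, 0, seq = s))
    }, 0)
    as.numeric(stats::quantile(best, quantile))
  })
}

#' Methylation type configured for a profile name
#'
#' Looks the name up in the library. The default library bakes in the
#' standard overrides for families whose training sets mix characterized
#' m6A and m4C examples: `b1a`, `lmoa118-like` and `nru-like` are treated as
#' m6A and `b3` as m4C. Profiles of non-MTase categories return `"none"`.
#'
#' @param name profile name
#' @param library list of profile models
#' @return `"m6A"`, `"m4C"`, `"m5C"` or `"none"`
#' @export
assign_meth_type <- function(name, library) {
  nm <- vapply(library, `[[`, "", "name")
  i <- match(name, nm)
  if (is.na(i)) stop("unknown profile name: ", name)
  library[[i]]$meth_type
}

#' Detect multiple profile domains in one sequence
#'
#' Reports all non-overlapping profile windows scoring at or above the
#' threshold, selected greedily by descending score (ties: profile name,
#' then leftmost window). A gene carrying two disjoint MTase-category hits —
#' typically a fusion of two MTase domains — is flagged `fused`.
#'
#' @param seq protein sequence
#' @param library list of profile models
#' @param threshold bit-score threshold
#' @return list with `hits` (data.frame: `profile`, `category`, `start`,
#'   `end`, `score`) and `fused` (logical)
#' @export
detect_fused_domains <- function(seq, library, threshold = 20) {
  cand <- list()
  for (p in library) {
    sc <- profile_window_scores(p, seq)
    keep <- which(sc >= threshold)
    if (length(keep))
      cand[[length(cand) + 1L]] <- data.frame(
        profile = p$name, category = p$category,
        start = keep, end = keep + p$length - 1L, score = sc[keep],
        stringsAsFactors = FALSE)
  }
  empty <- data.frame(profile = character(0), category = character(0),
                      start = integer(0), end = integer(0), score = numeric(0))
  if (!length(cand)) return(list(hits = empty, fused = FALSE))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$profile, cand$start), , drop = FALSE]
  chosen <- empty
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, , drop = FALSE]
    overlaps <- nrow(chosen) &&
      any(row$start <= chosen$end & row$end >= chosen$start)
    if (!overlaps) chosen <- rbind(chosen, row)
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  fused <- sum(chosen$category %in% MTASE_CATEGORIES) >= 2L
  list(hits = chosen, fused = fused)
}

#' Build the default synthetic profile library
#'
#' A compact stand-in for a curated RM profile library, generated from
#' synthetic training families: one or more profiles per functional
#' category, each built from an alignment of sequences diverged from a
#' common ancestor. Includes the classically ambiguous MTase families with
#' their conventional methylation-type assignments (`b1a`, `lmoa118-like`,
#' `nru-like` as m6A; `b3` as m4C). Entirely synthetic: profile ancestors
#' are random, so the library is for pipeline testing, not for classifying
#' real proteins.
#'
#' @param seed integer seed
#' @param n_train training sequences per profile (default 8)
#' @param divergence training divergence from the family ancestor
#' @return named list of `profile_model`s
#' @export
default_profile_library <- function(seed = 42L, n_train = 8L, divergence = 0.15) {
  defs <- list(
    list("im-alpha",      "IM",   "m6A"),
    list("ir-alpha",      "IR",   "none"),
    list("is-alpha",      "IS",   "none"),
    list("b1a",           "IIM",  "m6A"),
    list("lmoa118-like",  "IIM",  "m6A"),
    list("nru-like",      "IIM",  "m6A"),
    list("b3",            "IIM",  "m4C"),
    list("dcm-like",      "IIM",  "m5C"),
    list("iir-dpnii",     "IIR",  "none"),
    list("iig-eco57i",    "IIG",  "m6A"),
    list("iiim-mod",      "IIIM", "m6A"),
    list("iiir-res",      "IIIR", "none"),
    list("iv-mrr",        "IV",   "none"),
    list("brex-pglx",     "M",    "m6A"),
    list("c-protein",     "C",    "none"),
    list("vsr",           "V",    "none")
  )
  lib <- lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    fs <- family_spec(d[[1]], mode = "sporadic", category = d[[2]],
                      meth_type = d[[3]], ancestor_length = 250L,
                      divergence = divergence)
    msa <- emit_family_sequences(fs, n_train, seed = seed + i)$aligned
    build_profile(msa, name = d[[1]], category = d[[2]], meth_type = d[[3]])
  })
  setNames(lib, vapply(lib, `[[`, "", "name"))
}
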