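# one-sided Fisher's exact p-value for elevated read1 C>T, vectorized.
# For the 2x2 table {r1_t, r1_c; r2_t, r2_c} the one-sided exact test is
# the hypergeometric tail P(X >= r1_t) with margins fixed, identical to
# fisher.test(alternative = "greater") and fast enough to run per position.
.fisher_greater <- function(r1_t, r1_c, r2_t, r2_c) {
  phyper(r1_t - 1, r1_t + r2_t, r1_c + r2_c, r1_t + r1_c, lower.tail = FALSE)
}

#' Call m5C positions from paired-read deamination counts
#'
#' At every cytosine position with at least `min_coverage` reads in both
#' read1 and read2, tests whether the read1 C>T rate exceeds the read2 rate
#' (one-sided Fisher's exact test on the 2x2 count table), then controls the
#' Benjamini-Hochberg false discovery rate across positions. m5C positions
#' are preferentially deaminated in read1, so they stand out against the
#' shared background deamination rate visible in read2.
#'
#' The read2 reference arm of the 2x2 table is, by default, the read2
#' counts pooled across all eligible positions: read2 never sees the
#' methylation-dependent deamination boost, so the whole genome's read2
#' counts estimate the shared background rate with high precision, giving
#' the test per-position power that a single position's read2 counts cannot
#' (at 100x coverage a local 10-vs-0 table is barely significant, while
#' 10-of-100 against a pooled 0.5% background is decisive).
#' `background = "local"` uses each position's own read2 counts instead.
#'
#' @param table deamination table (`pos`, `strand`, `r1_c`, `r1_t`, `r2_c`,
#'   `r2_t`), e.g. from [emit_rims_counts()]
#' @param min_coverage minimum read1 and read2 coverage (default 10)
#' @param fdr BH false discovery rate level (default 0.05)
#' @param background `"pooled"` (read2 pooled genome-wide, the default) or
#'   `"local"` (per-position read2)
#' @return data.frame of significant positions, sorted by `pos` then
#'   `strand`: `pos`, `strand`, `r1_rate`, `r2_rate`, `p`, `q`
#' @export
call_m5c_sites <- function(table, min_coverage = 10L, fdr = 0.05,
                           background = c("pooled", "local")) {
  background <- match.arg(background)
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  cov1 <- table$r1_c + table$r1_t
  cov2 <- table$r2_c + table$r2_t
  zero <- cov1 + cov2 == 0
  if (any(zero))
    message(sum(zero), " position(s) with zero total coverage skipped")
  eligible <- cov1 >= min_coverage & cov2 >= min_coverage
  tab <- table[eligible, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(pos = integer(0), strand = character(0),
                      r1_rate = numeric(0), r2_rate = numeric(0),
                      p = numeric(0), q = numeric(0)))
  p <- if (background == "pooled") {
    .fisher_greater(tab$r1_t, tab$r1_c, sum(tab$r2_t), sum(tab$r2_c))
  } else {
    .fisher_greater(tab$r1_t, tab$r1_c, tab$r2_t, tab$r2_c)
  }
  q <- p.adjust(p, method = "BH")
  sig <- q <= fdr
  out <- data.frame(pos = tab$pos[sig], strand = tab$strand[sig],
                    r1_rate = (tab$r1_t / (tab$r1_t + tab$r1_c))[sig],
                    r2_rate = (tab$r2_t / (tab$r2_t + tab$r2_c))[sig],
                    p = p[sig], q = q[sig])
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# context k-mer on the site's own strand with the site C at 0-based offset
# `o`: top-strand window is [pos-o, pos-o+k-1] for "+" sites and the reverse
# complement of [pos-(k-1-o), pos+o] for "-" sites. NA outside the genome.
.site_contexts <- function(sites, genome, k, o) {
  L <- nchar(genome)
  start <- ifelse(sites$strand == "+", sites$pos - o, sites$pos - (k - 1L - o))
  ok <- start >= 1L & start + k - 1L <= L
  ctx <- rep(NA_character_, nrow(sites))
  ctx[ok] <- substring(genome, start[ok], start[ok] + k - 1L)
  flip <- ok & sites$strand == "-"
  ctx[flip] <- vapply(ctx[flip], revcomp, "")
  ctx
}

# genome-wide k-mer counts over both strands (named integer vector)
.genome_kmer_counts <- function(genome, k) {
  dna <- Biostrings::DNAStringSet(c(genome, revcomp(genome)))
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
  colSums(counts)
}

# IUPAC motif as list of base sets -> string
.sets_to_motif <- function(sets) paste(vapply(sets, .iupac_code_for, ""), collapse = "")

.motif_ic <- function(motif) {
  sum(vapply(iupac_sets(motif), function(b) 2 - log2(length(b)), 0))
}

#' Consolidate significant k-mers into degenerate IUPAC motifs
#'
#' Iteratively merges pairs of same-length, same-offset motifs that differ
#' at exactly one position and have comparable support (within
#' `max_support_ratio`) into a single motif degenerate at that position
#' (e.g. CCAGG + CCTGG becomes CCWGG), until no pair merges. Fully
#' degenerate (N) leading or trailing positions are then trimmed, with the
#' methylated offset adjusted. Consolidating an already-degenerate set is a
#' no-op.
#'
#' @param motifs data.frame with `motif`, `offset` (0-based index of the
#'   methylated C), `support`
#' @param max_support_ratio largest support ratio for a merge (default 5)
#' @return data.frame with the same columns, consolidated
#' @export
consolidate_motifs <- function(motifs, max_support_ratio = 5) {
  if (!nrow(motifs)) return(motifs)
  motifs <- motifs[order(-motifs$support, motifs$motif), , drop = FALSE]
  # 4-bit base-set masks (A=1, C=2, G=4, T=8) make the hamming-1 scan and
  # the degenerate union cheap enough for hundreds of candidate k-mers
  base_mask <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  to_mask <- function(m) vapply(iupac_sets(m), function(b)
    Reduce(bitwOr, base_mask[b]), 0L)
  mask_to_motif <- function(mask) {
    paste(vapply(mask, function(v) {
      .iupac_code_for(names(base_mask)[bitwAnd(v, base_mask) > 0L])
    }, ""), collapse = "")
  }
  groups <- split(seq_len(nrow(motifs)),
                  paste(nchar(motifs$motif), motifs$offset))
  out <- list()
  for (ix in groups) {
    masks <- lapply(motifs$motif[ix], to_mask)
    support <- motifs$support[ix]
    offset <- motifs$offset[ix][1]
    alive <- rep(TRUE, length(ix))
    repeat {
      merged <- FALSE
      live <- which(alive)
      for (i in live) {
        if (!alive[i]) next
        for (j in live[live > i]) {
          if (!alive[j]) next
          diff <- which(masks[[i]] != masks[[j]])
          if (length(diff) != 1L || diff == offset + 1L) next
          ratio <- max(support[i], support[j]) / max(1, min(support[i], support[j]))
          if (ratio > max_support_ratio) next
          masks[[i]][diff] <- bitwOr(masks[[i]][diff], masks[[j]][diff])
          support[i] <- support[i] + support[j]
          alive[j] <- FALSE
          merged <- TRUE
        }
      }
      if (!merged) break
    }
    keep <- which(alive)
    out[[length(out) + 1L]] <- data.frame(
      motif = vapply(masks[keep], mask_to_motif, ""),
      offset = offset, support = support[keep], stringsAsFactors = FALSE)
  }
  motifs <- do.call(rbind, out)
  motifs <- motifs[order(-motifs$support, motifs$motif), , drop = FALSE]
  # trim fully-degenerate ends, adjusting the offset into the motif
  for (i in seq_len(nrow(motifs))) {
    chars <- strsplit(motifs$motif[i], "")[[1]]
    first <- which(chars != "N")[1]
    last <- max(which(chars != "N"))
    motifs$motif[i] <- paste(chars[first:last], collapse = "")
    motifs$offset[i] <- motifs$offset[i] - (first - 1L)
  }
  # de-duplicate identical (motif, offset), summing support is wrong here —
  # duplicates arise from trimming contexts of the same sites, so keep max
  key <- paste(motifs$motif, motifs$offset)
  agg <- tapply(motifs$support, key, max)
  motifs <- motifs[!duplicated(key), , drop = FALSE]
  motifs$support <- as.integer(agg[paste(motifs$motif, motifs$offset)])
  rownames(motifs) <- NULL
  motifs
}

# sites (pos, strand) matching an IUPAC motif with its C at `offset`;
# returns number of matching sites and, for palindromes, duplex-unique support
.motif_site_support <- function(motif, offset, sites, genome) {
  k <- nchar(motif)
  ctx <- .site_contexts(sites, genome, k, offset)
  sets <- iupac_sets(motif)
  m <- !is.na(ctx) & vapply(ctx, function(x) {
    ch <- strsplit(x, "")[[1]]
    all(mapply(`%in%`, ch, sets))
  }, NA)
  matched <- sites[m, , drop = FALSE]
  if (is_palindrome(motif)) {
    inst <- ifelse(matched$strand == "+", matched$pos - offset,
                   matched$pos - (k - 1L - offset))
    support <- length(unique(inst))
  } else {
    support <- nrow(matched)
  }
  list(n_sites = sum(m), support = support, matched = which(m))
}

#' Discover recognition motifs around called m5C sites
#'
#' Exhaustive k-mer over-representation scan: for every k in `k_range` and
#' every alignment offset placing a C of the k-mer on a called site, counts
#' how many called sites carry each context k-mer (on the site's own
#' strand) and tests that count against the genome-wide frequency of the
#' k-mer among all cytosines (one-sided binomial, BH-controlled across all
#' tested k-mers). Significant k-mers are consolidated into degenerate
#' IUPAC motifs, and near-redundant motifs — those whose site sets are
#' almost entirely covered by a stronger motif — are dropped. Motifs are
#' ranked by support times information content, so the maximally specific
#' motif explaining the full site set ranks first.
#'
#' @param sites called positions from [call_m5c_sites()]
#' @param genome genome character string
#' @param k_range k-mer lengths to scan (default 3:8)
#' @param fdr BH level for k-mer enrichment (default 0.05)
#' @param min_sites minimum called sites carrying a k-mer for it to be
#'   tested (default 3)
#' @param max_support_ratio merge tolerance passed to [consolidate_motifs()]
#' @param redundancy_overlap fraction of a motif's sites that must be
#'   covered by a stronger motif for it to be dropped as redundant
#'   (default 0.8)
#' @return data.frame of motif calls sorted by rank: `motif`, `offset`
#'   (0-based methylated C), `support` (duplex-unique for palindromes),
#'   `n_sites`, `fold_enrichment`, `p`, `q`
#' @export
find_motifs <- function(sites, genome, k_range = 3:8, fdr = 0.05,
                        min_sites = 3L, max_support_ratio = 5,
                        redundancy_overlap = 0.8) {
  if (!nzchar(genome)) stop("empty genome")
  if (!nrow(sites))
    return(data.frame(motif = character(0), offset = integer(0),
                      support = integer(0), n_sites = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      q = numeric(0)))
  n_c <- sum(.genome_kmer_counts(genome, 1L)[c("C")])  # Cs on both strands
  tests <- list()
  # the multiple-testing family is every C-anchored k-mer present in the
  # genome, not just those observed at called sites: testing only k-mers
  # that already look enriched and correcting over that subset would be a
  # selection bias (the unobserved k-mers were candidates too)
  gcounts_by_k <- lapply(setNames(k_range, k_range), function(k)
    .genome_kmer_counts(genome, k))
  m_total <- 0L
  for (k in k_range) {
    present <- names(gcounts_by_k[[as.character(k)]])[gcounts_by_k[[as.character(k)]] > 0]
    for (o in 0:(k - 1L))
      m_total <- m_total + sum(substr(present, o + 1L, o + 1L) == "C")
  }
  for (k in k_range) {
    gcounts <- gcounts_by_k[[as.character(k)]]
    for (o in 0:(k - 1L)) {
      ctx <- .site_contexts(sites, genome, k, o)
      tab <- table(ctx[!is.na(ctx)])
      tab <- tab[vapply(names(tab), function(x) substr(x, o + 1L, o + 1L) == "C",
                        NA)]
      tab <- tab[tab >= min_sites]
      if (!length(tab)) next
      p0 <- pmin(1, as.numeric(gcounts[names(tab)]) / n_c)
      tests[[length(tests) + 1L]] <- data.frame(
        motif = names(tab), offset = o, k = k,
        n_sites = as.integer(tab),
        expected = p0 * nrow(sites),
        p = pbinom(as.integer(tab) - 1L, nrow(sites), p0, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(tests)) return(find_motifs(sites[0, , drop = FALSE], genome))
  tests <- do.call(rbind, tests)
  tests$q <- p.adjust(tests$p, method = "BH", n = max(m_total, nrow(tests)))
  sig <- tests[tests$q <= fdr & tests$n_sites > tests$expected, , drop = FALSE]
  if (!nrow(sig)) return(find_motifs(sites[0, , drop = FALSE], genome))
  cons <- list()
  for (k in unique(sig$k)) {
    sk <- sig[sig$k == k, c("motif", "offset", "n_sites"), drop = FALSE]
    names(sk)[3] <- "support"
    cons[[as.character(k)]] <- consolidate_motifs(sk, max_support_ratio)
  }
  cons <- do.call(rbind, cons)
  # recompute support/site sets for the consolidated motifs
  info <- lapply(seq_len(nrow(cons)), function(i)
    .motif_site_support(cons$motif[i], cons$offset[i], sites, genome))
  matched_sets <- setNames(lapply(info, `[[`, "matched"),
                           paste(cons$motif, cons$offset))
  cons$n_sites <- vapply(info, `[[`, 0L, "n_sites")
  cons$support <- vapply(info, `[[`, 0L, "support")
  cons$score <- cons$n_sites * vapply(cons$motif, .motif_ic, 0)
  # enrichment stats against the genome-wide motif frequency among Cs
  cons$p <- NA_real_; cons$fold_enrichment <- NA_real_
  for (i in seq_len(nrow(cons))) {
    k <- nchar(cons$motif[i])
    gcounts <- gcounts_by_k[[as.character(k)]] %||% .genome_kmer_counts(genome, k)
    km <- expand.grid(iupac_sets(cons$motif[i]), stringsAsFactors = FALSE)
    plain <- apply(km, 1, paste, collapse = "")
    p0 <- pmin(1, sum(gcounts[intersect(plain, names(gcounts))]) / n_c)
    cons$p[i] <- pbinom(cons$n_sites[i] - 1L, nrow(sites), p0,
                        lower.tail = FALSE)
    cons$fold_enrichment[i] <- (cons$n_sites[i] / nrow(sites)) / max(p0, 1e-12)
  }
  cons$q <- p.adjust(cons$p, method = "BH")
  cons <- cons[order(-cons$score, cons$motif), , drop = FALSE]
  # redundancy filter: drop motifs whose sites are covered by a kept motif
  kept <- integer(0)
  covered <- list()
  for (i in seq_len(nrow(cons))) {
    site_set <- matched_sets[[paste(cons$motif[i], cons$offset[i])]]
    redundant <- any(vapply(covered, function(cs)
      length(intersect(site_set, cs)) >= redundancy_overlap * length(site_set),
      NA))
    if (!isTRUE(redundant)) {
      kept <- c(kept, i)
      covered[[length(covered) + 1L]] <- site_set
    }
  }
  out <- cons[kept, c("motif", "offset", "support", "n_sites",
                      "fold_enrichment", "p", "q"), drop = FALSE]
  rownames(out) <- NULL
  out
}
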