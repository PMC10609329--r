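#' Generate a random genome sequence
#' @param length_bp genome length in bp
#' @param seed integer seed
#' @param gc GC fraction (default 0.5)
#' @return character string over ACGT
#' @export
random_genome <- function(length_bp, seed = 1L, gc = 0.5) {
  stopifnot_scalar_prob(gc, "gc")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
  })
}

# methylated C positions (1-based top-strand coordinate) for an IUPAC motif:
# per duplex instance, the C at `offset` (0-based into the motif) on the
# instance's own strand. Palindromic motifs match identically on both
# strands, so each duplex instance yields one "+" and one "-" position.
.methylated_positions <- function(genome, motif, offset) {
  k <- nchar(motif)
  sets <- iupac_sets(motif)
  if (!identical(sets[[offset + 1L]], "C"))
    stop("methylated offset does not address a C in the motif")
  fwd <- match_iupac(genome, motif)
  plus <- data.frame(instance = fwd, pos = fwd + offset, strand = "+")
  if (is_palindrome(motif)) {
    minus <- data.frame(instance = fwd, pos = fwd + (k - 1L - offset),
                        strand = "-")
    rbind(plus, minus)
  } else {
    rev <- match_iupac(genome, revcomp(motif))
    minus <- data.frame(instance = rev, pos = rev + (k - 1L - offset),
                        strand = "-")
    rbind(plus, minus)
  }
}

#' Simulate RIMS-seq-style per-cytosine deamination counts
#'
#' Emulates the read-level signature used for m5C calling: partial enzymatic
#' deamination converts C to U preferentially when the C is methylated, so
#' read1 of a pair shows an elevated C>T rate at m5C positions while read2
#' stays at the background deamination rate. Every C on each strand receives
#' binomial read1/read2 C>T counts at the background rate, except read1 at
#' methylated motif instances, which uses `m5c_rate`. Methylation is sampled
#' per duplex motif instance at `methylation_fraction`, so both strands of a
#' palindromic site are methylated together.
#'
#' @param genome_length genome length in bp (a random genome is drawn), or
#'   pass `genome` directly
#' @param motif IUPAC recognition motif of the planted MTase
#' @param methylated_offset 0-based offset of the methylated C in the motif
#' @param methylation_fraction fraction of duplex motif instances methylated
#' @param background_rate background C>T deamination rate (both reads)
#' @param m5c_rate read1 C>T rate at methylated positions; must exceed the
#'   background for a detectable signal
#' @param coverage reads per strand covering each position
#' @param seed integer seed
#' @param genome optional explicit genome string (overrides `genome_length`)
#' @return list with `genome` (character) and `table`: a data.frame with one
#'   row per C position per strand — `pos` (1-based, top strand), `strand`,
#'   `r1_c`, `r1_t`, `r2_c`, `r2_t` — plus a logical `methylated` ground
#'   truth column
#' @export
emit_rims_counts <- function(genome_length = NULL, motif, methylated_offset,
                             methylation_fraction = 1, background_rate = 0.005,
                             m5c_rate = 0.1, coverage = 100L, seed = 1L,
                             genome = NULL) {
  stopifnot_scalar_prob(methylation_fraction, "methylation_fraction")
  stopifnot_scalar_prob(background_rate, "background_rate")
  stopifnot_scalar_prob(m5c_rate, "m5c_rate")
  if (coverage < 0) stop("coverage must be >= 0")
  if (methylation_fraction > 0 && m5c_rate <= background_rate)
    stop("m5c_rate must exceed background_rate for a detectable signal")
  with_seed(seed, {
    if (is.null(genome)) genome <- random_genome(genome_length, seed = NULL)
    bases <- strsplit(genome, "")[[1]]
    cpos <- data.frame(pos = c(which(bases == "C"), which(bases == "G")),
                       strand = rep(c("+", "-"),
                                    c(sum(bases == "C"), sum(bases == "G"))))
    meth <- .methylated_positions(genome, motif, methylated_offset)
    inst <- unique(meth$instance)
    meth_inst <- inst[runif(length(inst)) < methylation_fraction]
    meth <- meth[meth$instance %in% meth_inst, , drop = FALSE]
    key <- function(d) paste(d$pos, d$strand)
    cpos$methylated <- key(cpos) %in% key(meth)
    n <- nrow(cpos)
    r1_rate <- ifelse(cpos$methylated, m5c_rate, background_rate)
    cpos$r1_t <- rbinom(n, coverage, r1_rate)
    cpos$r1_c <- coverage - cpos$r1_t
    cpos$r2_t <- rbinom(n, coverage, background_rate)
    cpos$r2_c <- coverage - cpos$r2_t
    cpos <- cpos[order(cpos$pos, cpos$strand),
                 c("pos", "strand", "r1_c", "r1_t", "r2_c", "r2_t", "methylated")]
    rownames(cpos) <- NULL
    list(genome = genome, table = cpos)
  })
}
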