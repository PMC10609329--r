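#' @importFrom stats p.adjust pbinom phyper rbinom runif setNames weighted.mean
#' @importFrom utils head read.delim write.table
NULL

# 20 standard amino acids, fixed order used throughout profile emission tables
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# The 13 functional categories used for RM-gene classification: Type I
# methyltransferase/REase/specificity subunits, Type II MTase/REase, fused
# Type IIG, Type III Mod/Res, methyl-directed Type IV REases, BREX-associated
# MTases (M), control proteins (C), Vsr nucleases (V), and a catch-all Other.
RM_CATEGORIES <- c("IM", "IR", "IS", "IIM", "IIR", "IIG",
                   "IIIM", "IIIR", "IV", "M", "C", "V", "Other")

# Categories whose gene products are DNA MTase domains (can carry a
# methylation type and contribute motifs to a methylome)
MTASE_CATEGORIES <- c("IM", "IIM", "IIG", "IIIM", "M")

METH_TYPES <- c("m6A", "m4C", "m5C")

# IUPAC degenerate nucleotide alphabet as base sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# inverse lookup: sorted base set -> IUPAC code
.iupac_code_for <- local({
  tab <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    code <- names(tab)[match(key, tab)]
    if (is.na(code)) stop("no IUPAC code for base set: ", key)
    code
  }
})

#' Expand an IUPAC motif into per-position base sets
#' @param motif IUPAC string, e.g. "CCWGG"
#' @return list of character vectors, one per position
#' @keywords internal
iupac_sets <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "))
  lapply(chars, function(ch) IUPAC_SETS[[ch]])
}

#' Reverse complement of an IUPAC motif or plain DNA string
#' @param x character string over the IUPAC alphabet
#' @return character string
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  chars <- rev(strsplit(toupper(x), "")[[1]])
  paste(comp[chars], collapse = "")
}

#' Is a motif its own reverse complement?
#' @param motif IUPAC string
#' @return logical
#' @export
is_palindrome <- function(motif) identical(toupper(motif), revcomp(motif))

#' Locate IUPAC motif matches on the top strand of a genome string
#' @param genome character string over ACGT
#' @param motif IUPAC string
#' @return integer vector of 1-based match start positions
#' @keywords internal
match_iupac <- function(genome, motif) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(motif)),
                                   Biostrings::DNAString(genome),
                                   fixed = FALSE)
  Biostrings::start(hits)
}

# run `code` with a locally scoped RNG seed (NULL leaves RNG state alone)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single number in [0, 1]")
  invisible(x)
}
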