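#' Shipped reference census tables
#'
#' The package ships three small reference tables summarizing a survey of
#' RM systems across the 519 completely sequenced archaeal genomes in the
#' REBASE restriction-enzyme database: the per-taxon functional-category
#' census (`"rm_census"`: mean genes per genome for the 13 categories), the
#' methylation-type census (`"meth_census"`: mean MTase genes and observed
#' SMRT methylome motifs per genome by methylated base), and the persistent
#' RM systems table (`"persistent_systems"`: homologous groups meeting, or
#' nearly meeting, the 75%/5-genome persistence rule, with taxon sizes,
#' member counts, system class and motif). Taxon ranks follow the survey's
#' convention (phylum / class / order plus lower ranks where named); the
#' `TOTAL` row spans all genomes.
#'
#' @param which `"rm_census"`, `"meth_census"` or `"persistent_systems"`
#' @return data.frame
#' @export
read_survey_table <- function(which = c("rm_census", "meth_census",
                                        "persistent_systems")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("archaea_", which, ".tsv"),
                   package = "rmcensus", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a strain manifest, gene table or census to TSV
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a deamination count table written by [write_tsv()]
#' @param path TSV with columns pos, strand, r1_c, r1_t, r2_c, r2_t
#' @return data.frame
#' @export
read_deamination_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("pos", "strand", "r1_c", "r1_t", "r2_c", "r2_t")
  if (!all(needed %in% names(tab)))
    stop("deamination table needs columns: ", paste(needed, collapse = ", "))
  tab
}
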