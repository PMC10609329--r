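#' Derive an observed methylome from planted MTase genes
#'
#' Each planted gene of an MTase family contributes its family's true
#' recognition motif to its strain's observed-motif list, unless silenced.
#' Silencing emulates inactive genes; the m5C detection rate emulates the
#' poor sensitivity of kinetics-based methylome calling for m5C marks, which
#' is why real gene/motif reconciliations expect genes >= motifs.
#'
#' @param gene_table gene table from [plant_families()]
#' @param truth ground truth from [plant_families()]
#' @param silencing_rate probability that an MTase gene contributes no motif
#' @param m5c_detection_rate probability that an m5C motif, if expressed, is
#'   actually observed
#' @param seed integer seed
#' @param extra_motifs optional data.frame (`strain_id`, `motif`, `type`,
#'   `methylated_offset`) of motifs injected with no gene behind them — the
#'   "missing plasmid" scenario in which observed motifs outnumber genes
#' @return data.frame with columns `strain_id`, `motif`, `type`,
#'   `methylated_offset`
#' @export
emit_methylome <- function(gene_table, truth, silencing_rate = 0,
                           m5c_detection_rate = 1, seed = 1L,
                           extra_motifs = NULL) {
  stopifnot_scalar_prob(silencing_rate, "silencing_rate")
  stopifnot_scalar_prob(m5c_detection_rate, "m5c_detection_rate")
  bad <- vapply(truth, function(tr) {
    identical(tr$meth_type, "none") && !is.na(tr$motif %||% NA_character_)
  }, NA)
  if (any(bad))
    stop("family with meth_type 'none' carries a motif: ",
         paste(names(truth)[bad], collapse = ", "))
  mt <- gene_table[gene_table$active & gene_table$meth_type %in% METH_TYPES, ,
                   drop = FALSE]
  motifs <- vapply(mt$family_id, function(f) truth[[f]]$motif %||% NA_character_,
                   "")
  with_seed(seed, {
    expressed <- runif(nrow(mt)) >= silencing_rate
    detected <- ifelse(mt$meth_type == "m5C",
                       runif(nrow(mt)) < m5c_detection_rate, TRUE)
    keep <- expressed & detected & !is.na(motifs)
    out <- data.frame(strain_id = mt$strain_id[keep],
                      motif = motifs[keep],
                      type = mt$meth_type[keep],
                      methylated_offset = rep(NA_integer_, sum(keep)),
                      stringsAsFactors = FALSE)
    if (!is.null(extra_motifs)) {
      out <- rbind(out, extra_motifs[, c("strain_id", "motif", "type",
                                         "methylated_offset")])
    }
    rownames(out) <- NULL
    out
  })
}
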