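#' Completeness filter for a strain manifest
#'
#' Keeps genomes suitable for a census of complete, closed sequences. A
#' record flagged `complete_genome` in its definition line is always kept —
#' the flag short-circuits the other rules. Among the remainder, records are
#' dropped in a fixed rule order so that every rejection carries exactly one
#' primary reason: first whole-genome shotgun data (`wgs`), then longest
#' sequence under 500 kb (exactly 500,000 bp is kept), then a sequencing
#' project status short of `complete`. Malformed records (missing fields)
#' are dropped with reason `"malformed"`.
#'
#' @param manifest data.frame with at least `strain_id`, `definition_flag`
#'   (`complete_genome` / `wgs` / `other`), `longest_bp`, `project_status`
#'   (`complete` / `incomplete` / `unknown`)
#' @param min_longest_bp length threshold in bp (default 500,000; records
#'   strictly below it are dropped)
#' @return list with `kept` (data.frame) and `dropped` (data.frame with an
#'   added `reason` column: `wgs`, `length`, `status` or `malformed`)
#' @export
filter_complete <- function(manifest, min_longest_bp = 5e5) {
  needed <- c("strain_id", "definition_flag", "longest_bp", "project_status")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  malformed <- is.na(manifest$definition_flag) | is.na(manifest$longest_bp) |
    is.na(manifest$project_status) |
    !manifest$definition_flag %in% c("complete_genome", "wgs", "other")
  reason <- rep(NA_character_, nrow(manifest))
  reason[malformed] <- "malformed"
  flagged <- !malformed & manifest$definition_flag == "complete_genome"
  rest <- !malformed & !flagged
  # fixed rule order on the non-flagged remainder
  r_wgs <- rest & manifest$definition_flag == "wgs"
  reason[r_wgs] <- "wgs"
  r_len <- rest & !r_wgs & manifest$longest_bp < min_longest_bp
  reason[r_len] <- "length"
  r_status <- rest & !r_wgs & !r_len & manifest$project_status != "complete"
  reason[r_status] <- "status"
  if (any(malformed))
    message(sum(malformed), " malformed record(s) dropped")
  keep <- is.na(reason)
  kept <- manifest[keep, , drop = FALSE]
  dropped <- manifest[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}
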