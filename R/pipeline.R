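#' Run the full mutation-calling cascade
#'
#' Chains every stage of the caller: candidate enumeration (any cell with
#' a variant read), singlet removal, cross-lineage removal, the per-cell
#' binomial allelic filter, gene/trinucleotide annotation, lineage
#' enrichment statistics, the fixed final-filter thresholds, the
#' transcribed-strand context bias filter, and proximity clustering.
#' Attrition (candidate counts after every stage) is logged and attached
#' to the result.
#'
#' @param acm an [allele_count_matrix()].
#' @param cells cell metadata from [read_cell_metadata()].
#' @param genome named `DNAStringSet` of reference contigs.
#' @param masks a [mask_set()] (SNP sites, gene annotation).
#' @param config a [call_config()].
#' @return data.frame of final PASS calls (class `mutation_calls`), with
#'   attributes `attrition` (named stage counts), `flags` (the fully
#'   flagged pre-strand-filter table) and `strand_classes`.
#' @export
call_mutations <- function(acm, cells, genome, masks = mask_set(),
                           config = call_config()) {
  att <- c()
  cands <- enumerate_candidates(acm, cells)
  att["candidates"] <- nrow(cands)
  cands <- remove_singlets(cands)
  att["post_singlet"] <- nrow(cands)
  cands <- remove_cross_lineage_shared(cands, cells)
  att["post_cross_lineage"] <- nrow(cands)
  cands <- binomial_allelic_filter(cands, acm, alpha = config$binom_alpha)
  att["post_allelic_binomial"] <- nrow(cands)
  cands <- annotate_candidates(cands, genome, masks)
  cands <- compute_enrichment(cands, acm, cells, grouping = "lineage")
  thr <- apply_final_thresholds(cands, masks, config)
  flags <- attr(thr, "flags")
  att["post_thresholds"] <- nrow(thr)
  sb <- strand_bias_filter(thr, min_class_size = config$strand_min_class_size,
                           alpha = config$strand_alpha)
  att["post_strand_bias"] <- nrow(sb)
  final <- proximity_filter(sb, max_gap = config$proximity_bp)
  att["final_calls"] <- nrow(final)
  for (s in names(att)) sc_log(s, ": ", att[s])
  stopifnot(all(vapply(final$carriers, function(cc)
    length(unique(cells[cc, "lineage"])), 1L) <= 1L))
  attr(final, "attrition") <- att
  attr(final, "flags") <- flags
  attr(final, "strand_classes") <- attr(sb, "strand_classes")
  class(final) <- c("mutation_calls", "data.frame")
  final
}

#' Call mutations within clonotyped T cells
#'
#' Runs the same cascade restricted to cells carrying a TCR clonotype,
#' grouping by clonotype instead of major lineage (so the cross-lineage
#' and strand/proximity stages, which act across lineages or need genome
#' annotation, are replaced by the clonotype enrichment test at identical
#' thresholds: p < 1e-4, factor >= 5, >= 5 variant cells in the most
#' prevalent clonotype, >= 20 reference cells in the other clonotypes).
#' These calls feed the clonotype benchmark.
#'
#' @inheritParams call_mutations
#' @return data.frame of PASS clonotype-level calls.
#' @export
call_clonotype_mutations <- function(acm, cells, config = call_config()) {
  tcells <- cells[!is.na(cells$clonotype_id), , drop = FALSE]
  if (!nrow(tcells)) stop("no clonotyped cells in metadata")
  sub <- acm_subset(acm, cells = intersect(colnames(acm$ref), tcells$cell_id))
  sub <- acm_subset(sub, loci = Matrix::rowSums(sub$var) >= 1)
  if (!nrow(sub$loci))
    return(structure(data.frame(), class = c("mutation_calls", "data.frame")))
  cands <- enumerate_candidates(sub, tcells)
  cands <- remove_singlets(cands)
  cands <- binomial_allelic_filter(cands, sub, alpha = config$binom_alpha)
  cands <- compute_enrichment(cands, sub, tcells, grouping = "clonotype")
  thr <- apply_final_thresholds(cands, mask_set(), config)
  class(thr) <- c("mutation_calls", "data.frame")
  thr
}

#' @export
print.mutation_calls <- function(x, ...) {
  cat("mutation_calls:", nrow(x), "PASS calls over",
      length(unique(x$patient_id)), "patient(s)\n")
  att <- attr(x, "attrition")
  if (!is.null(att))
    cat(paste0("  ", names(att), ": ", att, collapse = "\n"), "\n")
  invisible(x)
}
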