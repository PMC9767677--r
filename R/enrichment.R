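#' Thresholds and tuning parameters of the calling cascade
#'
#' Defaults are the operating point of the published filter cascade:
#' Fisher enrichment p < 1e-4 with at least a 5-fold enrichment factor,
#' at least 5 variant cells in the top lineage and at least 20
#' reference-bearing cells in the reference population, a per-cell
#' binomial allelic filter at p < 0.05, a two-sided strand-bias binomial
#' filter at p < 0.005 over trinucleotide classes with at least 10
#' strand-assignable members, and removal of calls clustered within 4
#' bases of one another in a patient.
#'
#' @param fisher_alpha Fisher enrichment significance threshold.
#' @param min_enrichment minimum enrichment factor.
#' @param min_var_cells minimum variant cells in the top group.
#' @param min_ref_cells minimum reference cells outside the top group.
#' @param binom_alpha per-cell allelic filter significance.
#' @param strand_alpha strand-bias class test significance.
#' @param strand_min_class_size minimum strand-assignable mutations for a
#'   context class to be tested at all.
#' @param proximity_bp maximum distance (bp) at which two calls in one
#'   patient are considered a cluster and removed.
#' @return a list of class `call_config`.
#' @export
call_config <- function(fisher_alpha = 1e-4, min_enrichment = 5,
                        min_var_cells = 5L, min_ref_cells = 20L,
                        binom_alpha = 0.05, strand_alpha = 0.005,
                        strand_min_class_size = 10L, proximity_bp = 4L) {
  structure(list(fisher_alpha = fisher_alpha, min_enrichment = min_enrichment,
                 min_var_cells = as.integer(min_var_cells),
                 min_ref_cells = as.integer(min_ref_cells),
                 binom_alpha = binom_alpha, strand_alpha = strand_alpha,
                 strand_min_class_size = as.integer(strand_min_class_size),
                 proximity_bp = as.integer(proximity_bp)),
            class = "call_config")
}

## Variant / reference cell sets for one candidate within its patient.
## A "reference cell" covers the reference allele without a credible
## variant call: var == 0 and ref >= 1, or a carrier whose call was
## ignored by the allelic filter (it has a reference-read excess).
candidate_cell_classes <- function(candidate, acm, cells) {
  pcells <- cells$cell_id[cells$patient_id == candidate$patient_id]
  pcells <- intersect(colnames(acm$ref), pcells)
  cnt <- locus_counts(acm, candidate$locus, pcells)
  var_cells <- intersect(candidate$carriers[[1L]], pcells)
  ignored <- intersect(candidate$carriers_ignored[[1L]], pcells)
  ref_cells <- pcells[(cnt$var == 0 & cnt$ref >= 1)]
  ref_cells <- union(ref_cells[!ref_cells %in% var_cells], ignored)
  list(var_cells = var_cells, ref_cells = ref_cells)
}

#' Two-by-two enrichment table for a candidate
#'
#' Cells of the candidate's patient are split into variant cells (credible
#' carriers) and reference cells (reference reads, no credible variant
#' call), then grouped by major lineage or TCR clonotype. The top group is
#' the one with the most variant cells, ties broken lexicographically (and
#' flagged); all remaining groups are pooled.
#'
#' @param candidate one-row candidates data.frame.
#' @param acm allele count matrix.
#' @param cells cell metadata.
#' @param grouping `"lineage"` or `"clonotype"`.
#' @return list with `top_group`, `var_top`, `ref_top`, `var_other`,
#'   `ref_other` and `tie` (logical).
#' @export
group_counts <- function(candidate, acm, cells,
                         grouping = c("lineage", "clonotype")) {
  grouping <- match.arg(grouping)
  gcol <- if (grouping == "lineage") "lineage" else "clonotype_id"
  if (grouping == "clonotype" && all(is.na(cells$clonotype_id)))
    stop("clonotype grouping requested but no cell has a clonotype_id")
  cls <- candidate_cell_classes(candidate, acm, cells)
  gv <- cells[cls$var_cells, gcol]
  gr <- cells[cls$ref_cells, gcol]
  gv <- gv[!is.na(gv)]; gr <- gr[!is.na(gr)]
  groups <- sort(unique(c(gv, gr)))
  vt <- table(factor(gv, levels = groups))
  rt <- table(factor(gr, levels = groups))
  if (length(groups) == 0)
    return(list(top_group = NA_character_, var_top = 0L, ref_top = 0L,
                var_other = 0L, ref_other = 0L, tie = FALSE))
  top <- groups[which.max(vt)]  # which.max takes the first = lexicographic
  tie <- sum(vt == max(vt)) > 1L && max(vt) > 0
  list(top_group = top,
       var_top = as.integer(vt[top]), ref_top = as.integer(rt[top]),
       var_other = as.integer(sum(vt) - vt[top]),
       ref_other = as.integer(sum(rt) - rt[top]),
       tie = tie)
}

#' One-sided Fisher enrichment test and enrichment factor
#'
#' Tests whether variant cells are proportionally concentrated in the top
#' group: the one-sided (greater) exact hypergeometric tail for the 2x2
#' table `[[var_top, ref_top], [var_other, ref_other]]`. The enrichment
#' factor is the prevalence ratio
#' `(var_top/(var_top+ref_top)) / (var_other/(var_other+ref_other))`,
#' `+Inf` when the mutation is absent outside the top group, and 0 for a
#' degenerate all-zero table (for which p = 1).
#'
#' @param var_top,ref_top,var_other,ref_other the 2x2 table cells; the
#'   first argument may instead be a 2x2 matrix with rows (top, other)
#'   and columns (variant, reference).
#' @return list with `fisher_p` and `enrichment_factor`.
#' @export
fisher_enrichment <- function(var_top, ref_top = NULL, var_other = NULL,
                              ref_other = NULL) {
  if (is.matrix(var_top)) {
    tab <- var_top
    var_top <- tab[1, 1]; ref_top <- tab[1, 2]
    var_other <- tab[2, 1]; ref_other <- tab[2, 2]
  }
  if (any(c(var_top, ref_top, var_other, ref_other) < 0))
    stop("negative cell counts in enrichment table")
  n_top <- var_top + ref_top
  n_var <- var_top + var_other
  n_tot <- n_top + var_other + ref_other
  if (n_tot == 0)
    return(list(fisher_p = 1, enrichment_factor = 0))
  p <- phyper(var_top - 1, n_var, n_tot - n_var, n_top, lower.tail = FALSE)
  prev_top <- if (n_top > 0) var_top / n_top else 0
  n_other <- var_other + ref_other
  ef <- if (var_top == 0) {
    0
  } else if (var_other == 0) {
    Inf
  } else {
    prev_top / (var_other / n_other)
  }
  list(fisher_p = p, enrichment_factor = ef)
}

#' Attach enrichment statistics to every candidate
#'
#' @param candidates candidates table (post allelic filter).
#' @param acm allele count matrix.
#' @param cells cell metadata.
#' @param grouping `"lineage"` (default) or `"clonotype"`.
#' @return candidates with columns `top_group`, `var_cells_top`,
#'   `ref_cells_top`, `var_cells_other`, `ref_cells_other`, `fisher_p`,
#'   `enrichment_factor`, `top_tie`.
#' @export
compute_enrichment <- function(candidates, acm, cells,
                               grouping = c("lineage", "clonotype")) {
  grouping <- match.arg(grouping)
  n <- nrow(candidates)
  cols <- data.frame(top_group = character(n), var_cells_top = integer(n),
                     ref_cells_top = integer(n), var_cells_other = integer(n),
                     ref_cells_other = integer(n), fisher_p = numeric(n),
                     enrichment_factor = numeric(n), top_tie = logical(n))
  for (r in seq_len(n)) {
    gc <- group_counts(candidates[r, , drop = FALSE], acm, cells, grouping)
    fe <- fisher_enrichment(gc$var_top, gc$ref_top, gc$var_other, gc$ref_other)
    cols$top_group[r] <- gc$top_group
    cols$var_cells_top[r] <- gc$var_top
    cols$ref_cells_top[r] <- gc$ref_top
    cols$var_cells_other[r] <- gc$var_other
    cols$ref_cells_other[r] <- gc$ref_other
    cols$fisher_p[r] <- fe$fisher_p
    cols$enrichment_factor[r] <- fe$enrichment_factor
    cols$top_tie[r] <- gc$tie
  }
  cbind(candidates, cols)
}

#' Apply the fixed final-filter thresholds
#'
#' The four criteria of the final filter: (i) Fisher enrichment p below
#' `fisher_alpha` with an enrichment factor of at least `min_enrichment`;
#' (ii) absence from the known-SNP mask; (iii) the site is not called in
#' any other patient; (iv) adequate coverage — at least `min_var_cells`
#' variant cells in the top group and `min_ref_cells` reference cells in
#' the reference population. No multiple-testing correction is applied:
#' the cascade works at fixed raw thresholds.
#'
#' @param calls candidates with enrichment columns, pooled across all
#'   patients (cross-patient sharing is judged on this set).
#' @param masks a [mask_set()].
#' @param config a [call_config()].
#' @return the surviving calls; the full table with per-criterion logical
#'   flags (`pass_fisher`, `pass_enrichment`, `pass_snp`,
#'   `pass_patient_unique`, `pass_min_var`, `pass_min_ref`, `pass`) is
#'   attached as attribute `"flags"`.
#' @export
apply_final_thresholds <- function(calls, masks = mask_set(),
                                   config = call_config()) {
  site <- paste(calls$chrom, calls$pos, calls$alt, sep = ":")
  n_pat <- vapply(split(calls$patient_id, site),
                  function(p) length(unique(p)), 1L)
  calls$pass_fisher <- calls$fisher_p < config$fisher_alpha
  calls$pass_enrichment <- calls$enrichment_factor >= config$min_enrichment
  calls$pass_snp <- !(site %in% masks$snp_keys)
  calls$pass_patient_unique <- n_pat[site] == 1L
  calls$pass_min_var <- calls$var_cells_top >= config$min_var_cells
  calls$pass_min_ref <- calls$ref_cells_other >= config$min_ref_cells
  calls$pass <- calls$pass_fisher & calls$pass_enrichment & calls$pass_snp &
    calls$pass_patient_unique & calls$pass_min_var & calls$pass_min_ref
  out <- calls[calls$pass, , drop = FALSE]
  attr(out, "flags") <- calls
  out
}

#' Transcribed-strand context bias filter
#'
#' Some substitution classes arise at the RNA level (library preparation,
#' sequencing chemistry or RNA editing) rather than in DNA; these show a
#' strong asymmetry between genes transcribed from the plus versus minus
#' strand, which no DNA mutational process produces. Calls are pooled
#' across the dataset into classes keyed by (trinucleotide context, alt
#' base) in reference orientation; for every class with at least
#' `min_class_size` strand-assignable members, strand counts are tested
#' against balance with a two-sided exact binomial test, and every member
#' of a failing class is removed — including members without a strand
#' assignment, erring toward specificity. Smaller classes are untested
#' and retained.
#'
#' @param calls annotated calls (need `tri_context`, `alt`, `tx_strand`).
#' @param min_class_size minimum strand-assignable class size to test.
#' @param alpha class-level significance (default 0.005).
#' @return surviving calls; a per-class summary (counts, p, removed) is
#'   attached as attribute `"strand_classes"`.
#' @export
strand_bias_filter <- function(calls, min_class_size = 10L, alpha = 0.005) {
  if (!nrow(calls)) {
    attr(calls, "strand_classes") <- data.frame()
    return(calls)
  }
  cls <- sprintf("%s>%s", calls$tri_context, calls$alt)
  summ <- do.call(rbind, lapply(split(seq_along(cls), cls), function(idx) {
    strands <- calls$tx_strand[idx]
    n_plus <- sum(strands == "+", na.rm = TRUE)
    n_minus <- sum(strands == "-", na.rm = TRUE)
    n <- n_plus + n_minus
    tested <- n >= min_class_size
    p <- if (tested) stats::binom.test(n_plus, n, 0.5)$p.value else NA_real_
    data.frame(class = cls[idx[1]], n_members = length(idx),
               n_plus = n_plus, n_minus = n_minus, tested = tested,
               p = p, removed = tested && !is.na(p) && p < alpha)
  }))
  rownames(summ) <- summ$class
  keep <- !summ[cls, "removed"]
  out <- calls[keep, , drop = FALSE]
  attr(out, "strand_classes") <- summ
  out
}

#' Remove proximity-clustered calls
#'
#' Within each patient, any group of calls on one chromosome in which
#' consecutive positions lie within `max_gap` bases of each other is
#' removed wholesale (clusters are transitive); such clusters betray
#' alignment artifacts rather than independent mutations.
#'
#' @param calls calls table.
#' @param max_gap maximum distance defining a cluster (default 4 bp).
#' @return surviving calls; removed locus keys in attribute `"removed"`.
#' @export
proximity_filter <- function(calls, max_gap = 4L) {
  if (!nrow(calls)) {
    attr(calls, "removed") <- character()
    return(calls)
  }
  drop <- logical(nrow(calls))
  for (idx in split(seq_len(nrow(calls)),
                    paste(calls$patient_id, calls$chrom))) {
    ord <- idx[order(calls$pos[idx])]
    pos <- calls$pos[ord]
    if (length(pos) < 2) next
    new_cluster <- c(TRUE, diff(pos) > max_gap)
    cl <- cumsum(new_cluster)
    sizes <- table(cl)
    drop[ord] <- sizes[as.character(cl)] >= 2
  }
  out <- calls[!drop, , drop = FALSE]
  attr(out, "removed") <- calls$locus[drop]
  out
}
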