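#' Read a DNA-evidence table
#'
#' Per-locus orthogonal DNA read support used to benchmark the
#' scRNA-derived calls: tumor variant/reference pileup read counts,
#' matched-normal variant reads, and whether the orthogonal DNA pipeline
#' called the site.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_var`, `tumor_ref`, `normal_var`, `orthogonal_call` (logical
#'   or 0/1); an optional `patient_id` column scopes evidence per patient.
#' @return data.frame keyed by locus (rownames = locus keys, or
#'   patient-prefixed keys when `patient_id` is present).
#' @export
read_dna_evidence <- function(path) {
  tab <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "tumor_var", "tumor_ref",
           "normal_var", "orthogonal_call")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("DNA evidence table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(tab$tumor_var < 0 | tab$tumor_ref < 0 | tab$normal_var < 0))
    stop("DNA evidence: negative read counts")
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$orthogonal_call <- as.logical(tab$orthogonal_call)
  key <- locus_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  if ("patient_id" %in% names(tab)) key <- paste(tab$patient_id, key)
  if (anyDuplicated(key)) stop("DNA evidence: duplicate loci")
  rownames(tab) <- key
  tab
}

## Coverage-adequacy check for a locus that scRNA did not call: is there
## one lineage with >= min_var cells holding any read, and >= min_ref
## cells carrying the reference base outside that lineage?
scrna_coverage_adequate <- function(acm, cells, key, patient_id,
                                    min_var = 5L, min_ref = 20L) {
  if (!key %in% rownames(acm$loci)) return(FALSE)
  pcells <- intersect(colnames(acm$ref),
                      cells$cell_id[cells$patient_id == patient_id])
  cnt <- locus_counts(acm, key, pcells)
  covered <- cnt$ref + cnt$var >= 1
  if (!any(covered)) return(FALSE)
  lin <- cells[pcells, "lineage"]
  cov_by_lin <- tapply(covered, lin, sum)
  top <- names(cov_by_lin)[which.max(cov_by_lin)]
  ref_cells <- cnt$ref >= 1 & cnt$var == 0 & lin != top
  max(cov_by_lin) >= min_var && sum(ref_cells) >= min_ref
}

#' Classify scRNA calls against orthogonal DNA evidence
#'
#' Each scRNA call becomes exactly one of: `TP` (also called by the DNA
#' pipeline), `TP_pileup_only` (not called orthogonally, but the tumor
#' pileup shows variant reads — at least `min_pileup_var` — with none in
#' the matched normal; typically low-coverage or mitochondrial sites),
#' `FP` (fewer than 5 variant reads and more than 20 reference reads in
#' the DNA — the DNA had power and saw nothing), or `indeterminate`
#' (insufficient DNA depth to corroborate either way; also used, with a
#' warning, for calls absent from the evidence table). Each DNA-pipeline
#' call that scRNA missed becomes `FN` when the scRNA data had adequate
#' coverage to call it (>= 5 cells of one lineage with any read at the
#' locus and >= 20 reference cells elsewhere), else it is ignored.
#'
#' @param calls final scRNA calls ([call_mutations()]).
#' @param dna DNA evidence from [read_dna_evidence()].
#' @param acm allele count matrix (for FN coverage checks).
#' @param cells cell metadata.
#' @param min_pileup_var minimum tumor pileup variant reads counting as
#'   DNA evidence of the mutation (default 2).
#' @return data.frame with one row per considered locus: `locus`,
#'   `patient_id`, `source` (scRNA/DNA-only) and `category`.
#' @export
classify_calls <- function(calls, dna, acm, cells, min_pileup_var = 2L) {
  per_patient <- "patient_id" %in% names(dna) &&
    any(grepl(" ", rownames(dna), fixed = TRUE))
  dkey <- function(patient, key) if (per_patient) paste(patient, key) else key
  rows <- list()
  for (r in seq_len(nrow(calls))) {
    key <- calls$locus[r]; pat <- calls$patient_id[r]
    k <- dkey(pat, key)
    if (!k %in% rownames(dna)) {
      warning("scRNA call absent from DNA evidence table: ", key,
              " (treated as indeterminate)")
      cat_ <- "indeterminate"
    } else {
      e <- dna[k, ]
      cat_ <- if (isTRUE(e$orthogonal_call)) {
        "TP"
      } else if (e$tumor_var >= min_pileup_var && e$normal_var == 0) {
        "TP_pileup_only"
      } else if (e$tumor_var < 5 && e$tumor_ref > 20) {
        "FP"
      } else {
        "indeterminate"
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(locus = key, patient_id = pat, source = "scRNA",
                 category = cat_)
  }
  called <- dkey(calls$patient_id, calls$locus)
  dna_only <- dna[dna$orthogonal_call & !(rownames(dna) %in% called), ,
                  drop = FALSE]
  for (r in seq_len(nrow(dna_only))) {
    e <- dna_only[r, ]
    key <- locus_key(e$chrom, e$pos, e$ref, e$alt)
    pat <- if ("patient_id" %in% names(e)) e$patient_id else
      unique(cells$patient_id)[1]
    cat_ <- if (scrna_coverage_adequate(acm, cells, key, pat)) "FN" else
      "no_scrna_coverage"
    rows[[length(rows) + 1L]] <-
      data.frame(locus = key, patient_id = pat, source = "DNA_only",
                 category = cat_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precision and sensitivity from benchmark categories
#'
#' Precision counts pileup-corroborated calls as true:
#' `(TP + TP_pileup_only) / (TP + TP_pileup_only + FP)`. Sensitivity is
#' relative to the orthogonal DNA calls: `TP / (TP + FN)`. Indeterminate
#' calls and DNA-only loci without adequate scRNA coverage enter neither
#' statistic. A zero denominator yields `NA` (absent), never 0.
#'
#' @param categories per-locus classification from [classify_calls()],
#'   or a named vector/list of category counts.
#' @return list with `precision`, `sensitivity`, and the `counts`.
#' @export
precision_sensitivity <- function(categories) {
  lv <- c("TP", "TP_pileup_only", "FP", "FN", "indeterminate",
          "no_scrna_coverage")
  cnt <- if (is.data.frame(categories)) {
    table(factor(categories$category, levels = lv))
  } else {
    full <- setNames(rep(0L, length(lv)), lv)
    full[names(categories)] <- unlist(categories)
    as.table(full)
  }
  prec_den <- cnt["TP"] + cnt["TP_pileup_only"] + cnt["FP"]
  sens_den <- cnt["TP"] + cnt["FN"]
  list(precision = if (prec_den > 0)
         unname((cnt["TP"] + cnt["TP_pileup_only"]) / prec_den) else NA_real_,
       sensitivity = if (sens_den > 0)
         unname(cnt["TP"] / sens_den) else NA_real_,
       counts = cnt)
}

#' Benchmark report with exonic-only statistics
#'
#' @param categories classification from [classify_calls()].
#' @param exonic optional logical vector (same length) marking loci whose
#'   calls are exonic; when supplied, precision/sensitivity are also
#'   computed on the exonic subset.
#' @return list of class `benchmark_report`.
#' @export
benchmark_report <- function(categories, exonic = NULL) {
  overall <- precision_sensitivity(categories)
  out <- list(counts = overall$counts, precision = overall$precision,
              sensitivity = overall$sensitivity,
              precision_exonic = NA_real_, sensitivity_exonic = NA_real_)
  if (!is.null(exonic)) {
    sub <- precision_sensitivity(categories[exonic, , drop = FALSE])
    out$precision_exonic <- sub$precision
    out$sensitivity_exonic <- sub$sensitivity
  }
  class(out) <- "benchmark_report"
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report\n")
  print(x$counts)
  cat(sprintf("precision = %.3f  sensitivity = %.3f\n",
              x$precision, x$sensitivity))
  if (!is.na(x$precision_exonic))
    cat(sprintf("exonic: precision = %.3f  sensitivity = %.3f\n",
                x$precision_exonic, x$sensitivity_exonic))
  invisible(x)
}

#' Fraction of clonotype-level calls restricted to a single TCR clone
#'
#' Somatic mutations in adult expanded CD8+ T cells are mostly acquired
#' after thymic selection, so a genuine call should sit inside one
#' clonotype; a call whose variant cells span clonotypes (variant cells
#' outside the top clonotype) counts as unrestricted.
#'
#' @param calls clonotype-level calls from [call_clonotype_mutations()].
#' @return list with `fraction` (restricted / evaluated), `n_calls` and
#'   `n_restricted`; `fraction` is `NA` when no calls are evaluated.
#' @export
clonotype_restriction <- function(calls) {
  n <- nrow(calls)
  restricted <- if (n) sum(calls$var_cells_other == 0L) else 0L
  list(fraction = if (n) restricted / n else NA_real_,
       n_calls = n, n_restricted = restricted)
}

#' Write a benchmark report as JSON
#'
#' @param report a `benchmark_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_json <- function(report, path) {
  jsonlite::write_json(
    list(counts = as.list(unclass(report$counts)),
         precision = report$precision, sensitivity = report$sensitivity,
         precision_exonic = report$precision_exonic,
         sensitivity_exonic = report$sensitivity_exonic),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
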